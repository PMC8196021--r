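# Fixtures are generated in code; the small atlas is cached across tests.

tiny_series <- function(nt, id = "s1", dims = c(4L, 4L, 3L), group = "control",
                        tr = 3, seed = 1) {
  data <- withr::with_seed(seed,
    array(rnorm(prod(dims) * nt, mean = 100), dim = c(dims, nt)))
  structure(
    list(data = data, tr = tr, brain_mask = array(TRUE, dim = dims),
         subject_id = id, group = group),
    class = "bold_series"
  )
}

small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom_atlas(c(18L, 18L, 16L), seed = 2)
    cache
  }
})

# tiny rest cohort on the small atlas, trimmed and concatenated
small_rest_group <- function(n = 3, n_volumes = 65, seed0 = 40, group = "control",
                             effect = effect_spec(), scale_voxels = FALSE) {
  atlas <- small_atlas()
  design <- make_design("rest", tr = 3, n_volumes = n_volumes)
  runs <- lapply(seq_len(n), function(i) trim_initial_volumes(
    simulate_subject(atlas, design, group, effect = effect, seed = seed0 + i,
                     subject_id = sprintf("%s%02d", group, i)), 5))
  concatenate_group(runs, mask = atlas$brain_mask, group = group,
                    scale_voxels = scale_voxels)
}
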