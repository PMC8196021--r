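#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end study emulation. The defaults
#' mirror the acquisition and analysis settings of the two-group
#' (7 control / 5 injured) resting-state + block-design study the package
#' models: TR 3 s, 305 resting and 125 task volumes with 5 trimmed, six group
#' datasets, lambda 0.15, dictionaries sized to the run length, 70 ICA
#' components, z-threshold 1, alpha 0.05.
#'
#' @param grid_dims Phantom grid dimensions.
#' @param atlas_seed Seed for atlas placement.
#' @param tr Repetition time in seconds.
#' @param rest_volumes Volumes per resting run.
#' @param dead_time,block_on,block_off,n_cycles Block-design timing (seconds).
#' @param trim Leading volumes dropped from every run.
#' @param groups Named list of `c(control = , injured = )` cohort sizes per
#'   paradigm (`rest`, `task_visual`, `task_tactile`).
#' @param task_networks Networks driven by each task paradigm.
#' @param methods Decomposition methods to run (`"sdl"`, `"ica"`).
#' @param lambda Sparsity weight for sparse coding.
#' @param n_atoms Named vector `c(rest = , task = )` of dictionary sizes.
#' @param n_components ICA component count.
#' @param sdl_max_iter Outer iterations for dictionary learning.
#' @param alpha Significance level for tests and permutation tails.
#' @param z_cut Map z-score threshold.
#' @param effect An [effect_spec()] describing the injury.
#' @param networks Networks to evaluate against the atlas.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param out_dir Output directory.
#' @return A `netdisrupt_config` list.
#' @export
netdisrupt_config <- function(grid_dims = c(24L, 24L, 16L), atlas_seed = 1L,
                              tr = 3, rest_volumes = 305L, dead_time = 15,
                              block_on = 30, block_off = 30, n_cycles = 6L,
                              trim = 5L,
                              groups = list(rest = c(control = 7L, injured = 5L),
                                            task_visual = c(control = 6L, injured = 5L),
                                            task_tactile = c(control = 4L, injured = 5L)),
                              task_networks = list(task_visual = "VIS",
                                                   task_tactile = c("SM", "EX", "CERE")),
                              methods = c("sdl", "ica"),
                              lambda = 0.15,
                              n_atoms = c(rest = 300L, task = 120L),
                              n_components = 70L,
                              sdl_max_iter = 10L,
                              alpha = 0.05, z_cut = 1,
                              effect = effect_spec(
                                attenuated = c(EX1 = 0.4, EX2 = 0.4, EX3 = 0.4,
                                               VIS1 = 0.3, VIS2 = 0.3, VIS3 = 0.3),
                                elevated = c(EX5 = 1.5, EX6 = 1.5)),
                              networks = network_names(),
                              seed = 1L, out_dir = tempfile("netdisrupt_run")) {
  stopifnot(lambda >= 0, alpha > 0, alpha < 1, trim >= 0,
            all(unlist(groups) >= 1))
  structure(
    list(grid_dims = grid_dims, atlas_seed = atlas_seed, tr = tr,
         rest_volumes = rest_volumes, dead_time = dead_time,
         block_on = block_on, block_off = block_off, n_cycles = n_cycles,
         trim = trim, groups = groups, task_networks = task_networks,
         methods = methods, lambda = lambda, n_atoms = n_atoms,
         n_components = n_components, sdl_max_iter = sdl_max_iter,
         alpha = alpha, z_cut = z_cut, effect = effect, networks = networks,
         seed = seed, out_dir = out_dir),
    class = "netdisrupt_config"
  )
}

#' Scaled-down demo configuration
#'
#' Same pipeline, smaller problem: 18 x 18 x 16 grid, 100-volume resting runs,
#' a 2-cycle block task (45 volumes), 4 control / 3 injured subjects per
#' paradigm, 20/16 dictionary atoms and 8 ICA components, so the whole
#' simulate-to-permutation run completes in minutes on one CPU.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param ... Overrides forwarded to [netdisrupt_config()].
#' @return A `netdisrupt_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("netdisrupt_demo"), ...) {
  netdisrupt_config(
    grid_dims = c(18L, 18L, 16L), rest_volumes = 100L, n_cycles = 2L,
    groups = list(rest = c(control = 4L, injured = 3L),
                  task_visual = c(control = 4L, injured = 3L),
                  task_tactile = c(control = 4L, injured = 3L)),
    n_atoms = c(rest = 20L, task = 16L), n_components = 8L,
    sdl_max_iter = 6L, seed = seed, out_dir = out_dir, ...
  )
}

# deterministic per-subject seed derivation kept below 2^31
derive_seed <- function(master, k) {
  (as.integer(master) %% 1000000L) * 1000L + k
}

#' Run the full simulate-to-permutation pipeline
#'
#' Executes, per paradigm and group: phantom simulation, trimming,
#' temporal concatenation, group decomposition (sparse dictionary learning
#' with dual regression and/or group ICA with back-reconstruction),
#' normalization and z-thresholding, maximal-map selection against every
#' network atlas with Pearson/mean-ratio metrics, Welch group tests under the
#' dual-metric rule, and the exhaustive voxelwise permutation test on the
#' sDL final maps with per-region percentages and NIfTI overlays. All
#' artifacts land under `config$out_dir`; a JSON manifest records sizes,
#' seeds and checksums.
#'
#' @param config A `netdisrupt_config`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "netdisrupt_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[netdisrupt] %s", sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  manifest <- list(package = "netdisrupt",
                   version = as.character(utils::packageVersion("netdisrupt")),
                   seed = config$seed, alpha = config$alpha,
                   lambda = config$lambda)

  atlas <- stage("atlas", {
    a <- make_phantom_atlas(config$grid_dims, config$atlas_seed)
    write_atlas(a, file.path(out, "atlas.nii.gz"))
    a
  })
  log_msg("atlas: %d brain voxels, %d structures", sum(atlas$brain_mask),
          nrow(atlas$structures))

  designs <- stage("designs", list(
    rest = make_design("rest", tr = config$tr, n_volumes = config$rest_volumes),
    block = make_design("block", tr = config$tr, dead_time = config$dead_time,
                        block_on = config$block_on, block_off = config$block_off,
                        n_cycles = config$n_cycles)
  ))

  paradigms <- names(config$groups)
  group_data <- list()
  counter <- 0L
  for (par in paradigms) {
    design <- if (par == "rest") designs$rest else designs$block
    tnets <- if (par == "rest") NULL else config$task_networks[[par]]
    for (grp in c("control", "injured")) {
      n <- config$groups[[par]][[grp]]
      runs <- stage(paste0("simulate/", par, "/", grp), lapply(seq_len(n), function(i) {
        counter <<- counter + 1L
        simulate_subject(atlas, design, group = grp, effect = config$effect,
                         seed = derive_seed(config$seed, counter),
                         subject_id = sprintf("%s_%s_%02d", par, grp, i),
                         task_networks = tnets)
      }))
      runs <- lapply(runs, trim_initial_volumes, k = config$trim)
      gd <- stage(paste0("concatenate/", par, "/", grp),
                  concatenate_group(runs, mask = atlas$brain_mask,
                                    paradigm = par, group = grp,
                                    scale_voxels = TRUE))
      group_data[[paste(par, grp, sep = "/")]] <- gd
      log_msg("group dataset %s/%s: %d x %d", par, grp, nrow(gd$matrix),
              ncol(gd$matrix))
    }
  }
  manifest$group_datasets <- lapply(group_data, function(g)
    list(paradigm = g$paradigm, group = g$group, voxels = nrow(g$matrix),
         volumes = ncol(g$matrix), subjects = nrow(g$spans)))
  jsonlite::write_json(
    lapply(group_data, function(g) g$spans),
    file.path(out, "group_spans.json"), auto_unbox = TRUE, digits = NA)

  metrics <- list()
  final_sdl_maps <- list()   # [[paradigm]][[network]][[group]] -> V x n matrix
  fit_seed <- 0L
  for (key in names(group_data)) {
    gd <- group_data[[key]]
    par <- gd$paradigm; grp <- gd$group
    natoms <- unname(config$n_atoms[[if (par == "rest") "rest" else "task"]])
    bm <- atlas$brain_mask
    net_ind <- lapply(config$networks, function(nw) network_mask(atlas, nw)[bm])
    names(net_ind) <- config$networks

    for (method in config$methods) {
      fit_seed <- fit_seed + 1L
      log_msg("decompose %s (%s)", key, method)
      if (method == "sdl") {
        fit <- stage(paste0("sdl/", key),
                     suppressWarnings(sdl_fit(gd, n_atoms = natoms,
                                              lambda = config$lambda,
                                              max_iter = config$sdl_max_iter,
                                              seed = derive_seed(config$seed, 900L + fit_seed))))
        gmax <- group_max(fit)
        subj_maps <- lapply(gd$spans$subject_id, function(sid) {
          dr <- dual_regression(extract_subject(gd, sid), fit$maps,
                                lambda = config$lambda)
          suppressWarnings(normalize_and_threshold(dr$maps, gmax, config$z_cut))
        })
      } else {
        fit <- stage(paste0("ica/", key),
                     suppressWarnings(group_ica(gd, n_components = config$n_components,
                                                seed = derive_seed(config$seed, 900L + fit_seed))))
        gmax <- group_max(fit)
        subj_maps <- lapply(gd$spans$subject_id, function(sid)
          suppressWarnings(normalize_and_threshold(back_reconstruct(fit, sid),
                                                   gmax, config$z_cut)))
      }
      names(subj_maps) <- gd$spans$subject_id

      for (nw in config$networks) {
        for (sid in gd$spans$subject_id) {
          sel <- select_maximal_map(subj_maps[[sid]], net_ind[[nw]], method)
          rec <- structure_metrics(sel$map, atlas, nw, subject_id = sid,
                                   method = method, paradigm = par)
          rec$group <- grp
          metrics[[length(metrics) + 1L]] <- rec
          if (method == "sdl")
            final_sdl_maps[[par]][[nw]][[grp]] <-
              cbind(final_sdl_maps[[par]][[nw]][[grp]], sel$map)
        }
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

  tests <- stage("group_tests", group_metric_tests(metrics, alpha = config$alpha))
  utils::write.csv(tests, file.path(out, "group_tests.csv"), row.names = FALSE)

  perm_rows <- list()
  if ("sdl" %in% config$methods) {
    vi <- which(atlas$brain_mask)
    for (par in names(final_sdl_maps)) {
      for (nw in names(final_sdl_maps[[par]])) {
        pm <- final_sdl_maps[[par]][[nw]]
        field <- stage(paste0("permtest/", par, "/", nw),
                       voxelwise_permutation(pm$control, pm$injured,
                                             alpha = config$alpha,
                                             voxel_index = vi,
                                             dims = atlas$dims))
        export_permutation_map(field,
                               file.path(out, sprintf("perm_%s_%s.nii.gz", par, nw)))
        rp <- region_percentages(field, atlas)
        rp <- rp[rp$network == nw, ]
        rp$paradigm <- par
        perm_rows[[length(perm_rows) + 1L]] <- rp
      }
    }
    perm_rows <- dplyr::bind_rows(perm_rows)
    utils::write.csv(perm_rows, file.path(out, "region_percentages.csv"),
                     row.names = FALSE)
  }

  files <- list.files(out, full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  manifest$out_dir <- out
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("done: %s", out)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Prints per-network metric tables in the layout of a group-comparison
#' results table — network rows with member-structure subrows, the Welch
#' p-values for the Pearson and mean-ratio metrics, and significance markers
#' (`*` significant decrease, `#` significant increase under the dual-metric
#' rule) — plus the permutation percentage summary. Missing artifacts are
#' listed and the remaining report is still produced.
#'
#' @param run A manifest returned by [run_pipeline()] or the run directory.
#' @return List of the underlying tibbles (`tests`, `percentages`), invisibly.
#' @export
report_run <- function(run) {
  dir <- if (is.character(run)) run else run$out_dir
  missing <- character()
  read_or_null <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) { missing <<- c(missing, f); return(NULL) }
    as_tibble(utils::read.csv(p))
  }
  tests <- read_or_null("group_tests.csv")
  pcts <- read_or_null("region_percentages.csv")
  if (length(missing))
    cat("Missing artifacts:", paste(missing, collapse = ", "), "\n")

  if (!is.null(tests)) {
    wide <- tidyr::pivot_wider(
      tests[, c("method", "paradigm", "network", "region", "region_type",
                "metric", "p_value", "significant_region", "region_direction")],
      names_from = "metric", values_from = "p_value")
    for (m in unique(wide$method)) for (par in unique(wide$paradigm)) {
      sub <- wide[wide$method == m & wide$paradigm == par, ]
      if (!nrow(sub)) next
      cat(sprintf("\n== %s / %s ==\n", toupper(m), par))
      cat(sprintf("%-28s %8s %10s %4s\n", "region", "Pearson", "MeanRatio", "Sig"))
      for (nw in unique(sub$network)) {
        nsub <- sub[sub$network == nw, ]
        nsub <- nsub[order(nsub$region_type != "network", nsub$region), ]
        for (i in seq_len(nrow(nsub))) {
          r <- nsub[i, ]
          mark <- if (isTRUE(r$significant_region))
            (if (identical(r$region_direction, "decrease")) "*" else "#") else ""
          ind <- if (r$region_type == "network") "" else "  "
          cat(sprintf("%-28s %8.3f %10.3f %4s\n",
                      paste0(ind, r$region),
                      r$pearson, r$mean_ratio, mark))
        }
      }
    }
  }
  if (!is.null(pcts)) {
    cat("\n== permutation: % significantly different voxels ==\n")
    cat(sprintf("%-14s %-10s %-8s %10s %10s\n", "paradigm", "network",
                "region", "%decrease", "%increase"))
    for (i in seq_len(nrow(pcts)))
      cat(sprintf("%-14s %-10s %-8s %10.1f %10.1f\n", pcts$paradigm[i],
                  pcts$network[i], pcts$region[i],
                  pcts$pct_decreasing[i], pcts$pct_increasing[i]))
  }
  invisible(list(tests = tests, percentages = pcts))
}
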