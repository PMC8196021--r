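test_that("phantom atlas has the full structure inventory and consistent masks", {
  atlas <- make_phantom_atlas(c(24, 24, 16), seed = 1)

  expect_equal(nrow(atlas$structures), 17L)
  expect_setequal(unique(atlas$structures$network), network_names())
  counts <- table(atlas$structures$network)
  expect_equal(unname(counts[c("VIS", "EX", "SM")]), c(3L, 7L, 3L),
               ignore_attr = TRUE)

  # every labeled voxel lies inside the brain mask
  expect_true(all(atlas$brain_mask[atlas$labels > 0]))

  # structure masks are pairwise disjoint (a voxel carries one label)
  per_structure <- vapply(atlas$structures$structure,
                          function(s) sum(structure_mask(atlas, s)), numeric(1))
  expect_equal(sum(per_structure), sum(atlas$labels > 0))
  expect_true(all(per_structure > 0))

  # each network mask is the exact union of its member structures
  for (nw in network_names()) {
    members <- atlas$structures$structure[atlas$structures$network == nw]
    un <- Reduce(`|`, lapply(members, structure_mask, atlas = atlas))
    expect_identical(network_mask(atlas, nw), un)
  }
})

test_that("atlas generation is deterministic and fails loudly when blobs cannot fit", {
  a1 <- make_phantom_atlas(c(18, 18, 16), seed = 5)
  a2 <- make_phantom_atlas(c(18, 18, 16), seed = 5)
  expect_identical(a1$labels, a2$labels)

  expect_error(make_phantom_atlas(c(15, 24, 16)), ">= 16")
  # oversized blobs cannot be packed; the error names the failing structure
  expect_error(make_phantom_atlas(c(16, 16, 16), seed = 1,
                                  blob_radius = c(6, 7)),
               "could not place structure")
})

test_that("block design arithmetic and regressor construction are correct", {
  d <- make_design("block", tr = 3, dead_time = 15, block_on = 30,
                   block_off = 30, n_cycles = 6)
  expect_equal(d$n_volumes, 125L)
  expect_equal(sum(d$boxcar), 60)                      # 6 x (30 s / 3 s)
  expect_equal(d$boxcar[1:5], rep(0, 5))               # 15 s dead time
  expect_equal(max(d$regressor), 1)                    # peak-normalized

  r <- make_design("rest", tr = 3, n_volumes = 305)
  expect_equal(r$n_volumes, 305L)
  expect_true(all(r$regressor == 0))

  expect_error(make_design("block", tr = 3, n_volumes = 100), "inconsistent")
  expect_error(make_design("block", tr = 3, dead_time = 14), "multiples")
})

test_that("noise-free zero-amplitude simulation is constant baseline", {
  atlas <- small_atlas()
  design <- make_design("rest", tr = 3, n_volumes = 20)
  s <- simulate_subject(atlas, design, "control",
                        effect = effect_spec(noise_sd = 0, amplitude = 0,
                                             baseline = 100),
                        seed = 1)
  vals <- s$data[rep(atlas$brain_mask, 20)]
  expect_true(all(vals == 100))
  expect_true(all(s$data[rep(!atlas$brain_mask, 20)] == 0))
})

test_that("simulation is a deterministic function of the seed", {
  atlas <- small_atlas()
  design <- make_design("rest", tr = 3, n_volumes = 12)
  s1 <- simulate_subject(atlas, design, "injured", seed = 7)
  s2 <- simulate_subject(atlas, design, "injured", seed = 7)
  s3 <- simulate_subject(atlas, design, "injured", seed = 8)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
})

test_that("planted attenuation factor is recovered from task-regressor betas", {
  atlas <- small_atlas()
  design <- make_design("block", tr = 3, dead_time = 15, block_on = 30,
                        block_off = 30, n_cycles = 2)
  eff <- effect_spec(attenuated = c(VIS1 = 0.3), amplitude_jitter = 0.05)
  reg <- design$regressor

  beta_in_vis1 <- function(group, seed) {
    s <- simulate_subject(atlas, design, group, effect = eff, seed = seed)
    m <- to_voxel_matrix(s, structure_mask(atlas, "VIS1"))$matrix
    # least-squares slope of each voxel on the known regressor, averaged
    mean(apply(m, 1, function(v) cov(v, reg) / var(reg)))
  }
  bc <- mean(vapply(1:6, function(i) beta_in_vis1("control", 100 + i), numeric(1)))
  bi <- mean(vapply(1:6, function(i) beta_in_vis1("injured", 200 + i), numeric(1)))
  expect_equal(bi / bc, 0.3, tolerance = 0.2)
})

test_that("resting latent fluctuations are band-limited below 0.1 Hz", {
  atlas <- small_atlas()
  design <- make_design("rest", tr = 3, n_volumes = 65)
  s <- simulate_subject(atlas, design, "control",
                        effect = effect_spec(noise_sd = 0), seed = 9)
  co <- arrayInd(which(structure_mask(atlas, "VIS1"))[1], atlas$dims)
  x <- s$data[co[1], co[2], co[3], ]
  x <- residuals(lm(x ~ seq_along(x)))
  pw <- Mod(fft(x))^2
  n <- length(x)
  fr <- (0:(n - 1)) / (n * 3)
  fr <- pmin(fr, 1 / 3 - fr)
  frac_low <- sum(pw[fr > 0 & fr < 0.1]) / sum(pw[fr > 0])
  expect_gt(frac_low, 0.8)
})

test_that("effect specifications are validated", {
  expect_error(effect_spec(attenuated = c(VIS1 = 1.2)), "\\[0, 1\\)")
  expect_error(effect_spec(attenuated = c(VIS1 = 0.5), elevated = c(VIS1 = 2)),
               "disjoint")
  expect_error(effect_spec(ar1 = 1), "ar1")
  atlas <- small_atlas()
  design <- make_design("rest", tr = 3, n_volumes = 10)
  expect_error(
    simulate_subject(atlas, design, "injured",
                     effect = effect_spec(attenuated = c(NOPE = 0.5))),
    "unknown in atlas")
})

test_that("BOLD and atlas NIfTI round-trips preserve data, tr and labels", {
  dir <- withr::local_tempdir()
  s <- tiny_series(10, dims = c(8L, 8L, 4L), id = "roundtrip", seed = 3)
  p <- file.path(dir, "run.nii.gz")
  write_bold(s, p)
  s2 <- read_bold(p)
  expect_lt(max(abs(s2$data - s$data)), 1e-6)
  expect_equal(s2$tr, s$tr)
  expect_equal(s2$subject_id, "roundtrip")
  expect_identical(dim(s2$data), dim(s$data))

  atlas <- small_atlas()
  pa <- file.path(dir, "atlas.nii.gz")
  write_atlas(atlas, pa)
  a2 <- read_atlas(pa)
  expect_identical(a2$labels, atlas$labels)
  expect_identical(a2$brain_mask, atlas$brain_mask)
  expect_equal(as.data.frame(a2$structures), as.data.frame(atlas$structures))

  # reading a 3D file as a BOLD series is a dimensionality error
  expect_error(read_bold(pa), "4D")
})
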