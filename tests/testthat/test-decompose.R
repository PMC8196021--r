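test_that("single-atom sparse coding matches the soft-threshold closed form", {
  withr::local_seed(1)
  for (lambda in c(0, 0.1, 0.5, 2)) {
    d <- rnorm(20); d <- d / sqrt(sum(d^2))
    s <- rnorm(20)
    sc <- sparse_code(matrix(s, 1), matrix(d), lambda)
    z <- sum(d * s)
    expect_equal(sc$maps[1, 1], sign(z) * max(abs(z) - lambda, 0),
                 tolerance = 1e-10)
  }
})

test_that("sparse coding returns the all-zero solution for large lambda", {
  withr::local_seed(2)
  D <- matrix(rnorm(30 * 4), 30, 4)
  D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  S <- matrix(rnorm(10 * 30), 10, 30)
  lam <- max(abs(crossprod(D, t(S)))) * 1.01
  sc <- sparse_code(S, D, lam)
  expect_true(all(sc$maps == 0))
})

test_that("coordinate descent agrees with an independent proximal-gradient solver", {
  withr::local_seed(3)
  for (rep in 1:20) {
    D <- matrix(rnorm(20 * 5), 20, 5)
    D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
    S <- matrix(rnorm(50 * 20), 50, 20)
    lam <- runif(1, 0.05, 0.5)
    sc <- sparse_code(S, D, lam, tol = 1e-10)
    obj_cd <- sum(attr(sc$objective, "per_voxel"))
    obj_pg <- sum(vapply(seq_len(nrow(S)), function(j) {
      a <- lasso_pg_oracle(S[j, ], D, lam)
      lasso_objective(S[j, ], D, a, lam)
    }, numeric(1)))
    expect_lt(abs(obj_cd - obj_pg) / abs(obj_pg), 1e-6)
  }
})

test_that("coordinate descent agrees with glmnet on random instances", {
  withr::local_seed(4)
  # glmnet solves (1/2n)||s - Da||^2 + lam ||a||_1 on standardized inputs;
  # align scales: lambda_glmnet = lambda / n, no intercept, no standardization
  for (rep in 1:3) {
    n <- 40
    D <- matrix(rnorm(n * 6), n, 6)
    D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
    s <- rnorm(n)
    lam <- 0.2
    sc <- sparse_code(matrix(s, 1), D, lam, tol = 1e-12)
    fit <- glmnet::glmnet(D, s, lambda = lam / n, intercept = FALSE,
                          standardize = FALSE, thresh = 1e-14)
    expect_equal(as.numeric(sc$maps), as.numeric(fit$beta), tolerance = 1e-5)
  }
})

test_that("dictionary learning reaches an exact factorization when one exists", {
  withr::local_seed(5)
  r <- 4
  D0 <- qr.Q(qr(matrix(rnorm(30 * r), 30, r)))
  A0 <- matrix(rnorm(r * 60) * rbinom(r * 60, 1, 0.5), r, 60)
  X <- t(D0 %*% A0)
  fit <- suppressWarnings(sdl_fit(X, n_atoms = r, lambda = 0, max_iter = 30,
                                  tol = 1e-12, seed = 1))
  resid <- X - t(fit$dictionary$atoms %*% fit$maps$maps)
  expect_lt(sqrt(sum(resid^2)), 1e-8)
})

test_that("the dictionary learning objective is non-increasing with unit-norm atoms", {
  withr::local_seed(6)
  for (seed in 1:3) {
    X <- matrix(rnorm(60 * 25), 60, 25)
    fit <- suppressWarnings(sdl_fit(X, n_atoms = 6, lambda = 0.1,
                                    max_iter = 8, seed = seed))
    expect_true(all(diff(fit$objective) <= 1e-8 * max(1, abs(fit$objective[1]))))
    nrm <- sqrt(colSums(fit$dictionary$atoms^2))
    expect_equal(nrm[!fit$dictionary$dead], rep(1, sum(!fit$dictionary$dead)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("group dictionary learning recovers every planted network", {
  gd <- small_rest_group(n = 3, n_volumes = 65, seed0 = 40, scale_voxels = TRUE)
  fit <- suppressWarnings(sdl_fit(gd, n_atoms = 15, lambda = 0.15,
                                  max_iter = 6, seed = 3))
  atlas <- small_atlas()
  bm <- atlas$brain_mask
  for (nw in network_names()) {
    ind <- network_mask(atlas, nw)[bm]
    r <- apply(fit$maps$maps, 1, function(m) suppressWarnings(cor(m, ind)))
    expect_gte(max(r, na.rm = TRUE), 0.5)
  }
})

test_that("dual regression reproduces an exact noiseless model", {
  withr::local_seed(7)
  Ag <- matrix(rnorm(4 * 80), 4, 80)
  Dstar <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))
  X <- t(Dstar %*% Ag)
  dr <- dual_regression(X, Ag, lambda = 0)
  # per component: spatial correlation 1 with the generating maps
  for (k in 1:4) {
    cc <- abs(cor(dr$maps$maps[k, ], t(Ag)))
    expect_equal(max(cc), 1, tolerance = 1e-8)
  }
})

test_that("stage-1 dual regression equals region-mean averaging for an indicator map", {
  withr::local_seed(8)
  V <- 50; Tn <- 30
  X <- matrix(rnorm(V * Tn), V, Tn)
  ind <- c(rep(1, 10), rep(0, 40))
  dr <- dual_regression(X, matrix(ind, 1), lambda = 0)
  d1 <- dr$dictionary$atoms[, 1]
  avg <- colMeans(X[1:10, ])
  expect_equal(d1, avg / sqrt(sum(avg^2)), tolerance = 1e-10)
})

test_that("dual regression zeroes all maps as lambda grows unbounded", {
  withr::local_seed(9)
  X <- matrix(rnorm(30 * 20), 30, 20)
  Ag <- matrix(rnorm(3 * 30), 3, 30)
  dr <- dual_regression(X, Ag, lambda = 1e6)
  expect_true(all(dr$maps$maps == 0))
})

test_that("sparse coding solutions are scale-consistent", {
  withr::local_seed(10)
  D <- matrix(rnorm(20 * 4), 20, 4)
  D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  S <- matrix(rnorm(15 * 20), 15, 20)
  c0 <- 3.7
  a1 <- sparse_code(S, D, 0.2, tol = 1e-10)$maps
  a2 <- sparse_code(c0 * S, D, c0 * 0.2, tol = 1e-10)$maps
  expect_equal(a2, c0 * a1, tolerance = 1e-6)
})

test_that("spatial ICA separates disjoint non-Gaussian sources", {
  withr::local_seed(11)
  V <- 400
  src <- cbind(c(runif(40, 2, 3), rep(0, V - 40)),
               c(rep(0, 200), runif(50, 2, 3), rep(0, V - 250)))
  A <- matrix(c(1.2, -0.4, 0.7, 1.5), 2, 2)
  X <- src %*% t(A)
  X <- cbind(X, X + matrix(rnorm(V * 2, sd = 0.01), V, 2))
  fit <- suppressWarnings(group_ica(X, 2, seed = 5))
  r <- abs(cor(t(fit$maps$maps), src))
  expect_true(all(apply(r, 2, max) >= 0.99))
})

test_that("ICA maps are mutually decorrelated and deterministic under seed", {
  withr::local_seed(12)
  X <- matrix(rnorm(300 * 40), 300, 40)
  f1 <- suppressWarnings(group_ica(X, 5, seed = 2))
  f2 <- suppressWarnings(group_ica(X, 5, seed = 2))
  expect_identical(f1$maps$maps, f2$maps$maps)
  cc <- cor(t(f1$maps$maps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
})

test_that("single-component ICA on rank-1 data recovers the spatial pattern", {
  withr::local_seed(13)
  pat <- c(rep(2, 30), rep(0, 170)) + rnorm(200, sd = 0.05)
  course <- rnorm(12)
  X <- tcrossprod(pat, course)
  fit <- suppressWarnings(group_ica(X, 1, seed = 1))
  expect_gt(abs(cor(fit$maps$maps[1, ], pat)), 0.999)
})

test_that("back-reconstruction degenerates correctly for trivial groups", {
  # single-subject "group": alpha_i equals alpha_g exactly
  s <- tiny_series(30, id = "solo", seed = 20)
  gd <- concatenate_group(list(s))
  fit <- suppressWarnings(group_ica(gd, 3, seed = 4))
  bi <- back_reconstruct(fit, "solo")
  expect_equal(bi$maps, fit$maps$maps, tolerance = 1e-8)

  # identical subjects: every alpha_i equals alpha_g
  runs <- lapply(1:3, function(i) {
    r <- tiny_series(30, id = paste0("s", i), seed = 21)
    r
  })
  gd2 <- concatenate_group(runs)
  fit2 <- suppressWarnings(group_ica(gd2, 3, seed = 4))
  for (sid in c("s1", "s2", "s3")) {
    bi <- back_reconstruct(fit2, sid)
    expect_equal(bi$maps, fit2$maps$maps, tolerance = 1e-6)
  }
})

test_that("back-reconstructed magnitudes track planted subject amplitudes", {
  withr::local_seed(14)
  V <- 300; Tn <- 40
  pat <- c(rep(1, 40), rep(0, V - 40))
  amps <- c(1, 2, 3)
  runs <- lapply(seq_along(amps), function(i) {
    course <- rnorm(Tn)
    data <- tcrossprod(amps[i] * pat, course) + matrix(rnorm(V * Tn, sd = 0.05), V, Tn)
    structure(list(data = array(data, dim = c(V, 1, 1, Tn)), tr = 3,
                   brain_mask = array(TRUE, dim = c(V, 1, 1)),
                   subject_id = paste0("s", i), group = "control"),
              class = "bold_series")
  })
  gd <- concatenate_group(runs)
  fit <- suppressWarnings(group_ica(gd, 2, seed = 6))
  # component matching the pattern
  k <- which.max(abs(cor(t(fit$maps$maps), pat)))
  mag <- vapply(c("s1", "s2", "s3"), function(sid)
    mean(abs(back_reconstruct(fit, sid)$maps[k, pat > 0])), numeric(1))
  expect_equal(order(mag), c(1, 2, 3), ignore_attr = TRUE)
})
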