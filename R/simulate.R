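#' Injury effect specification for the phantom
#'
#' Encodes the disruption/compensation pattern of the injured group as
#' multiplicative factors on BOLD fluctuation amplitude: attenuated
#' structures (factor in \[0, 1)) model hypoactivation of damaged areas and
#' elevated structures (factor > 1) model compensating areas. Controls always
#' use factor 1.
#'
#' @param attenuated Named numeric vector `structure -> factor` in \[0, 1).
#' @param elevated Named numeric vector `structure -> factor` > 1.
#' @param noise_sd SD of the additive AR(1) Gaussian voxel noise (signal units).
#' @param ar1 Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param amplitude_jitter SD of the per-subject log-normal amplitude spread.
#' @param baseline Constant baseline signal added to all in-brain voxels.
#' @param amplitude Network fluctuation amplitude for an unaffected structure,
#'   in the same units as `noise_sd`.
#' @param fluctuation Amplitude of the residual band-limited fluctuation added
#'   to task latent courses.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(attenuated = numeric(), elevated = numeric(),
                        noise_sd = 1, ar1 = 0.3, amplitude_jitter = 0.1,
                        baseline = 100, amplitude = 1, fluctuation = 0.2) {
  if (length(attenuated) && (is.null(names(attenuated)) || any(attenuated < 0 | attenuated >= 1)))
    abort("`attenuated` must be a named vector with factors in [0, 1).")
  if (length(elevated) && (is.null(names(elevated)) || any(elevated <= 1)))
    abort("`elevated` must be a named vector with factors > 1.")
  if (length(intersect(names(attenuated), names(elevated))))
    abort("`attenuated` and `elevated` structure sets must be disjoint.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must be in [0, 1).")
  structure(
    list(attenuated = attenuated, elevated = elevated, noise_sd = noise_sd,
         ar1 = ar1, amplitude_jitter = amplitude_jitter, baseline = baseline,
         amplitude = amplitude, fluctuation = fluctuation),
    class = "effect_spec"
  )
}

# Gaussian noise band-limited to [f_lo, f_hi] Hz at sampling interval tr,
# standardized to unit SD. Keeps at least one positive-frequency bin.
band_limited_noise <- function(n, tr, f_lo = 0.01, f_hi = 0.1) {
  x <- rnorm(n)
  xf <- fft(x)
  freq <- seq(0, n - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)  # two-sided
  keep <- freq >= f_lo & freq <= f_hi
  if (!any(keep)) {
    pos <- freq > 0
    keep <- pos & abs(freq - f_hi) == min(abs(freq[pos] - f_hi))
  }
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y <- y / s
  y
}

# AR(1) noise matrix (rows = voxels) with marginal SD `sd` and lag-1
# autocorrelation `phi`.
ar1_noise <- function(n_voxels, n_time, sd = 1, phi = 0.3) {
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(rnorm(n_voxels * n_time, sd = innov_sd), n_voxels, n_time)
  if (phi != 0 && n_time > 1) {
    e[, 1] <- e[, 1] / sqrt(1 - phi^2)  # stationary start
    for (t in 2:n_time) e[, t] <- e[, t] + phi * e[, t - 1]
  } else if (phi != 0) {
    e[, 1] <- e[, 1] / sqrt(1 - phi^2)
  }
  e
}

#' Simulate one subject's 4D BOLD run
#'
#' Each network carries one shared latent time course: band-limited
#' (0.01–0.1 Hz) Gaussian fluctuation at rest, or the design regressor plus a
#' small band-limited fluctuation for networks driven by a block task. A
#' voxel in structure `s` of network `k` records
#' `baseline + amplitude * jitter * factor_s * latent_k(t) + AR(1) noise`;
#' in-brain voxels outside any structure record baseline plus noise.
#' Injured subjects apply the `effect_spec` factors; controls use factor 1.
#' Deterministic for a fixed seed.
#'
#' @param atlas An `atlas_set`.
#' @param design A `stimulus_design`.
#' @param group `"control"` or `"injured"`.
#' @param effect An `effect_spec`.
#' @param seed Integer seed.
#' @param subject_id Optional identifier stored with the run.
#' @param task_networks For a block design, the networks whose latent course
#'   is the task regressor; all other networks fluctuate as at rest. Defaults
#'   to all networks.
#' @return A `bold_series`: list with `data` (4D array), `tr`, `brain_mask`,
#'   `subject_id` and `group`.
#' @export
simulate_subject <- function(atlas, design, group = c("control", "injured"),
                             effect = effect_spec(), seed = 1L,
                             subject_id = NULL, task_networks = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(atlas, "atlas_set"), inherits(design, "stimulus_design"))
  nt <- design$n_volumes
  tr <- design$tr
  nets <- network_names()
  if (design$paradigm == "block" && is.null(task_networks)) task_networks <- nets

  bad <- setdiff(c(names(effect$attenuated), names(effect$elevated)),
                 atlas$structures$structure)
  if (length(bad)) abort(sprintf("effect names unknown in atlas: %s",
                                 paste(bad, collapse = ", ")))

  vox <- which(atlas$brain_mask)
  V <- length(vox)
  lab_in <- atlas$labels[vox]

  M <- withr::with_seed(seed, {
    latents <- lapply(nets, function(k) {
      if (design$paradigm == "block" && k %in% task_networks) {
        design$regressor + effect$fluctuation * band_limited_noise(nt, tr)
      } else {
        band_limited_noise(nt, tr)
      }
    })
    names(latents) <- nets
    jit <- exp(rnorm(1, 0, effect$amplitude_jitter))

    M <- matrix(effect$baseline, V, nt)
    if (effect$noise_sd > 0)
      M <- M + ar1_noise(V, nt, sd = effect$noise_sd, phi = effect$ar1)

    for (i in seq_len(nrow(atlas$structures))) {
      st <- atlas$structures$structure[i]
      net <- atlas$structures$network[i]
      rows <- which(lab_in == atlas$structures$label[i])
      if (!length(rows)) next
      fac <- 1
      if (group == "injured") {
        if (st %in% names(effect$attenuated)) fac <- effect$attenuated[[st]]
        if (st %in% names(effect$elevated)) fac <- effect$elevated[[st]]
      }
      a <- effect$amplitude * jit * fac
      if (a != 0)
        M[rows, ] <- M[rows, ] + tcrossprod(rep(a, length(rows)), latents[[net]])
    }
    M
  })

  data <- array(0, dim = c(atlas$dims, nt))
  step <- prod(atlas$dims)
  for (t in seq_len(nt)) data[vox + (t - 1L) * step] <- M[, t]

  structure(
    list(data = data, tr = tr, brain_mask = atlas$brain_mask,
         subject_id = subject_id %||% paste0(substr(group, 1, 1), seed),
         group = group),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_series> ", x$subject_id, " (", x$group, "): ",
      paste(d[1:3], collapse = " x "), " x ", d[4], " volumes, tr = ",
      x$tr, " s\n", sep = "")
  invisible(x)
}
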