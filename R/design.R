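#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style kernel: a gamma response with delay 6 s minus an undershoot with
#' delay 16 s at ratio 1/6, i.e. `dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6`.
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t` (unnormalized).
#' @export
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' Build a stimulus design
#'
#' A resting design carries an all-zero regressor. A block design is a boxcar
#' (0 during dead time and OFF blocks, 1 during ON blocks) convolved with the
#' canonical double-gamma HRF sampled at the repetition time, truncated to the
#' run length and peak-normalized to 1.
#'
#' @param paradigm `"rest"` or `"block"`.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes. Required for `"rest"`; for `"block"` it
#'   is derived from the timing and, if supplied, must agree with it.
#' @param dead_time Initial stimulus-off period in seconds (block only).
#' @param block_on,block_off ON/OFF block durations in seconds.
#' @param n_cycles Number of ON/OFF cycles.
#' @return A `stimulus_design`: list with `paradigm`, `tr`, `n_volumes`,
#'   `boxcar` (pre-convolution, per volume) and `regressor`.
#' @examples
#' d <- make_design("block", tr = 3, dead_time = 15, block_on = 30,
#'                  block_off = 30, n_cycles = 6)
#' d$n_volumes  # 125
#' @export
make_design <- function(paradigm = c("rest", "block"), tr, n_volumes = NULL,
                        dead_time = 15, block_on = 30, block_off = 30,
                        n_cycles = 6) {
  paradigm <- match.arg(paradigm)
  if (tr <= 0) abort("`tr` must be positive.")

  if (paradigm == "rest") {
    if (is.null(n_volumes)) abort("`n_volumes` is required for a rest design.")
    return(structure(
      list(paradigm = "rest", tr = tr, n_volumes = as.integer(n_volumes),
           boxcar = numeric(n_volumes), regressor = numeric(n_volumes)),
      class = "stimulus_design"
    ))
  }

  is_mult <- function(x) abs(x / tr - round(x / tr)) < 1e-9
  if (!is_mult(dead_time) || !is_mult(block_on) || !is_mult(block_off))
    abort("`dead_time`, `block_on` and `block_off` must be integer multiples of `tr`.")

  total_s <- dead_time + n_cycles * (block_on + block_off)
  nv <- as.integer(round(total_s / tr))
  if (!is.null(n_volumes) && as.integer(n_volumes) != nv)
    abort(sprintf(
      "inconsistent design: dead_time + n_cycles*(on+off) = %gs is %d volumes at tr = %gs, not %d",
      total_s, nv, tr, as.integer(n_volumes)))

  t0 <- (seq_len(nv) - 1L) * tr  # volume onset times
  rel <- (t0 - dead_time) %% (block_on + block_off)
  boxcar <- as.numeric(t0 >= dead_time & rel < block_on)

  h <- hrf_double_gamma(seq(0, 32, by = tr))
  reg <- convolve(boxcar, rev(h), type = "open")[seq_len(nv)]
  if (max(reg) > 0) reg <- reg / max(reg)

  structure(
    list(paradigm = "block", tr = tr, n_volumes = nv,
         boxcar = boxcar, regressor = reg),
    class = "stimulus_design"
  )
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("<stimulus_design> ", x$paradigm, ", tr = ", x$tr, " s, ",
      x$n_volumes, " volumes\n", sep = "")
  invisible(x)
}
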