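#' Tidy a sparse dictionary learning fit
#'
#' One row per dictionary atom: how many voxels load on it and how strongly.
#'
#' @param x An `sdl_fit`.
#' @param ... Unused.
#' @return Tibble with `component`, `n_active_voxels`, `frac_active`,
#'   `max_abs_weight`.
#' @export
tidy.sdl_fit <- function(x, ...) {
  A <- x$maps$maps
  tibble(
    component = seq_len(nrow(A)),
    n_active_voxels = rowSums(A != 0),
    frac_active = rowMeans(A != 0),
    max_abs_weight = apply(abs(A), 1, max)
  )
}

#' @rdname tidy.sdl_fit
#' @export
glance.sdl_fit <- function(x, ...) {
  tibble(n_atoms = x$n_atoms, lambda = x$lambda, iterations = x$iterations,
         objective = x$objective[x$iterations], converged = x$converged)
}

#' Tidy a group ICA fit
#'
#' One row per component with simple map summaries (excess kurtosis is the
#' usual non-Gaussianity gauge for spatial components).
#'
#' @param x A `group_ica`.
#' @param ... Unused.
#' @return Tibble with `component`, `kurtosis`, `max_abs_weight`.
#' @export
tidy.group_ica <- function(x, ...) {
  S <- x$maps$maps
  kurt <- apply(S, 1, function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3)
  tibble(component = seq_len(nrow(S)), kurtosis = kurt,
         max_abs_weight = apply(abs(S), 1, max))
}

#' @rdname tidy.group_ica
#' @export
glance.group_ica <- function(x, ...) {
  tibble(n_components = x$n_components, iterations = x$iterations,
         converged = x$converged)
}

#' Tidy a permutation field
#'
#' @param x A `permutation_field`.
#' @param ... Unused.
#' @return Tibble with one row per direction: flagged voxel counts and
#'   fractions.
#' @export
tidy.permutation_field <- function(x, ...) {
  n <- length(x$t_actual)
  tibble(direction = c("decrease", "increase"),
         n_flagged = c(sum(x$decrease), sum(x$increase)),
         fraction = c(mean(x$decrease), mean(x$increase)))
}

#' @rdname tidy.permutation_field
#' @export
glance.permutation_field <- function(x, ...) {
  tibble(n_voxels = length(x$t_actual), n_permutations = x$n_permutations,
         alpha = x$alpha, n_control = x$n_control, n_injured = x$n_injured,
         min_p = 1 / x$n_permutations)
}

#' Objective trace of a dictionary learning fit
#'
#' @param object An `sdl_fit`.
#' @param ... Unused.
#' @return A ggplot of the (non-increasing) objective per outer iteration.
#' @export
autoplot.sdl_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective),
               objective = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "outer iteration", y = "sparse coding objective") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-region permutation percentages
#'
#' Blue bars: percentage of significantly decreasing voxels (injured below
#' control); red bars: significantly increasing.
#'
#' @param percentages Tibble from [region_percentages()] (a `paradigm` column
#'   is used for faceting when present).
#' @return A ggplot.
#' @export
plot_region_percentages <- function(percentages) {
  long <- tidyr::pivot_longer(percentages,
                              c("pct_decreasing", "pct_increasing"),
                              names_to = "direction", values_to = "pct")
  long$direction <- ifelse(long$direction == "pct_decreasing",
                           "decrease", "increase")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$pct,
                                          fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(decrease = "#2166ac",
                                          increase = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "% significantly different voxels") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("paradigm" %in% names(percentages))
    p <- p + ggplot2::facet_wrap(~paradigm, scales = "free_x")
  p
}

#' Boxplots of atlas metrics by group
#'
#' @param metrics Metric records with a `group` column, as produced by the
#'   pipeline.
#' @param metric `"pearson_r"` or `"mean_ratio"`.
#' @return A ggplot faceted by region.
#' @export
plot_metric_boxplots <- function(metrics, metric = c("pearson_r", "mean_ratio")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(metrics,
                  ggplot2::aes(.data$group, .data[[metric]], fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
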