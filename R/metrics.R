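#' Normalize by group maximum and threshold at a map z-score
#'
#' Divides every map by the maximum absolute group activation value of the
#' corresponding group fit, converts each map to voxelwise z-scores over the
#' in-brain voxel population (population SD), and zeroes voxels with
#' `z < z_cut`; surviving voxels keep their normalized value. A constant map
#' (zero SD) is zeroed entirely with a warning.
#'
#' @param maps A raw `spatial_map_set` (or k-by-voxels matrix).
#' @param group_max Positive scalar, `max(abs(alpha_g))` of the group fit;
#'   see [group_max()].
#' @param z_cut Z-score threshold (default 1).
#' @return The thresholded `spatial_map_set`.
#' @export
normalize_and_threshold <- function(maps, group_max, z_cut = 1) {
  M <- if (inherits(maps, "spatial_map_set")) maps$maps else as.matrix(maps)
  if (!is.numeric(group_max) || group_max <= 0) abort("`group_max` must be > 0.")
  M <- M / group_max
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    v <- M[i, ]
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) {
      warn(sprintf("map %d is constant; thresholded to all zeros", i))
      next
    }
    z <- (v - mean(v)) / s
    keep <- z >= z_cut
    out[i, keep] <- v[keep]
  }
  if (inherits(maps, "spatial_map_set")) {
    maps$maps <- out
    maps$state <- "thresholded"
    maps
  } else {
    new_spatial_map_set(out, method = "sdl", state = "thresholded")
  }
}

#' Maximum absolute group activation value of a fit
#' @param fit An `sdl_fit` or `group_ica`.
#' @return Scalar `max(abs(alpha_g))`.
#' @export
group_max <- function(fit) {
  stopifnot(inherits(fit, "sdl_fit") || inherits(fit, "group_ica"))
  max(abs(fit$maps$maps))
}

#' Pearson spatial correlation between a map and a reference atlas
#'
#' Correlates the map values with the 0/1 atlas indicator across in-brain
#' voxels. Undefined (NA) when either side has zero variance.
#'
#' @param map Numeric vector of map values over the in-brain voxels, or a 3D
#'   volume (then both masks must be 3D).
#' @param atlas_mask Logical atlas membership, same raster as `map`.
#' @param brain_mask Optional logical brain mask used to restrict 3D inputs.
#' @return Pearson r, or `NA_real_` when undefined.
#' @export
pearson_to_atlas <- function(map, atlas_mask, brain_mask = NULL) {
  if (!is.null(dim(map)) && length(dim(map)) == 3L && !is.null(brain_mask)) {
    map <- map[brain_mask]
    atlas_mask <- atlas_mask[brain_mask]
  }
  ind <- as.numeric(atlas_mask)
  if (sd(map) == 0 || sd(ind) == 0) return(NA_real_)
  cor(map, ind)
}

#' Mean ratio of a map with respect to a reference atlas
#'
#' Mean activation inside the atlas divided by the mean activation outside it
#' (within brain). Undefined (NA) when the outside mean is zero.
#'
#' @inheritParams pearson_to_atlas
#' @return The ratio, or `NA_real_` when undefined.
#' @export
mean_ratio <- function(map, atlas_mask, brain_mask = NULL) {
  if (!is.null(dim(map)) && length(dim(map)) == 3L && !is.null(brain_mask)) {
    map <- map[brain_mask]
    atlas_mask <- atlas_mask[brain_mask]
  }
  atlas_mask <- as.logical(atlas_mask)
  if (!any(atlas_mask) || all(atlas_mask))
    abort("atlas mask must be a proper non-empty subset of the brain.")
  outside <- mean(map[!atlas_mask])
  if (outside == 0) return(NA_real_)
  mean(map[atlas_mask]) / outside
}

#' Select the maximal activation map for one reference atlas
#'
#' ICA keeps the single component whose thresholded map has the largest
#' Pearson correlation with the atlas indicator. Sparse dictionary learning
#' averages the three distinct top-Pearson maps (atoms) and recomputes both
#' metrics on the averaged map. Ties break to the lowest component index.
#'
#' @param maps A thresholded `spatial_map_set` for one subject and dataset.
#' @param atlas_mask Logical network atlas over the same voxel raster
#'   (vector over in-brain voxels, or 3D with `brain_mask`).
#' @param method `"ica"` or `"sdl"`.
#' @param brain_mask Optional 3D brain mask for 3D inputs.
#' @return List with `map` (final map over in-brain voxels), `pearson_r`,
#'   `mean_ratio`, and `components` (indices used).
#' @export
select_maximal_map <- function(maps, atlas_mask, method = c("ica", "sdl"),
                               brain_mask = NULL) {
  method <- match.arg(method)
  M <- if (inherits(maps, "spatial_map_set")) maps$maps else as.matrix(maps)
  if (!is.null(dim(atlas_mask)) && length(dim(atlas_mask)) == 3L) {
    bm <- brain_mask %||% array(TRUE, dim = dim(atlas_mask))
    atlas_mask <- atlas_mask[bm]
  }
  ind <- as.numeric(atlas_mask)
  k <- nrow(M)
  if (method == "sdl" && k < 3L)
    abort("sDL maximal-map selection needs at least 3 maps.")
  r <- vapply(seq_len(k), function(i) {
    ri <- pearson_to_atlas(M[i, ], ind)
    if (is.na(ri)) -Inf else ri
  }, numeric(1))

  ord <- order(-r, seq_len(k))
  if (method == "ica") {
    sel <- ord[1]
    fin <- M[sel, ]
  } else {
    sel <- ord[1:3]
    fin <- colMeans(M[sel, , drop = FALSE])
  }
  list(map = fin,
       pearson_r = pearson_to_atlas(fin, ind),
       mean_ratio = mean_ratio(fin, as.logical(atlas_mask)),
       components = sel)
}

#' Per-structure and network-level metrics from a final map
#'
#' Computes Pearson r and the mean ratio of the final map against the network
#' atlas and against every member structure. The cerebellar network is
#' reported at network level only.
#'
#' @param final_map Final activation map over in-brain voxels (vector).
#' @param atlas An `atlas_set`.
#' @param network Network identifier.
#' @param subject_id,method,paradigm Metadata recorded in the output.
#' @return A tibble of metric records: one row per region (network first).
#' @export
structure_metrics <- function(final_map, atlas, network, subject_id = NA_character_,
                              method = NA_character_, paradigm = NA_character_) {
  bm <- atlas$brain_mask
  rec <- function(region, region_type, mask3d) {
    tibble(subject_id = subject_id, method = method, paradigm = paradigm,
           network = network, region = region, region_type = region_type,
           pearson_r = pearson_to_atlas(final_map, mask3d[bm]),
           mean_ratio = mean_ratio(final_map, mask3d[bm]))
  }
  out <- list(rec(network, "network", network_mask(atlas, network)))
  if (network != "CERE") {
    members <- atlas$structures$structure[atlas$structures$network == network]
    for (st in members)
      out <- c(out, list(rec(st, "structure", structure_mask(atlas, st))))
  }
  dplyr::bind_rows(out)
}

#' Welch two-sample test between control and injured metric values
#'
#' Two-sided two-sample t-test assuming unequal variances
#' (Welch–Satterthwaite degrees of freedom); the statistic is
#' `(mean_control - mean_injured) / se`. Undefined metric values are dropped
#' (count reported); with fewer than two remaining values per group the test
#' is skipped and the p-value is NA. Degenerate zero-variance inputs are
#' guarded by a 1e-12 variance floor.
#'
#' @param control_values,injured_values Numeric vectors (NAs allowed).
#' @return One-row tibble: `t`, `df`, `p_value`, `direction` (`"decrease"`
#'   when the injured mean is below the control mean), `n_control`,
#'   `n_injured`, `n_dropped`.
#' @export
welch_test <- function(control_values, injured_values) {
  nc0 <- length(control_values); ni0 <- length(injured_values)
  x <- control_values[is.finite(control_values)]
  y <- injured_values[is.finite(injured_values)]
  dropped <- nc0 + ni0 - length(x) - length(y)
  if (length(x) < 2L || length(y) < 2L)
    return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                  direction = NA_character_, n_control = length(x),
                  n_injured = length(y), n_dropped = dropped))

  res <- tryCatch(
    t.test(x, y, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # zero-variance fallback with an epsilon variance floor
    vx <- max(var(x), 1e-12); vy <- max(var(y), 1e-12)
    se <- sqrt(vx / length(x) + vy / length(y))
    tt <- (mean(x) - mean(y)) / se
    df <- (vx / length(x) + vy / length(y))^2 /
      ((vx / length(x))^2 / (length(x) - 1) + (vy / length(y))^2 / (length(y) - 1))
    p <- 2 * pt(-abs(tt), df)
    res <- list(statistic = tt, parameter = df, p.value = p)
  }
  tibble(
    t = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value,
    direction = if (mean(y) < mean(x)) "decrease" else "increase",
    n_control = length(x), n_injured = length(y), n_dropped = dropped
  )
}

#' Group comparison of atlas metrics with the dual-metric rule
#'
#' For every region (and method/paradigm stratum) runs [welch_test()] on the
#' Pearson correlations and on the mean ratios across subjects. A region is
#' significant only when both metrics have p < `alpha` and their directions
#' agree.
#'
#' @param metrics Tibble of metric records from [structure_metrics()] with a
#'   `group` column (`"control"` / `"injured"`).
#' @param alpha Per-metric significance level (default 0.05).
#' @return Tibble with one row per (stratum, region, metric): test results
#'   plus the region-level `significant_region` flag and its direction.
#' @export
group_metric_tests <- function(metrics, alpha = 0.05) {
  stopifnot(all(c("group", "region", "pearson_r", "mean_ratio") %in% names(metrics)))
  strata <- intersect(c("method", "paradigm", "network"), names(metrics))
  nested <- dplyr::group_split(dplyr::group_by(
    metrics, dplyr::across(dplyr::all_of(c(strata, "region", "region_type")))))

  out <- purrr::map(nested, function(df) {
    ctrl <- df[df$group == "control", ]
    inj <- df[df$group == "injured", ]
    res <- dplyr::bind_rows(
      dplyr::mutate(welch_test(ctrl$pearson_r, inj$pearson_r), metric = "pearson"),
      dplyr::mutate(welch_test(ctrl$mean_ratio, inj$mean_ratio), metric = "mean_ratio")
    )
    sig <- all(!is.na(res$p_value)) && all(res$p_value < alpha) &&
      length(unique(res$direction)) == 1L
    meta <- df[1, c(strata, "region", "region_type"), drop = FALSE]
    dplyr::bind_cols(meta[rep(1, nrow(res)), ], res,
                     tibble(significant_region = sig,
                            region_direction = if (sig) res$direction[1] else NA_character_))
  })
  dplyr::bind_rows(out)
}
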