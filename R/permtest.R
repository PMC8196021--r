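#' Enumerate all two-group assignments
#'
#' All distinct ways of splitting `n_control + n_injured` subjects into
#' pseudo-groups of the original sizes, in deterministic lexicographic order.
#' The first assignment is the true labeling (subjects `1..n_control` as
#' controls).
#'
#' @param n_control,n_injured Group sizes, each >= 1.
#' @return List with `assignments` (`n_control` x `n_permutations` matrix of
#'   control-subject indices, one column per assignment) and
#'   `n_permutations` = `choose(n_control + n_injured, n_control)`.
#' @examples
#' enumerate_assignments(7, 5)$n_permutations  # 792
#' @export
enumerate_assignments <- function(n_control, n_injured) {
  stopifnot(n_control >= 1, n_injured >= 1)
  a <- combn(n_control + n_injured, n_control)
  list(assignments = a, n_permutations = ncol(a))
}

#' Exhaustive voxelwise two-group permutation test
#'
#' For every voxel, computes `T = mean_control - mean_injured` under every
#' possible assignment of the subjects into pseudo-groups of the original
#' sizes. A voxel is flagged *decrease* (injured below control) when the
#' one-sided rank p-value `#\{T_perm >= T_actual\} / n_permutations` is at
#' most `alpha`, and *increase* when `#\{T_perm <= T_actual\} /
#' n_permutations <= alpha`. The true assignment is included in the
#' reference set and ties count against rejection, so p >= 1/n_permutations
#' everywhere. No multiple-comparison correction is applied.
#'
#' @param control_maps,injured_maps Voxels-by-subject matrices (or lists of
#'   per-subject map vectors) on a shared raster.
#' @param alpha Significance level (default 0.05).
#' @param voxel_index,dims Optional raster bookkeeping for export.
#' @return A `permutation_field`: list with `t_actual`, `decrease`,
#'   `increase` (per-voxel), `n_permutations`, `alpha`, group sizes and
#'   raster info.
#' @export
voxelwise_permutation <- function(control_maps, injured_maps, alpha = 0.05,
                                  voxel_index = NULL, dims = NULL) {
  as_mat <- function(x) if (is.list(x)) do.call(cbind, x) else as.matrix(x)
  Mc <- as_mat(control_maps); Mi <- as_mat(injured_maps)
  if (nrow(Mc) != nrow(Mi))
    abort("control and injured maps do not share a voxel raster.")
  nc <- ncol(Mc); ni <- ncol(Mi)
  stopifnot(nc >= 1, ni >= 1)
  M <- cbind(Mc, Mi)
  N <- nc + ni

  en <- enumerate_assignments(nc, ni)
  P <- en$n_permutations
  W <- matrix(-1 / ni, N, P)
  for (p in seq_len(P)) W[en$assignments[, p], p] <- 1 / nc

  Tall <- M %*% W
  t_actual <- Tall[, 1]
  # ties (including floating-point near-ties) count against rejection
  eps <- 1e-8 * pmax(apply(abs(M), 1, max), .Machine$double.eps)
  p_minus <- rowSums(Tall >= t_actual - eps) / P
  p_plus <- rowSums(Tall <= t_actual + eps) / P

  structure(
    list(t_actual = t_actual,
         decrease = p_minus <= alpha,
         increase = p_plus <= alpha,
         p_decrease = p_minus, p_increase = p_plus,
         n_permutations = P, alpha = alpha,
         n_control = nc, n_injured = ni,
         voxel_index = voxel_index, dims = dims),
    class = "permutation_field"
  )
}

#' @export
print.permutation_field <- function(x, ...) {
  cat("<permutation_field> ", length(x$t_actual), " voxels, ",
      x$n_permutations, " permutations (", x$n_control, " vs ",
      x$n_injured, "), alpha = ", x$alpha, "\n  flagged: ",
      sum(x$decrease), " decrease, ", sum(x$increase), " increase\n", sep = "")
  invisible(x)
}

#' Percentages of significantly different voxels per region
#'
#' For every network and member structure of the atlas: 100 x flagged voxels
#' / region voxels, separately for the decrease and increase directions.
#'
#' @param field A `permutation_field` computed over the atlas' in-brain
#'   voxels (its `voxel_index` must match the atlas raster, or the field must
#'   cover `which(atlas$brain_mask)`).
#' @param atlas An `atlas_set`.
#' @return Tibble with `network`, `region`, `region_type`, `n_voxels`,
#'   `pct_decreasing`, `pct_increasing`.
#' @export
region_percentages <- function(field, atlas) {
  stopifnot(inherits(field, "permutation_field"), inherits(atlas, "atlas_set"))
  vi <- field$voxel_index %||% which(atlas$brain_mask)
  if (length(vi) != length(field$t_actual))
    abort("field and atlas do not share a voxel raster.")

  pct <- function(mask3d, network, region, region_type) {
    inreg <- which(vi %in% which(mask3d))
    if (!length(inreg))
      abort(sprintf("region '%s' contains no voxels in the field", region))
    tibble(network = network, region = region, region_type = region_type,
           n_voxels = length(inreg),
           pct_decreasing = 100 * sum(field$decrease[inreg]) / length(inreg),
           pct_increasing = 100 * sum(field$increase[inreg]) / length(inreg))
  }

  out <- list()
  for (net in unique(atlas$structures$network)) {
    out <- c(out, list(pct(network_mask(atlas, net), net, net, "network")))
    for (st in atlas$structures$structure[atlas$structures$network == net])
      out <- c(out, list(pct(structure_mask(atlas, st), net, st, "structure")))
  }
  dplyr::bind_rows(out)
}

#' Export a permutation field as NIfTI overlays
#'
#' Writes a 3-valued label volume (0 = none, 1 = significant decrease,
#' 2 = significant increase) and the actual mean-difference field
#' (`<stem>_tactual.nii.gz`).
#'
#' @param field A `permutation_field` with raster info (`voxel_index`,
#'   `dims`), or pass them explicitly.
#' @param path Output path for the label volume (`.nii` / `.nii.gz`).
#' @param voxel_index,dims Raster bookkeeping overriding the field's own.
#' @return `path`, invisibly.
#' @export
export_permutation_map <- function(field, path, voxel_index = NULL, dims = NULL) {
  stopifnot(inherits(field, "permutation_field"))
  vi <- voxel_index %||% field$voxel_index
  dm <- dims %||% field$dims
  if (is.null(vi) || is.null(dm))
    abort("no voxel raster recorded in the field; pass `voxel_index` and `dims`.")
  lab <- integer(length(field$t_actual))
  lab[field$decrease] <- 1L
  lab[field$increase] <- 2L
  RNifti::writeNifti(RNifti::asNifti(values_to_volume(lab, vi, dm, fill = 0L)),
                     path, datatype = "int16")
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(RNifti::asNifti(values_to_volume(field$t_actual, vi, dm)),
                     paste0(stem, "_tactual.nii.gz"))
  invisible(path)
}
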