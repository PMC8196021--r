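#' Drop initial volumes of a run
#'
#' Removes the first `k` volumes (magnetization equilibration period) from a
#' BOLD run, e.g. 305 -> 300 resting volumes and 125 -> 120 task volumes with
#' the default `k = 5`.
#'
#' @param series A `bold_series`.
#' @param k Number of leading volumes to drop.
#' @return The trimmed `bold_series`.
#' @export
trim_initial_volumes <- function(series, k = 5L) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$data)[4]
  k <- as.integer(k)
  if (k >= nt)
    abort(sprintf("trimming %d volumes would empty a %d-volume series", k, nt))
  if (k > 0L) series$data <- series$data[, , , -(seq_len(k)), drop = FALSE]
  series
}

#' Rasterize a run to a voxel-by-time matrix
#'
#' Rows follow ascending linear index of the mask voxels (first spatial axis
#' fastest, R's native array order); this order is identical for every series
#' sharing the mask and is recorded in `voxel_index` so volumes can be
#' reconstructed exactly.
#'
#' @param series A `bold_series` or a 4D array.
#' @param mask 3D logical mask matching the spatial dimensions. Defaults to
#'   the series' own brain mask.
#' @return List with `matrix` (voxels x time) and `voxel_index` (linear
#'   indices into the 3D grid).
#' @export
to_voxel_matrix <- function(series, mask = NULL) {
  data <- if (inherits(series, "bold_series")) series$data else series
  mask <- mask %||% series$brain_mask
  d <- dim(data)
  if (!identical(dim(mask), d[1:3]))
    abort("`mask` dimensions do not match the series' spatial dimensions.")
  idx <- which(mask)
  if (!length(idx)) abort("`mask` is empty.")
  m <- matrix(data, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  list(matrix = m, voxel_index = idx)
}

#' Embed per-voxel values back into a 3D volume
#'
#' @param values Numeric vector, one value per mask voxel.
#' @param voxel_index Linear indices as returned by [to_voxel_matrix()].
#' @param dims 3D grid dimensions.
#' @param fill Value for voxels outside the mask.
#' @return 3D array.
#' @export
values_to_volume <- function(values, voxel_index, dims, fill = 0) {
  vol <- array(fill, dim = dims)
  vol[voxel_index] <- values
  vol
}

#' Temporally concatenate trimmed runs into a group dataset
#'
#' Stacks the subjects' in-brain voxel-by-time matrices along time in list
#' order, recording each subject's half-open column span. Voxel time series
#' are mean-centered within each subject span by default; per-subject
#' variance normalization is off by default.
#'
#' @param series_list List of trimmed `bold_series` sharing grid and tr.
#' @param mask Shared 3D mask; defaults to the first series' brain mask.
#' @param paradigm Label stored with the dataset
#'   (`"rest"`, `"task_visual"`, `"task_tactile"`).
#' @param group Group label (`"control"` or `"injured"`).
#' @param center Center each voxel's time series within each subject span.
#' @param scale_voxels Additionally scale each voxel's within-subject time
#'   series to unit Euclidean norm (the convention under which the default
#'   sparsity weight `lambda = 0.15` bounds the atom-signal correlation;
#'   zero series are left at zero).
#' @return A `group_dataset`: list with `matrix` (voxels x total time),
#'   `spans` (tibble `subject_id`, `start`, `end`, half-open 0-based),
#'   `voxel_index`, `dims`, `tr`, `paradigm`, `group`.
#' @export
concatenate_group <- function(series_list, mask = NULL, paradigm = "rest",
                              group = "control", center = TRUE,
                              scale_voxels = FALSE) {
  if (!length(series_list)) abort("`series_list` must be non-empty.")
  mask <- mask %||% series_list[[1]]$brain_mask
  d0 <- dim(series_list[[1]]$data)[1:3]
  tr0 <- series_list[[1]]$tr

  blocks <- vector("list", length(series_list))
  spans <- vector("list", length(series_list))
  off <- 0L
  idx <- NULL
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    if (!identical(dim(s$data)[1:3], d0) || !isTRUE(all.equal(s$tr, tr0)))
      abort(sprintf("subject '%s' has mismatched dimensions or tr", s$subject_id))
    vm <- to_voxel_matrix(s, mask)
    idx <- vm$voxel_index
    m <- vm$matrix
    if (center || scale_voxels) {
      mu <- rowMeans(m)
      m <- m - mu
      if (scale_voxels) {
        nrm <- sqrt(rowSums(m^2))
        nrm[nrm == 0] <- 1
        m <- m / nrm
      }
      if (!center) m <- m + mu
    }
    nt <- ncol(m)
    blocks[[i]] <- m
    spans[[i]] <- tibble(subject_id = s$subject_id %||% paste0("s", i),
                         start = off, end = off + nt)
    off <- off + nt
  }

  structure(
    list(matrix = do.call(cbind, blocks), spans = dplyr::bind_rows(spans),
         voxel_index = idx, dims = d0, tr = tr0,
         paradigm = paradigm, group = group),
    class = "group_dataset"
  )
}

#' @export
print.group_dataset <- function(x, ...) {
  cat("<group_dataset> ", x$paradigm, "/", x$group, ": ",
      nrow(x$matrix), " voxels x ", ncol(x$matrix), " volumes (",
      nrow(x$spans), " subjects)\n", sep = "")
  invisible(x)
}

#' Extract one subject's columns from a group dataset
#'
#' @param group A `group_dataset`.
#' @param subject_id Subject identifier recorded in `spans`.
#' @return Voxels-by-time matrix for that subject.
#' @export
extract_subject <- function(group, subject_id) {
  sp <- group$spans[group$spans$subject_id == subject_id, ]
  if (nrow(sp) == 0L)
    abort(sprintf("subject '%s' not found in group dataset", subject_id))
  group$matrix[, (sp$start + 1L):sp$end, drop = FALSE]
}
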