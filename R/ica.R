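#' Group spatial ICA with PCA reduction
#'
#' Reduces the group voxels-by-time matrix to `n_components` temporal
#' principal components and unmixes the reduced spatial data into maximally
#' independent spatial maps by a fixed-point ICA iteration (log-cosh
#' contrast, symmetric decorrelation). Components follow the package sign
#' convention (the voxel of maximum absolute weight is positive) and the fit
#' stores the per-subject reduced data so individual maps can be
#' back-reconstructed.
#'
#' @param group A `group_dataset` (or voxels-by-time matrix).
#' @param n_components Number of components (the field default for such
#'   studies is 70; must not exceed `min(voxels, time)`).
#' @param seed Seed for the random orthonormal initialization.
#' @param tol Convergence tolerance on the unmixing update.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `group_ica`: list with `maps` (k-by-voxels `spatial_map_set`),
#'   `mixing` (time-by-k component time courses), `reduction` (unmixing and
#'   per-subject reduced scores used for back-reconstruction), `converged`,
#'   `iterations`.
#' @export
group_ica <- function(group, n_components, seed = 1L, tol = 1e-6,
                      max_iter = 1000L) {
  vi <- NULL; dm <- NULL; spans <- NULL
  X <- group
  if (inherits(group, "group_dataset")) {
    vi <- group$voxel_index; dm <- group$dims; spans <- group$spans
    X <- group$matrix
  }
  V <- nrow(X); Tn <- ncol(X)
  k <- as.integer(n_components)
  if (k > min(V, Tn))
    abort(sprintf("`n_components` (%d) exceeds min(voxels, time) = %d", k, min(V, Tn)))

  colc <- colMeans(X)
  Xc <- sweep(X, 2, colc)

  # PCA on the smaller side of the matrix
  if (V <= Tn) {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    sv <- sqrt(pmax(eg$values[seq_len(k)], 0))
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    Z <- U %*% diag(sv, k)                      # V x k PCA scores
    E <- crossprod(Xc, U) %*% diag(1 / ifelse(sv > 0, sv, 1), k)  # T x k
  } else {
    eg <- eigen(crossprod(Xc), symmetric = TRUE)
    E <- eg$vectors[, seq_len(k), drop = FALSE]
    Z <- Xc %*% E
    sv <- sqrt(pmax(eg$values[seq_len(k)], 0))
  }
  if (any(sv < 1e-10))
    warn("group_ica: near-zero singular values; data rank below n_components")

  colsd <- sv / sqrt(V)
  colsd[colsd == 0] <- 1
  Zw <- sweep(Z, 2, colsd, `/`)   # whitened spatial data, V x k

  sym_decor <- function(W) {
    e <- eigen(crossprod(W), symmetric = TRUE)
    W %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), ncol(W)) %*% t(e$vectors)
  }

  W <- withr::with_seed(seed, matrix(rnorm(k * k), k, k))
  W <- sym_decor(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U1 <- Zw %*% W          # V x k
    gU <- tanh(U1)
    W1 <- crossprod(Zw, gU) / V - W %*% diag(colMeans(1 - gU^2), k)
    W1 <- sym_decor(W1)
    delta <- max(abs(1 - abs(colSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("group_ica: not converged after %d iterations", it))

  S <- Zw %*% W                     # V x k independent spatial maps (unit cov)
  flip <- apply(S, 2, function(col) {
    f <- sign(col[which.max(abs(col))]); if (f == 0) 1 else f
  })
  S <- sweep(S, 2, flip, `*`)
  mixing <- crossprod(Xc, S) / V    # T x k component time courses

  # back-reconstruction: alpha_i = n_subj * (X_s E_s) G, G = diag(1/sd) W flip
  Gmat <- sweep(diag(1 / colsd, k) %*% W, 2, flip, `*`)
  subject_scores <- NULL
  if (!is.null(spans)) {
    subject_scores <- lapply(seq_len(nrow(spans)), function(i) {
      cols <- (spans$start[i] + 1L):spans$end[i]
      Xc[, cols, drop = FALSE] %*% E[cols, , drop = FALSE]
    })
    names(subject_scores) <- spans$subject_id
  }

  maps <- new_spatial_map_set(t(S), method = "ica", state = "raw",
                              voxel_index = vi, dims = dm)
  structure(
    list(maps = maps, mixing = mixing,
         reduction = list(G = Gmat, subject_scores = subject_scores,
                          n_subjects = if (is.null(spans)) 1L else nrow(spans),
                          spans = spans),
         n_components = k, converged = converged, iterations = it,
         seed = seed),
    class = "group_ica"
  )
}

#' @export
print.group_ica <- function(x, ...) {
  cat("<group_ica> ", x$n_components, " components, ",
      x$iterations, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Back-reconstruct per-subject component maps from a group ICA fit
#'
#' Projects the subject's partition of the reduced group data through the
#' inverse of the group unmixing, scaled by the number of subjects so that a
#' degenerate single-subject "group" reproduces the group maps exactly.
#'
#' @param fit A `group_ica` fitted on a `group_dataset`.
#' @param subject_id Subject identifier recorded in the group dataset spans.
#' @return A `spatial_map_set` of per-subject component maps.
#' @export
back_reconstruct <- function(fit, subject_id) {
  stopifnot(inherits(fit, "group_ica"))
  red <- fit$reduction
  if (is.null(red$subject_scores))
    abort("fit was not computed from a group_dataset; no subject spans stored.")
  Zs <- red$subject_scores[[subject_id]]
  if (is.null(Zs))
    abort(sprintf("subject '%s' not found in the group fit", subject_id))
  Ai <- red$n_subjects * (Zs %*% red$G)
  new_spatial_map_set(t(Ai), method = "ica", state = "raw",
                      subject_id = subject_id,
                      voxel_index = fit$maps$voxel_index, dims = fit$maps$dims)
}
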