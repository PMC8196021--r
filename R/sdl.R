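#' Construct a temporal dictionary
#'
#' @param atoms Time-by-n matrix. Columns are renormalized to unit Euclidean
#'   norm; all-zero columns are flagged dead.
#' @param source `"group"` or `"subject"`.
#' @return A `time_dictionary`.
#' @export
time_dictionary <- function(atoms, source = c("group", "subject")) {
  source <- match.arg(source)
  atoms <- as.matrix(atoms)
  nrm <- sqrt(colSums(atoms^2))
  dead <- nrm == 0
  atoms[, !dead] <- sweep(atoms[, !dead, drop = FALSE], 2, nrm[!dead], `/`)
  structure(list(atoms = atoms, n = ncol(atoms), dead = dead, source = source),
            class = "time_dictionary")
}

#' @export
print.time_dictionary <- function(x, ...) {
  cat("<time_dictionary> ", nrow(x$atoms), " timepoints x ", x$n, " atoms (",
      sum(x$dead), " dead, source: ", x$source, ")\n", sep = "")
  invisible(x)
}

new_spatial_map_set <- function(maps, method, state = "raw", subject_id = NULL,
                                voxel_index = NULL, dims = NULL,
                                objective = NULL) {
  structure(
    list(maps = maps, n_components = nrow(maps), method = method,
         state = state, subject_id = subject_id, voxel_index = voxel_index,
         dims = dims, objective = objective),
    class = "spatial_map_set"
  )
}

#' @export
print.spatial_map_set <- function(x, ...) {
  cat("<spatial_map_set> ", x$n_components, " ", x$method, " maps over ",
      ncol(x$maps), " voxels (", x$state,
      if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Sparse coding of voxel time series against a fixed dictionary
#'
#' Solves, independently for every voxel j, the LASSO problem
#' \deqn{\min_{\alpha_j} \tfrac12 \lVert s_j - D\alpha_j \rVert_2^2 +
#'   \lambda \lVert \alpha_j \rVert_1}
#' by cyclic coordinate descent (soft-thresholding updates against the
#' precomputed Gram matrix), to a coefficient-change tolerance.
#'
#' @param mat Voxels-by-time matrix (or a `group_dataset`).
#' @param dictionary A `time_dictionary` or time-by-n matrix.
#' @param lambda Sparsity weight, >= 0.
#' @param tol Convergence tolerance on the largest coefficient change per sweep.
#' @param max_sweeps Maximum coordinate-descent sweeps per voxel.
#' @return A raw `spatial_map_set` whose `maps` are the n-by-voxels codes;
#'   `objective` holds the summed Eq.-objective over voxels, with the
#'   per-voxel values in attribute `per_voxel`.
#' @export
sparse_code <- function(mat, dictionary, lambda, tol = 1e-6,
                        max_sweeps = 1000L) {
  vi <- NULL; dm <- NULL; sid <- NULL
  if (inherits(mat, "group_dataset")) {
    vi <- mat$voxel_index; dm <- mat$dims; mat <- mat$matrix
  }
  D <- if (inherits(dictionary, "time_dictionary")) dictionary$atoms else as.matrix(dictionary)
  if (!all(is.finite(mat)) || !all(is.finite(D)))
    abort("non-finite values in data or dictionary.")
  if (nrow(D) != ncol(mat))
    abort(sprintf("dictionary time length (%d) does not match data (%d volumes)",
                  nrow(D), ncol(mat)))
  if (lambda < 0) abort("`lambda` must be >= 0.")
  res <- cd_sparse_code(mat, D, lambda, tol, as.integer(max_sweeps))
  obj <- sum(res$objective)
  attr(obj, "per_voxel") <- as.numeric(res$objective)
  new_spatial_map_set(res$codes, method = "sdl", state = "raw",
                      voxel_index = vi, dims = dm, objective = obj)
}

# Flip component signs so the voxel of maximum absolute weight is positive.
# Applied jointly to maps (rows) and the paired time courses (columns) so the
# reconstruction D %*% A is unchanged.
sign_convention <- function(maps, courses = NULL) {
  flip <- apply(maps, 1, function(r) {
    if (all(r == 0)) 1 else sign(r[which.max(abs(r))])
  })
  flip[flip == 0] <- 1
  maps <- maps * flip
  if (!is.null(courses)) courses <- sweep(courses, 2, flip, `*`)
  list(maps = maps, courses = courses)
}

#' Group sparse dictionary learning
#'
#' Alternating minimization of the sparse-coding objective over a unit-norm
#' temporal dictionary: sparse coding of every voxel with the dictionary
#' fixed, then a Gauss–Seidel per-atom least-squares update on the unit
#' sphere (closed form `d_k = E_k a_k / ||E_k a_k||` on the atom's active
#' set). Dead atoms are re-seeded from the worst-reconstructed voxel's
#' residual time course. The objective is recorded after each coding stage
#' and is non-increasing.
#'
#' @param group A `group_dataset` (or voxels-by-time matrix).
#' @param n_atoms Dictionary size; the field default matches the run length
#'   (e.g. 300 resting / 120 task volumes).
#' @param lambda Sparsity weight (default 0.15).
#' @param max_iter Maximum outer iterations.
#' @param tol Relative objective-change stopping tolerance; also the
#'   coordinate-descent tolerance.
#' @param seed Seed for the data-driven dictionary initialization.
#' @return An `sdl_fit`: list with `dictionary` (`time_dictionary`), `maps`
#'   (group codes, a raw `spatial_map_set`), `objective` (per outer
#'   iteration), `lambda`, `n_atoms`, `converged`, `iterations`.
#' @export
sdl_fit <- function(group, n_atoms, lambda = 0.15, max_iter = 15L,
                    tol = 1e-6, seed = 1L) {
  vi <- NULL; dm <- NULL; meta <- NULL
  X <- group
  if (inherits(group, "group_dataset")) {
    vi <- group$voxel_index; dm <- group$dims
    meta <- list(paradigm = group$paradigm, group = group$group)
    X <- group$matrix
  }
  V <- nrow(X); Tn <- ncol(X)
  if (n_atoms < 1) abort("`n_atoms` must be >= 1.")

  D <- withr::with_seed(seed, {
    rows <- sample.int(V, min(n_atoms, V))
    D0 <- t(X[rows, , drop = FALSE])
    if (n_atoms > V)
      D0 <- cbind(D0, matrix(rnorm(Tn * (n_atoms - V)), Tn))
    nrm <- sqrt(colSums(D0^2))
    bad <- nrm < 1e-12
    if (any(bad)) D0[, bad] <- matrix(rnorm(Tn * sum(bad)), Tn)
    D0
  })
  D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)

  objs <- numeric(0)
  A <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sc <- cd_sparse_code(X, D, lambda, tol, 1000L)
    A <- sc$codes
    obj <- sum(sc$objective)
    objs <- c(objs, obj)
    if (it > 1 && abs(objs[it - 1] - obj) <= tol * max(1, abs(objs[it - 1]))) {
      converged <- TRUE
      break
    }

    # dictionary update: P = A A', Q = X' A'
    P <- tcrossprod(A)
    Q <- crossprod(X, t(A))
    # rank voxels by reconstruction error once; dead atoms are re-seeded from
    # distinct worst-reconstructed voxels' residual time courses
    Rres <- X - t(D %*% A)
    worst_order <- order(rowSums(Rres^2), decreasing = TRUE)
    n_reseeded <- 0L
    for (k in seq_len(ncol(D))) {
      if (P[k, k] <= 1e-12) {
        n_reseeded <- n_reseeded + 1L
        j <- worst_order[min(n_reseeded, length(worst_order))]
        u <- Rres[j, ]
        if (sqrt(sum(u^2)) > 1e-12) D[, k] <- u / sqrt(sum(u^2))
        next
      }
      u <- Q[, k] - D %*% P[, k] + D[, k] * P[k, k]
      nu <- sqrt(sum(u^2))
      if (nu > 1e-12) D[, k] <- u / nu
    }
  }
  if (!converged)
    warn(sprintf("sdl_fit: objective not converged after %d outer iterations", max_iter))

  sc <- sign_convention(A, D)
  A <- sc$maps; D <- sc$courses

  maps <- new_spatial_map_set(A, method = "sdl", state = "raw",
                              voxel_index = vi, dims = dm,
                              objective = objs[length(objs)])
  structure(
    list(dictionary = time_dictionary(D, "group"), maps = maps,
         objective = objs, lambda = lambda, n_atoms = n_atoms,
         converged = converged, iterations = length(objs), meta = meta),
    class = "sdl_fit"
  )
}

#' @export
print.sdl_fit <- function(x, ...) {
  cat("<sdl_fit> ", x$n_atoms, " atoms, lambda = ", x$lambda, ", ",
      x$iterations, " iterations, objective = ",
      format(x$objective[x$iterations]), "\n", sep = "")
  invisible(x)
}

#' Dual regression of a subject against group spatial maps
#'
#' Stage 1 solves `s_i = D_i alpha_g` for the subject dictionary `D_i` by
#' ordinary least squares (ridge jitter 1e-8 on a rank-deficient Gram, with a
#' warning) and renormalizes its columns to unit norm. Stage 2 sparse-codes
#' the subject's data against `D_i` to obtain the subject maps `alpha_i`.
#'
#' @param subject Voxels-by-time matrix for one subject (same voxel raster as
#'   the group maps), or a `bold_series` plus `mask`.
#' @param group_maps Group `spatial_map_set` (or n-by-voxels matrix).
#' @param lambda Sparsity weight for stage 2.
#' @param mask Optional mask when `subject` is a `bold_series`.
#' @param tol,max_sweeps Passed to [sparse_code()].
#' @return List with `dictionary` (subject `time_dictionary`) and `maps`
#'   (subject `spatial_map_set`).
#' @export
dual_regression <- function(subject, group_maps, lambda = 0.15, mask = NULL,
                            tol = 1e-6, max_sweeps = 1000L) {
  if (inherits(subject, "bold_series"))
    subject <- to_voxel_matrix(subject, mask)$matrix
  vi <- NULL; dm <- NULL
  Ag <- group_maps
  if (inherits(group_maps, "spatial_map_set")) {
    vi <- group_maps$voxel_index; dm <- group_maps$dims
    Ag <- group_maps$maps
  }
  if (ncol(Ag) != nrow(subject))
    abort("group maps and subject data do not share a voxel raster.")

  G <- tcrossprod(Ag)                 # n x n
  XtA <- crossprod(subject, t(Ag))    # T x n
  Di <- tryCatch(
    t(solve(G, t(XtA))),
    error = function(e) {
      warn("dual_regression: rank-deficient group maps; using ridge jitter 1e-8")
      t(solve(G + 1e-8 * diag(nrow(G)), t(XtA)))
    }
  )
  dict <- time_dictionary(Di, "subject")
  maps <- sparse_code(subject, dict, lambda, tol = tol, max_sweeps = max_sweeps)
  maps$voxel_index <- vi
  maps$dims <- dm
  list(dictionary = dict, maps = maps)
}
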