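#' Structure inventory of the seven-network phantom atlas
#'
#' Seventeen named anatomical structures grouped into the seven functional
#' networks examined by the pipeline: visual (VIS, 3 structures), executive
#' control (EX, 7), sensorimotor (SM, 3), and single placeholder structures
#' for the cerebellar (CERE), default mode (DMN), salience (SAL) and basal
#' ganglia (BAS) networks.
#'
#' @return A tibble with columns `label`, `structure`, `structure_name` and
#'   `network`.
#' @export
phantom_structures <- function() {
  inv <- list(
    VIS = c(VIS1 = "primary visual cortex",
            VIS2 = "secondary visual cortex",
            VIS3 = "associative visual cortex"),
    EX  = c(EX1 = "primary somatosensory cortex",
            EX2 = "dorsolateral prefrontal cortex",
            EX3 = "anterior prefrontal cortex",
            EX4 = "orbitofrontal cortex",
            EX5 = "insular cortex",
            EX6 = "ventral anterior cingulate cortex",
            EX7 = "dorsal anterior cingulate cortex"),
    SM  = c(SM1 = "primary motor cortex",
            SM2 = "somatosensory associative cortex",
            SM3 = "premotor cortex"),
    CERE = c(CERE1 = "cerebellum"),
    DMN  = c(DMN1 = "default mode region"),
    SAL  = c(SAL1 = "salience region"),
    BAS  = c(BAS1 = "basal ganglia")
  )
  out <- purrr::imap(inv, function(str, net) {
    tibble(structure = names(str), structure_name = unname(str), network = net)
  })
  out <- dplyr::bind_rows(out)
  out$label <- seq_len(nrow(out))
  out[, c("label", "structure", "structure_name", "network")]
}

#' Network names used throughout the pipeline
#' @return Character vector of the seven network identifiers.
#' @export
network_names <- function() c("VIS", "EX", "SM", "CERE", "DMN", "SAL", "BAS")

#' Generate the phantom label atlas
#'
#' Builds a shared brain space for the synthetic study: an ellipsoidal brain
#' mask inside `grid_dims` and 17 non-overlapping blob-shaped structures
#' (ellipsoids with jittered semi-axes) assigned to the seven networks.
#' Placement is rejection sampling and is deterministic for a fixed seed.
#'
#' @param grid_dims Integer triple, each entry at least 16.
#' @param seed Integer seed controlling placement.
#' @param blob_radius Numeric length-2 range of blob semi-axes in voxels.
#' @return An `atlas_set`: list with `labels` (3D integer array, 0 =
#'   background), `brain_mask` (3D logical), `structures` (tibble mapping
#'   label to structure and network) and `dims`.
#' @export
make_phantom_atlas <- function(grid_dims = c(24L, 24L, 16L), seed = 1L,
                               blob_radius = c(1.6, 2.6)) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 16L))
    abort("`grid_dims` must be three integers, each >= 16.")

  ctr <- (grid_dims + 1) / 2
  semi <- 0.45 * grid_dims
  ax <- seq_len(grid_dims[1]); ay <- seq_len(grid_dims[2]); az <- seq_len(grid_dims[3])
  gx <- (ax - ctr[1]) / semi[1]
  gy <- (ay - ctr[2]) / semi[2]
  gz <- (az - ctr[3]) / semi[3]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  brain <- d2 <= 1

  structures <- phantom_structures()
  labels <- array(0L, dim = grid_dims)

  brain_idx <- which(brain)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(structures))) {
      placed <- FALSE
      for (attempt in seq_len(800L)) {
        cen <- arrayInd(sample(brain_idx, 1L), grid_dims)[1, ] +
          stats::runif(3, -0.5, 0.5)
        # fall back to the smallest blobs once placement gets tight
        rmax <- if (attempt > 400L) blob_radius[1] else blob_radius[2]
        rad <- stats::runif(3, blob_radius[1], rmax)
        bx <- (ax - cen[1]) / rad[1]
        by <- (ay - cen[2]) / rad[2]
        bz <- (az - cen[3]) / rad[3]
        blob <- outer(outer(bx^2, by^2, `+`), bz^2, `+`) <= 1
        if (!any(blob)) next
        if (all(brain[blob]) && all(labels[blob] == 0L)) {
          labels[blob] <- structures$label[i]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort(sprintf("could not place structure '%s' without overlap; grid too small",
                      structures$structure[i]))
    }
  })

  structure(
    list(labels = labels, brain_mask = brain, structures = structures,
         dims = grid_dims),
    class = "atlas_set"
  )
}

#' @export
print.atlas_set <- function(x, ...) {
  cat("<atlas_set> ", paste(x$dims, collapse = " x "),
      " grid, ", sum(x$brain_mask), " brain voxels, ",
      nrow(x$structures), " structures in ",
      length(unique(x$structures$network)), " networks\n", sep = "")
  invisible(x)
}

#' Binary mask of one structure
#' @param atlas An `atlas_set`.
#' @param structure Structure identifier, e.g. `"VIS1"`.
#' @return 3D logical array.
#' @export
structure_mask <- function(atlas, structure) {
  row <- atlas$structures[atlas$structures$structure == structure, ]
  if (nrow(row) == 0L) abort(sprintf("unknown structure '%s'", structure))
  atlas$labels == row$label
}

#' Binary mask of one network (union of its member structures)
#' @param atlas An `atlas_set`.
#' @param network Network identifier, e.g. `"VIS"`.
#' @return 3D logical array.
#' @export
network_mask <- function(atlas, network) {
  labs <- atlas$structures$label[atlas$structures$network == network]
  if (length(labs) == 0L) abort(sprintf("unknown network '%s'", network))
  array(atlas$labels %in% labs, dim = atlas$dims)
}
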