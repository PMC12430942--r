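# Invertible affine spatial augmentations for the two adaptation branches.
# A transform stores a 4x4 pull-back matrix on 0-based voxel coordinates: the
# forward warp samples the input at `matrix %*% p` for each output voxel p,
# and the inverse warp uses the exact matrix inverse. Voxels whose source
# location falls outside the original grid carry no real image content; they
# are filled and flagged false in a validity mask (the out-of-field marker is
# a boolean channel, not a sentinel intensity).

#' Default affine augmentation ranges
#'
#' Mild, invertible distortions: per-axis rotation, isotropic scale, shear and
#' translation as a fraction of the grid extent.
#'
#' @param rotation_deg max absolute rotation per axis, degrees.
#' @param scale isotropic scale range `c(min, max)`.
#' @param shear max absolute shear coefficient.
#' @param translation_frac max absolute translation as a fraction of extent.
#' @return A list of class `dg_affine_ranges`.
#' @export
affine_ranges <- function(rotation_deg = 10, scale = c(0.9, 1.1),
                          shear = 0.05, translation_frac = 0.05) {
  if (rotation_deg < 0 || shear < 0 || translation_frac < 0)
    stop("augmentation ranges must be non-negative")
  if (length(scale) != 2L || any(scale <= 0) || scale[1] > scale[2])
    stop("scale must be a positive c(min, max) range")
  structure(list(rotation_deg = rotation_deg, scale = scale, shear = shear,
                 translation_frac = translation_frac),
            class = "dg_affine_ranges")
}

.rot3 <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Sample a random invertible affine augmentation
#'
#' Rotation, isotropic scale, shear and translation are drawn uniformly from
#' the configured ranges and composed about the grid centre. The exact matrix
#' inverse is stored alongside, so the forward/inverse pair round-trips to
#' identity within 1e-9.
#'
#' @param dim grid extent (voxel triple) the transform acts on.
#' @param ranges an [affine_ranges()]; all-zero ranges give the identity.
#' @return An object of class `dg_affine` with elements `matrix`,
#'   `inverse_matrix` and `dim`.
#' @export
sample_affine <- function(dim, ranges = affine_ranges()) {
  dim <- as.integer(dim)
  ang <- runif(3, -1, 1) * ranges$rotation_deg * pi / 180
  sc <- runif(1, ranges$scale[1], ranges$scale[2])
  sh <- runif(3, -1, 1) * ranges$shear
  tr <- runif(3, -1, 1) * ranges$translation_frac * dim
  lin <- .rot3(ang[1], ang[2], ang[3])
  shm <- diag(3); shm[1, 2] <- sh[1]; shm[1, 3] <- sh[2]; shm[2, 3] <- sh[3]
  lin <- lin %*% shm %*% (diag(3) * sc)
  m <- diag(4)
  m[1:3, 1:3] <- lin
  ctr <- (dim - 1) / 2
  m[1:3, 4] <- ctr - lin %*% ctr + tr
  if (abs(det(m)) < 1e-8)
    stop("sampled transform is numerically non-invertible; narrow the ranges")
  affine_augmentation(m, dim)
}

#' Construct an affine augmentation from an explicit matrix
#'
#' @param matrix 4 x 4 pull-back matrix on 0-based voxel coordinates.
#' @param dim grid extent the transform acts on.
#' @return An object of class `dg_affine`.
#' @export
affine_augmentation <- function(matrix, dim) {
  if (!all(dim(matrix) == c(4L, 4L))) stop("matrix must be 4 x 4")
  if (abs(det(matrix)) < 1e-12) stop("matrix must be invertible")
  structure(list(matrix = matrix, inverse_matrix = solve(matrix),
                 dim = as.integer(dim)),
            class = "dg_affine")
}

#' Identity augmentation on a grid
#' @param dim grid extent.
#' @return An identity `dg_affine`.
#' @export
identity_affine <- function(dim) affine_augmentation(diag(4), dim)

#' @export
print.dg_affine <- function(x, ...) {
  cat("<dg_affine> pull-back matrix:\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# Analytic validity mask of a pull-back matrix on a grid: voxels whose source
# coordinate lies inside the original grid.
.affine_valid_mask <- function(mat, dm) {
  src <- cbind(.index_grid(dm), 1) %*% t(mat)
  v <- src[, 1L] >= 0 & src[, 1L] <= dm[1L] - 1L &
    src[, 2L] >= 0 & src[, 2L] <= dm[2L] - 1L &
    src[, 3L] >= 0 & src[, 3L] <= dm[3L] - 1L
  array(v, dm)
}

# Core array warp on a channel-major array (C x D x H x W) or 3D array.
# Returns list(data, valid, structure?) where valid marks voxels whose source
# coordinate lies inside the original grid. When `src_valid` is given (the
# validity mask the source field itself carries, e.g. from a previous warp),
# validity additionally requires every interpolation corner with non-zero
# weight to be a valid source voxel, so fill values never leak into voxels
# reported as valid.
.warp_array <- function(arr, mat, interpolation = "linear", structure = FALSE,
                        src_valid = NULL) {
  chan_first <- length(dim(arr)) == 4L
  dm <- if (chan_first) dim(arr)[-1L] else dim(arr)
  grid <- .index_grid(dm)
  src <- cbind(grid, 1) %*% t(mat)
  if (chan_first) {
    C <- dim(arr)[1L]
    out <- array(0, dim = dim(arr))
    valid <- NULL; str1 <- NULL
    for (c in seq_len(C)) {
      ch <- array(arr[c, , , ], dim = dm)
      s <- if (interpolation == "nearest")
        .sample_nearest(ch, src[, 1:3], oob = "mask")
      else
        .sample_trilinear(ch, src[, 1:3], oob = "mask", structure = structure && c == 1L)
      out[c, , , ] <- s$values
      if (is.null(valid)) valid <- s$valid
      if (structure && c == 1L) str1 <- s
    }
    if (!is.null(src_valid))
      valid <- valid & .propagated_validity(src_valid, src[, 1:3], interpolation)
    res <- list(data = out, valid = array(valid, dm))
    if (structure) res$structure <- list(idx = str1$idx, w = str1$w,
                                         valid = as.vector(valid))
    res
  } else {
    s <- if (interpolation == "nearest")
      .sample_nearest(arr, src[, 1:3], oob = "mask")
    else
      .sample_trilinear(arr, src[, 1:3], oob = "mask", structure = structure)
    valid <- s$valid
    if (!is.null(src_valid))
      valid <- valid & .propagated_validity(src_valid, src[, 1:3], interpolation)
    res <- list(data = array(s$values, dm), valid = array(valid, dm))
    if (structure) res$structure <- list(idx = s$idx, w = s$w, valid = as.vector(valid))
    res
  }
}

# Conservative warp of a validity mask: trilinear interpolation of the 0/1
# field equals 1 exactly when every corner contributing non-zero weight is
# valid; nearest interpolation just samples the mask.
.propagated_validity <- function(src_valid, coords, interpolation) {
  sv <- array(as.numeric(src_valid), dim(src_valid))
  if (interpolation == "nearest")
    .sample_nearest(sv, coords, oob = "mask")$values > 0.5
  else
    .sample_trilinear(sv, coords, oob = "mask")$values > 1 - 1e-9
}

#' Warp a field through an affine augmentation
#'
#' Resamples the field through the transform's (inverse) matrix. Scalar
#' volumes and probability maps use trilinear interpolation, label maps
#' nearest-neighbour. Output voxels whose pull-back coordinate falls outside
#' the original grid are filled with 0 and reported `FALSE` in the validity
#' mask; warped probability maps are renormalised per voxel on valid voxels.
#'
#' @param field a `dg_volume`, `dg_label_map`, `dg_prob_map`, or plain array
#'   (3D, or 4D channel-major).
#' @param t a `dg_affine`.
#' @param direction `"forward"` applies the augmentation, `"inverse"` undoes it.
#' @param src_valid optional validity mask carried by `field` itself (e.g.
#'   from a previous warp); fill values behind it are never reported valid.
#' @return A list with elements `field` (same type as the input) and `valid`
#'   (logical array over the grid).
#' @export
warp <- function(field, t, direction = c("forward", "inverse"),
                 src_valid = NULL) {
  direction <- match.arg(direction)
  mat <- if (direction == "forward") t$matrix else t$inverse_matrix
  if (inherits(field, "dg_label_map")) {
    r <- .warp_array(field$data, mat, interpolation = "nearest",
                     src_valid = src_valid)
    out <- label_map(array(as.integer(r$data), dim(field$data)),
                     class_ids = field$class_ids,
                     background_id = field$background_id,
                     spacing = field$spacing, affine = field$affine)
    return(list(field = out, valid = r$valid))
  }
  if (inherits(field, "dg_prob_map")) {
    r <- .warp_array(field$data, mat, interpolation = "linear",
                     src_valid = src_valid)
    dat <- .renormalize_probs(r$data, r$valid)
    out <- probability_map(dat, field$class_ids, spacing = field$spacing,
                           affine = field$affine)
    return(list(field = out, valid = r$valid))
  }
  if (inherits(field, "dg_volume")) {
    r <- .warp_array(field$data, mat, interpolation = "linear",
                     src_valid = src_valid)
    out <- as_volume(r$data, spacing = field$spacing, affine = field$affine)
    return(list(field = out, valid = r$valid))
  }
  r <- .warp_array(field, mat, interpolation = "linear", src_valid = src_valid)
  list(field = r$data, valid = r$valid)
}

# Per-voxel renormalisation of a warped channel-major probability array,
# restricted to valid voxels (interpolated simplex values stay a simplex up
# to numerical error, so this is a safeguard rather than a correction).
.renormalize_probs <- function(dat, valid) {
  C <- dim(dat)[1L]
  flat <- matrix(dat, nrow = C)
  s <- colSums(flat)
  v <- as.vector(valid) & s > 1e-12
  flat[, v] <- sweep(flat[, v, drop = FALSE], 2L, s[v], `/`)
  flat[flat < 0] <- 0
  array(flat, dim(dat))
}

#' Combine two branch validity masks into the consistency mask
#'
#' Logical AND: a voxel enters the consistency loss only when both
#' inverse-warped branch outputs carry real image content there.
#'
#' @param valid_a,valid_b logical arrays on a common grid.
#' @return An object of class `dg_consistency_mask` (logical array).
#' @export
consistency_mask <- function(valid_a, valid_b) {
  if (!identical(dim(valid_a), dim(valid_b)))
    stop("validity masks must share one grid")
  structure(valid_a & valid_b, class = "dg_consistency_mask")
}
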