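#' Construct a 3D scalar volume
#'
#' A `dg_volume` is the package's canonical container for one 3D scalar image:
#' a numeric array of shape D x H x W together with the physical voxel spacing
#' (mm per axis) and a 4 x 4 voxel-to-world affine. Voxel indexing is 0-based
#' in all coordinate computations; orientation is taken as stored.
#'
#' @param data numeric 3D array.
#' @param spacing positive numeric of length 3, voxel size in mm.
#' @param affine 4 x 4 voxel-to-world matrix; defaults to `diag(c(spacing, 1))`.
#' @return An object of class `dg_volume`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data))) stop("volume data must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "dg_volume")
}

#' Construct an integer label map
#'
#' Hard segmentations aligned to a volume grid. Every voxel must carry either
#' the background id or one of the declared class ids.
#'
#' @param data integer 3D array.
#' @param class_ids integers allowed in the map (foreground classes); defaults
#'   to the sorted non-background values present.
#' @param background_id background label, default 0.
#' @param spacing,affine grid metadata, as in [as_volume()].
#' @return An object of class `dg_label_map`.
#' @export
label_map <- function(data, class_ids = NULL, background_id = 0L,
                      spacing = c(1, 1, 1), affine = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (any(data != round(data))) stop("label data must be integer-valued")
  storage.mode(data) <- "integer"
  present <- sort(unique(as.vector(data)))
  if (is.null(class_ids)) class_ids <- setdiff(present, background_id)
  class_ids <- as.integer(class_ids)
  bad <- setdiff(present, c(class_ids, background_id))
  if (length(bad))
    stop("label map contains undeclared class ids: ", paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, class_ids = class_ids,
                 background_id = as.integer(background_id),
                 spacing = spacing, affine = affine),
            class = c("dg_label_map", "dg_volume"))
}

#' Construct a per-class probability map
#'
#' Channel-major soft segmentation: `data` has shape C x D x H x W with one
#' channel per class id. Values must lie in `[0, 1]`; maps produced by the
#' network's softmax head sum to 1 per voxel within 1e-5.
#'
#' @param data numeric 4D array, channel-major.
#' @param class_ids ordered class ids of length `dim(data)[1]`.
#' @param spacing,affine grid metadata.
#' @return An object of class `dg_prob_map`.
#' @export
probability_map <- function(data, class_ids, spacing = c(1, 1, 1), affine = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 4L) stop("probability data must be a 4D channel-major array")
  if (dim(data)[1L] != length(class_ids))
    stop("channel count does not match length(class_ids)")
  if (min(data) < -1e-8 || max(data) > 1 + 1e-8)
    stop("probabilities must lie in [0, 1]")
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, class_ids = as.integer(class_ids),
                 spacing = spacing, affine = affine),
            class = "dg_prob_map")
}

#' @export
print.dg_volume <- function(x, ...) {
  kind <- if (inherits(x, "dg_label_map")) "label map" else "volume"
  cat(sprintf("<dg_%s> %s voxels, spacing %s mm\n",
              gsub(" ", "_", kind), paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  if (inherits(x, "dg_label_map"))
    cat("  classes:", paste(x$class_ids, collapse = ", "),
        " background:", x$background_id, "\n")
  else
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.dg_prob_map <- function(x, ...) {
  cat(sprintf("<dg_prob_map> %d classes over %s voxels\n",
              dim(x$data)[1L], paste(dim(x$data)[-1L], collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param as_labels read as an integer [label_map()] instead of a float volume.
#' @return A [as_volume()] object (or `dg_label_map` when `as_labels = TRUE`).
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("expected a 3D image, got ", length(dm), "D: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  dat <- as.array(img)
  attributes(dat) <- list(dim = dm)
  if (as_labels) label_map(dat, spacing = spacing, affine = aff)
  else as_volume(dat, spacing = spacing, affine = aff)
}

#' Read a channel-major probability map from 4D NIfTI
#'
#' The 4th NIfTI dimension is interpreted as the class channel and moved first.
#'
#' @param path path to a 4D NIfTI file.
#' @param class_ids class ids per channel; defaults to `0:(C-1)`.
#' @return A [probability_map()].
#' @export
read_probability_map <- function(path, class_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4D image: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  dat <- as.array(img); attributes(dat) <- list(dim = dm)
  if (is.null(class_ids)) class_ids <- seq_len(dm[4L]) - 1L
  probability_map(aperm(dat, c(4L, 1L, 2L, 3L)), class_ids, spacing = spacing)
}

#' Write a volume, label map or probability map as NIfTI
#'
#' Volumes are stored as float64, label maps as int16, probability maps as
#' float 4D images with the class channel last (NIfTI dimension 4).
#'
#' @param v a `dg_volume`, `dg_label_map` or `dg_prob_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (inherits(v, "dg_prob_map")) {
    dat <- aperm(v$data, c(2L, 3L, 4L, 1L))
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- c(v$spacing, 1)
    dtype <- "double"
  } else if (inherits(v, "dg_label_map")) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    dtype <- "int16"
  } else if (inherits(v, "dg_volume")) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    dtype <- "double"
  } else stop("unsupported object for write_volume()")
  if (!is.null(v$affine) && !inherits(v, "dg_prob_map")) {
    aff <- structure(v$affine, code = 2L)
    img <- RNifti::`sform<-`(img, value = aff)
    img <- RNifti::`qform<-`(img, value = aff)
  }
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a volume or label map to a target voxel spacing
#'
#' The output grid size per axis is `round(size * spacing / target_spacing)`.
#' Scalar volumes use trilinear interpolation by default; label maps must use
#' nearest-neighbour (requesting linear interpolation for a label map is an
#' error). Resampling at the current spacing is the identity.
#'
#' @param v a `dg_volume` or `dg_label_map`.
#' @param target_spacing positive mm triple (a scalar is recycled).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return Resampled object of the same class.
#' @export
resample_to_spacing <- function(v, target_spacing,
                                interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(target_spacing <= 0)) stop("target_spacing must be strictly positive")
  is_labels <- inherits(v, "dg_label_map")
  if (is_labels && interpolation == "linear")
    stop("label maps must be resampled with nearest-neighbour interpolation")
  dm <- dim(v$data)
  scale <- target_spacing / v$spacing
  new_dm <- pmax(1L, as.integer(round(dm * v$spacing / target_spacing)))
  if (all(new_dm == dm) && all(abs(scale - 1) < 1e-12)) return(v)
  coords <- .index_grid(new_dm)
  coords <- sweep(coords, 2L, scale, `*`)
  vals <- if (interpolation == "nearest" || is_labels)
    .sample_nearest(v$data, coords, oob = "clamp")$values
  else
    .sample_trilinear(v$data, coords, oob = "clamp")$values
  new_aff <- v$affine
  new_aff[, 1:3] <- sweep(new_aff[, 1:3, drop = FALSE], 2L, scale, `*`)
  if (is_labels)
    label_map(array(as.integer(vals), new_dm), class_ids = v$class_ids,
              background_id = v$background_id, spacing = target_spacing,
              affine = new_aff)
  else
    as_volume(array(vals, new_dm), spacing = target_spacing, affine = new_aff)
}

# One-hot encode a label map against an ordered class vector -> C x D x H x W.
.one_hot <- function(labels, classes) {
  dm <- dim(labels)
  out <- array(0, dim = c(length(classes), dm))
  for (k in seq_along(classes))
    out[k, , , ] <- as.numeric(labels == classes[k])
  out
}

# Collapse a channel-major probability array to hard labels by argmax.
.argmax_labels <- function(prob, classes) {
  dm <- dim(prob)[-1L]
  flat <- matrix(prob, nrow = dim(prob)[1L])
  array(classes[max.col(t(flat), ties.method = "first")], dim = dm)
}
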