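# Self-similarity context descriptor: per voxel, exponentiated noise-normalised
# patch distances between the 12 diagonal pairs of a voxel's 6-neighbourhood.
# The descriptor compares neighbouring patches with each other and ignores the
# centre patch itself, which is what makes it robust to monotone and affine
# intensity changes across modalities.

# Shift an array by an integer voxel offset with edge replication, so the
# output grid equals the input grid.
.shift_replicate <- function(arr, off) {
  dm <- dim(arr)
  ix <- pmin(pmax(seq_len(dm[1L]) + off[1L], 1L), dm[1L])
  iy <- pmin(pmax(seq_len(dm[2L]) + off[2L], 1L), dm[2L])
  iz <- pmin(pmax(seq_len(dm[3L]) + off[3L], 1L), dm[3L])
  arr[ix, iy, iz, drop = FALSE]
}

# Box-sum over a cubic patch of edge length `size` (odd), edge-replicated.
.box_sum <- function(arr, size) {
  if (size <= 1L) return(arr)
  r <- (size - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
    out <- out + .shift_replicate(arr, c(dx, dy, dz))
  out
}

#' Enumerate the 12 neighbour-pair offsets of the 6-neighbourhood
#'
#' The 6 neighbours sit at `patch_distance` voxels along each axis direction.
#' The descriptor uses the 12 unordered pairs of neighbours that are diagonal
#' to each other (Chebyshev-adjacent, i.e. not opposite along one axis).
#' Enumeration is lexicographic over the offset triples, fixing the channel
#' order of the descriptor.
#'
#' @param patch_distance integer spacing of the neighbourhood in voxels.
#' @return List of 12 lists with elements `a` and `b`, each an offset triple.
#' @export
ssc_pair_offsets <- function(patch_distance = 1L) {
  d <- as.integer(patch_distance)
  if (d < 1L) stop("patch_distance must be >= 1")
  nb <- list(c(-d, 0L, 0L), c(0L, -d, 0L), c(0L, 0L, -d),
             c(0L, 0L, d), c(0L, d, 0L), c(d, 0L, 0L))
  pairs <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    if (all(nb[[i]] + nb[[j]] == 0L)) next  # opposite neighbours: not adjacent
    pairs[[length(pairs) + 1L]] <- list(a = nb[[i]], b = nb[[j]])
  }
  stopifnot(length(pairs) == 12L)
  pairs
}

#' Number of descriptor channels for a neighbourhood pattern
#'
#' The 6-neighbourhood yields 12 diagonal neighbour pairs, so the descriptor
#' maps a 1-channel volume to a 12-channel field.
#'
#' @param neighborhood neighbourhood name; only `"six"` is supported.
#' @return Integer channel count (12).
#' @export
descriptor_channel_count <- function(neighborhood = "six") {
  if (!identical(neighborhood, "six"))
    stop("unsupported neighbourhood: ", neighborhood)
  12L
}

#' Patchwise sum-of-squared-differences field between two shifted copies
#'
#' At each voxel p the field holds the SSD between the patch centred at
#' `p + offset_a` and the patch centred at `p + offset_b`, realised as a
#' box-sum of the squared shifted-difference image with edge replication.
#'
#' @param x a `dg_volume` or 3D array.
#' @param offset_a,offset_b distinct integer voxel offset triples.
#' @param patch_size odd patch edge length in voxels (1 = single voxel).
#' @return 3D array of SSD values on the grid of `x`.
#' @export
patch_ssd_field <- function(x, offset_a, offset_b, patch_size = 1L) {
  arr <- if (inherits(x, "dg_volume")) x$data else x
  if (all(offset_a == offset_b))
    stop("offset_a and offset_b must differ (zero-distance pair)")
  d <- .shift_replicate(arr, offset_a) - .shift_replicate(arr, offset_b)
  .box_sum(d * d, as.integer(patch_size))
}

#' Per-voxel noise estimate from the 12 SSD fields
#'
#' The noise normaliser of the descriptor: the per-voxel mean of the 12 patch
#' distances, floored at a small positive epsilon so flat regions map to
#' exp(0) = 1 instead of 0/0.
#'
#' @param ssd_fields list of 12 SSD arrays on a common grid.
#' @return 3D array of floored per-voxel means.
#' @export
noise_estimate <- function(ssd_fields) {
  if (length(ssd_fields) != 12L) stop("expected 12 SSD fields")
  dm <- dim(ssd_fields[[1L]])
  for (f in ssd_fields)
    if (!identical(dim(f), dm)) stop("SSD fields must share one grid")
  s <- Reduce(`+`, ssd_fields) / 12
  floor_eps <- max(1e-6 * mean(s), 1e-12)
  pmax(s, floor_eps)
}

#' Compute the 12-channel self-similarity context descriptor
#'
#' For each of the 12 diagonal neighbour pairs the channel value is
#' `exp(-SSD / sigma2)` where `sigma2` is the noise estimate — by default the
#' per-voxel mean of the 12 SSD values ([noise_estimate()]), optionally a
#' single image-global mean. Because both SSD and the normaliser scale with
#' the square of any affine intensity rescaling, the descriptor is invariant
#' to `a * x + b` for `a > 0`.
#'
#' @param x a `dg_volume` or 3D array, at least 3 voxels per axis.
#' @param patch_size odd patch edge length in voxels (default 1).
#' @param patch_distance neighbourhood spacing in voxels (default 1).
#' @param sigma_mode `"voxel"` (per-voxel normaliser, default) or `"global"`.
#' @return An object of class `dg_ssc` with channel-major `data`
#'   (12 x D x H x W), the pair offsets, and the parameters used.
#' @export
compute_ssc <- function(x, patch_size = 1L, patch_distance = 1L,
                        sigma_mode = c("voxel", "global")) {
  sigma_mode <- match.arg(sigma_mode)
  arr <- if (inherits(x, "dg_volume")) x$data else x
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  if (any(dim(arr) < 3L)) stop("volume must be at least 3 voxels per axis")
  pairs <- ssc_pair_offsets(patch_distance)
  ssd <- lapply(pairs, function(p)
    patch_ssd_field(arr, p$a, p$b, patch_size = patch_size))
  if (sigma_mode == "voxel") {
    sigma2 <- noise_estimate(ssd)
  } else {
    m <- mean(Reduce(`+`, ssd) / 12)
    sigma2 <- array(max(m, 1e-12), dim(arr))
  }
  out <- array(0, dim = c(12L, dim(arr)))
  for (k in 1:12) out[k, , , ] <- exp(-ssd[[k]] / sigma2)
  structure(list(data = out, pair_offsets = pairs,
                 patch_size = as.integer(patch_size),
                 patch_distance = as.integer(patch_distance),
                 sigma_mode = sigma_mode),
            class = "dg_ssc")
}

#' @export
print.dg_ssc <- function(x, ...) {
  cat(sprintf("<dg_ssc> 12-channel descriptor over %s voxels (patch %d, distance %d, sigma %s)\n",
              paste(dim(x$data)[-1L], collapse = "x"), x$patch_size,
              x$patch_distance, x$sigma_mode))
  invisible(x)
}

# Fast internal path: descriptor channels as a plain channel-major array.
.ssc_array <- function(arr, patch_size = 1L, patch_distance = 1L)
  compute_ssc(arr, patch_size, patch_distance)$data
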