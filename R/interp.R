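# Internal resampling primitives shared by grid resampling and affine warping.
# All voxel coordinates are 0-based and refer to array index space (first array
# dimension first). A coordinate is "in bounds" when it lies in [0, n - 1] on
# every axis; callers choose whether out-of-bounds samples are clamped to the
# edge (grid resampling) or filled and flagged invalid (spatial augmentation).

# coords: n x 3 matrix of 0-based sample positions.
# Returns list(values, valid) and, if structure = TRUE, the 8 corner linear
# indices and weights needed for the transpose (scatter) pass of the warp.
.sample_trilinear <- function(arr, coords, oob = c("clamp", "mask"),
                              fill = 0, structure = FALSE) {
  oob <- match.arg(oob)
  dm <- dim(arr)
  x <- coords[, 1L]; y <- coords[, 2L]; z <- coords[, 3L]
  valid <- x >= 0 & x <= dm[1L] - 1L & y >= 0 & y <= dm[2L] - 1L &
    z >= 0 & z <= dm[3L] - 1L
  cx <- pmin(pmax(x, 0), dm[1L] - 1L)
  cy <- pmin(pmax(y, 0), dm[2L] - 1L)
  cz <- pmin(pmax(z, 0), dm[3L] - 1L)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  x1 <- pmin(x0 + 1, dm[1L] - 1L)
  y1 <- pmin(y0 + 1, dm[2L] - 1L)
  z1 <- pmin(z0 + 1, dm[3L] - 1L)
  sxy <- dm[1L] * dm[2L]
  lin <- function(ix, iy, iz) 1 + ix + dm[1L] * iy + sxy * iz
  idx <- cbind(lin(x0, y0, z0), lin(x1, y0, z0), lin(x0, y1, z0), lin(x1, y1, z0),
               lin(x0, y0, z1), lin(x1, y0, z1), lin(x0, y1, z1), lin(x1, y1, z1))
  w <- cbind((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
             (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
             (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
             (1 - fx) * fy * fz,             fx * fy * fz)
  v <- numeric(nrow(coords))
  av <- as.vector(arr)
  for (k in 1:8) v <- v + w[, k] * av[idx[, k]]
  if (oob == "mask") v[!valid] <- fill
  out <- list(values = v, valid = valid)
  if (structure) { out$idx <- idx; out$w <- w }
  out
}

.sample_nearest <- function(arr, coords, oob = c("clamp", "mask"), fill = 0) {
  oob <- match.arg(oob)
  dm <- dim(arr)
  x <- round(coords[, 1L]); y <- round(coords[, 2L]); z <- round(coords[, 3L])
  valid <- coords[, 1L] >= 0 & coords[, 1L] <= dm[1L] - 1L &
    coords[, 2L] >= 0 & coords[, 2L] <= dm[2L] - 1L &
    coords[, 3L] >= 0 & coords[, 3L] <= dm[3L] - 1L
  x <- pmin(pmax(x, 0), dm[1L] - 1L)
  y <- pmin(pmax(y, 0), dm[2L] - 1L)
  z <- pmin(pmax(z, 0), dm[3L] - 1L)
  v <- as.vector(arr)[1 + x + dm[1L] * y + dm[1L] * dm[2L] * z]
  if (oob == "mask") v[!valid] <- fill
  list(values = v, valid = valid)
}

# Transpose of the trilinear gather: scatter-add grad * weight into the source
# grid. Used to propagate loss gradients through an (inverse) warp.
.scatter_trilinear <- function(grad_values, structure, in_dim, valid_only = TRUE) {
  g <- numeric(prod(in_dim))
  gv <- grad_values
  if (valid_only) gv[!structure$valid] <- 0
  for (k in 1:8) {
    contrib <- structure$w[, k] * gv
    nz <- contrib != 0
    if (any(nz)) {
      s <- rowsum(contrib[nz], group = structure$idx[nz, k], reorder = FALSE)
      g[as.integer(rownames(s))] <- g[as.integer(rownames(s))] + s[, 1L]
    }
  }
  array(g, dim = in_dim)
}

# 0-based voxel index grid of a 3D extent, as an n x 3 matrix (first axis fastest).
.index_grid <- function(dm) {
  cbind(rep.int(seq_len(dm[1L]) - 1L, dm[2L] * dm[3L]),
        rep.int(rep(seq_len(dm[2L]) - 1L, each = dm[1L]), dm[3L]),
        rep(seq_len(dm[3L]) - 1L, each = dm[1L] * dm[2L]))
}
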