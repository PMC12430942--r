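# Shared fixtures: all inputs are generated in code at test time.

smooth_field <- function(dm) {
  f <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3]))
    f[i, j, k] <- sin(i / 8) + cos(j / 9) + sin(k / 10)
  f
}

random_simplex_map <- function(C, dm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- array(runif(C * prod(dm)), c(C, dm))
  s <- apply(p, 2:4, sum)
  for (c in seq_len(C)) p[c, , , ] <- p[c, , , ] / s
  p
}

tiny_phantom_set <- function(n, seeds, grid = 32L) {
  lapply(seeds[seq_len(n)], function(s)
    generate_phantom(phantom_spec(grid_size = rep(grid, 3), seed = s)))
}

# Independent brute-force implementation of the self-similarity descriptor:
# per-voxel triple loop, edge-replicated reads, per-voxel noise normaliser
# with the same floor rule as the package.
naive_ssc <- function(arr, patch_size = 1L, patch_distance = 1L) {
  dm <- dim(arr)
  gv <- function(i, j, k)
    arr[min(max(i, 1L), dm[1]), min(max(j, 1L), dm[2]), min(max(k, 1L), dm[3])]
  pairs <- dgtta::ssc_pair_offsets(patch_distance)
  r <- (patch_size - 1L) %/% 2L
  box <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  ssd <- array(0, c(12, dm))
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    for (q in 1:12) {
      a <- pairs[[q]]$a; b <- pairs[[q]]$b
      acc <- 0
      for (t in seq_len(nrow(box))) {
        va <- gv(i + a[1] + box$dx[t], j + a[2] + box$dy[t], k + a[3] + box$dz[t])
        vb <- gv(i + b[1] + box$dx[t], j + b[2] + box$dy[t], k + b[3] + box$dz[t])
        acc <- acc + (va - vb)^2
      }
      ssd[q, i, j, k] <- acc
    }
  }
  s <- apply(ssd, 2:4, mean)
  floor_eps <- max(1e-6 * mean(s), 1e-12)
  s <- pmax(s, floor_eps)
  out <- array(0, c(12, dm))
  for (q in 1:12) out[q, , , ] <- exp(-ssd[q, , , ] / s)
  out
}
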