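# Synthetic cross-domain phantoms: paired renderings of one label geometry
# under two intensity regimes. The source domain uses a monotone, CT-like
# per-class intensity lookup; the target domain uses a non-monotone remapping
# (contrast inversion for some class pairs), extra noise and a smooth
# multiplicative bias field — a stand-in for the CT-to-MR appearance gap.
# A purely affine intensity change would be closed by the self-similarity
# descriptor alone, so the gap is deliberately non-affine.

#' Phantom specification
#'
#' @param grid_size voxel triple (default 64^3).
#' @param n_structures number of foreground classes, each one randomized
#'   smooth-boundary ellipsoid (default 4).
#' @param spacing voxel size in mm (default 1.5 isotropic, the uniform
#'   spacing the pipeline resamples to).
#' @param source_means per-class mean intensity, background first; monotone
#'   increasing, CT-like.
#' @param target_means per-class mean intensity in the target domain: a
#'   non-monotone, non-affine remapping of `source_means` on a different
#'   overall scale (contrast inversion between class pairs), MR-like.
#' @param noise_sigma named additive Gaussian noise levels `c(source=, target=)`.
#'   Class mean separations must stay >= 2 * noise_sigma per domain so the
#'   structures remain learnable.
#' @param texture_amplitude named oriented-texture amplitudes
#'   `c(source=, target=)`. Each foreground class carries a sinusoidal
#'   texture with its own orientation and wavelength, mimicking
#'   class-distinctive tissue texture: the pattern geometry is shared by both
#'   domains (anatomy), while its amplitude/sign changes with the domain (a
#'   locally affine appearance change). Intensity-level classifiers must rely
#'   on the remapped class means, whereas self-similarity features can key on
#'   the preserved texture geometry. Set to zero for untextured phantoms.
#' @param texture_wavelengths per-class texture wavelength in voxels.
#' @param texture_invert foreground classes whose texture sign flips in the
#'   target domain.
#' @param bias_amplitude amplitude of the low-frequency multiplicative bias
#'   field applied to the target domain (0 disables it).
#' @param seed integer seed; all randomness flows from it through named
#'   substreams (geometry, intensity network, noise).
#' @return An object of class `dg_phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64L, 64L, 64L), n_structures = 4L,
                         spacing = c(1.5, 1.5, 1.5),
                         source_means = c(0.00, 0.25, 0.45, 0.65, 0.85),
                         target_means = c(0.20, 1.70, 0.50, 1.30, 0.90),
                         noise_sigma = c(source = 0.05, target = 0.05),
                         texture_amplitude = c(source = 0.08, target = 0.15),
                         texture_wavelengths = c(5, 7, 9, 6),
                         texture_invert = c(1L, 3L),
                         bias_amplitude = 0.3, seed = 1L) {
  grid_size <- rep_len(as.integer(grid_size), 3L)
  if (any(grid_size < 16L)) stop("grid too small for the structure model")
  if (length(source_means) != n_structures + 1L ||
      length(target_means) != n_structures + 1L)
    stop("intensity lookups need one value per class plus background")
  for (mns in list(source = source_means, target = target_means)) {
    gap <- min(diff(sort(mns)))
    if (gap < 2 * max(noise_sigma))
      stop("class means must be separated by >= 2 * noise_sigma")
  }
  texture_wavelengths <- rep_len(texture_wavelengths, n_structures)
  structure(list(grid_size = grid_size, n_structures = as.integer(n_structures),
                 spacing = spacing, source_means = source_means,
                 target_means = target_means, noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 texture_wavelengths = texture_wavelengths,
                 texture_invert = as.integer(texture_invert),
                 bias_amplitude = bias_amplitude, seed = as.integer(seed)),
            class = "dg_phantom_spec")
}

# Substream seeds derived deterministically from the spec seed.
.substream_seeds <- function(seed, n = 3L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Smooth low-frequency multiplicative bias field exp(amplitude * poly).
.bias_field <- function(dm, amplitude) {
  if (amplitude <= 0) return(array(1, dm))
  co <- rnorm(9, sd = 1)
  x <- seq(-1, 1, length.out = dm[1L])
  y <- seq(-1, 1, length.out = dm[2L])
  z <- seq(-1, 1, length.out = dm[3L])
  gx <- array(rep(x, times = dm[2L] * dm[3L]), dm)
  gy <- array(rep(rep(y, each = dm[1L]), times = dm[3L]), dm)
  gz <- array(rep(z, each = dm[1L] * dm[2L]), dm)
  p <- co[1] * gx + co[2] * gy + co[3] * gz + co[4] * gx * gy +
    co[5] * gx * gz + co[6] * gy * gz + co[7] * (gx^2 - 1 / 3) +
    co[8] * (gy^2 - 1 / 3) + co[9] * (gz^2 - 1 / 3)
  p <- p - mean(p)
  r <- max(abs(p), 1e-9)
  exp(amplitude * p / r)
}

# Per-class oriented sinusoidal textures. Class k gets a plane wave along a
# class-specific direction with a class-specific wavelength and a random
# phase; the same pattern underlies both domains, with the sign flipped in
# the target domain for the classes in `texture_invert`.
.class_textures <- function(labels, dm, spec) {
  if (all(spec$texture_amplitude == 0) || spec$n_structures == 0L)
    return(list(source = array(0, dm), target = array(0, dm)))
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  gx <- array(rep(seq_len(dm[1L]), times = dm[2L] * dm[3L]), dm)
  gy <- array(rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]), dm)
  gz <- array(rep(seq_len(dm[3L]), each = dm[1L] * dm[2L]), dm)
  src <- array(0, dm); tgt <- array(0, dm)
  for (k in seq_len(spec$n_structures)) {
    d <- dirs[[(k - 1L) %% length(dirs) + 1L]]
    lam <- spec$texture_wavelengths[k]
    phase <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * (d[1] * gx + d[2] * gy + d[3] * gz) / lam + phase)
    mk <- labels == k
    src[mk] <- wave[mk]
    tgt[mk] <- if (k %in% spec$texture_invert) -wave[mk] else wave[mk]
  }
  list(source = src, target = tgt)
}

#' Generate one paired cross-domain phantom
#'
#' Places `n_structures` randomized smooth-boundary ellipsoids on the grid
#' (later structures overwrite earlier ones where they overlap), then renders
#' the geometry under both intensity lookups. The label geometry is identical
#' between the two domains by construction; only the appearance differs.
#'
#' @param spec a [phantom_spec()].
#' @return List with `label` (a [label_map()]), `source` and `target`
#'   (co-registered [as_volume()]s).
#' @export
generate_phantom <- function(spec) {
  dm <- spec$grid_size
  seeds <- .substream_seeds(spec$seed, 3L)

  set.seed(seeds[1L])  # geometry substream
  labels <- array(0L, dm)
  gx <- array(rep(seq_len(dm[1L]), times = dm[2L] * dm[3L]), dm)
  gy <- array(rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]), dm)
  gz <- array(rep(seq_len(dm[3L]), each = dm[1L] * dm[2L]), dm)
  for (k in seq_len(spec$n_structures)) {
    ctr <- runif(3, 0.28, 0.72) * dm
    ax <- runif(3, 0.09, 0.17) * dm
    if (any(ctr - ax < 1) || any(ctr + ax > dm))
      stop("structure does not fit the grid; enlarge grid_size")
    ang <- runif(3, -pi, pi)
    R <- .rot3(ang[1], ang[2], ang[3])
    dx <- sweep(cbind(as.vector(gx), as.vector(gy), as.vector(gz)), 2L, ctr)
    rot <- dx %*% t(R)
    q <- (rot[, 1] / ax[1])^2 + (rot[, 2] / ax[2])^2 + (rot[, 3] / ax[3])^2
    # smooth boundary: modulate the radius with a mild low-frequency ripple
    ripple <- 1 + 0.15 * sin(2 * pi * (rot[, 1] / ax[1]) / 2 + runif(1, 0, 2 * pi)) *
      cos(2 * pi * (rot[, 2] / ax[2]) / 2 + runif(1, 0, 2 * pi))
    inside <- q <= ripple
    labels[array(inside, dm)] <- k
  }

  set.seed(seeds[2L])  # intensity substream (bias field and texture phases)
  bias <- .bias_field(dm, spec$bias_amplitude)
  texture <- .class_textures(labels, dm, spec)

  set.seed(seeds[3L])  # noise substream
  src <- array(spec$source_means[labels + 1L], dm) +
    spec$texture_amplitude[["source"]] * texture$source
  if (spec$noise_sigma[["source"]] > 0)
    src <- src + rnorm(length(src), sd = spec$noise_sigma[["source"]])
  tgt <- (array(spec$target_means[labels + 1L], dm) +
            spec$texture_amplitude[["target"]] * texture$target) * bias
  if (spec$noise_sigma[["target"]] > 0)
    tgt <- tgt + rnorm(length(tgt), sd = spec$noise_sigma[["target"]])

  list(label = label_map(labels, class_ids = seq_len(spec$n_structures),
                         spacing = spec$spacing),
       source = as_volume(src, spacing = spec$spacing),
       target = as_volume(tgt, spacing = spec$spacing))
}

#' Generate and write a split phantom dataset
#'
#' Writes `source/train`, `source/test` and `target/test` NIfTI trees plus a
#' manifest JSON. Each phantom has its own derived seed; train and test
#' phantoms never overlap, and the target test images share their label
#' geometry with the corresponding source test phantoms.
#'
#' @param spec a [phantom_spec()]; its `seed` is combined with `seed`.
#' @param n_train,n_test phantoms per split (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed dataset-level seed used to derive per-phantom seeds.
#' @return The manifest as a list, invisibly; also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
generate_dataset <- function(spec, n_train, n_test, out_dir, seed = spec$seed) {
  if (n_train < 1L || n_test < 1L) stop("n_train and n_test must be >= 1")
  set.seed(seed)
  ph_seeds <- sample.int(.Machine$integer.max - 1L, n_train + n_test)
  dirs <- file.path(out_dir, c("source/train", "source/test", "target/test"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, n_train = n_train, n_test = n_test,
                   grid_size = spec$grid_size, spacing = spec$spacing,
                   phantoms = list())
  for (i in seq_along(ph_seeds)) {
    sp <- spec; sp$seed <- ph_seeds[i]
    ph <- generate_phantom(sp)
    id <- sprintf("ph%010d", ph_seeds[i])
    split <- if (i <= n_train) "train" else "test"
    files <- list()
    img_s <- file.path(out_dir, "source", split, paste0(id, "_image.nii.gz"))
    lab_s <- file.path(out_dir, "source", split, paste0(id, "_label.nii.gz"))
    write_volume(ph$source, img_s)
    write_volume(ph$label, lab_s)
    files$source_image <- img_s; files$source_label <- lab_s
    if (split == "test") {
      img_t <- file.path(out_dir, "target", "test", paste0(id, "_image.nii.gz"))
      lab_t <- file.path(out_dir, "target", "test", paste0(id, "_label.nii.gz"))
      write_volume(ph$target, img_t)
      write_volume(ph$label, lab_t)
      files$target_image <- img_t; files$target_label <- lab_t
    }
    manifest$phantoms[[length(manifest$phantoms) + 1L]] <-
      list(id = id, seed = ph_seeds[i], split = split,
           files = lapply(files, basename))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
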