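# Global intensity non-linear (GIN) augmentation: a shallow convolutional
# network with freshly randomised weights remaps the intensities/textures of
# the input, and the result is blended with the original image by a random
# convex weight alpha. Re-randomising the network at every training iteration
# exposes the model to a wide manifold of intensity appearances.

#' GIN augmentation configuration
#'
#' @param n_layers number of convolution layers of the random network (>= 1).
#' @param hidden_channels channels of the hidden layers (>= 1).
#' @param kernel_size convolution kernel edge length, 1 (default) or 3.
#'   Kernel 1 remaps intensities voxelwise and leaves spatial structure —
#'   in particular the local self-similarity pattern — exactly intact;
#'   kernel 3 additionally mixes neighbourhoods.
#' @param alpha optional fixed blend weight in `[0, 1]`; when `NULL` (default)
#'   a fresh `alpha ~ U(0, 1)` is drawn per augmented volume.
#' @param seed optional integer seed making one augmentation call reproducible.
#' @return An object of class `dg_gin_config`.
#' @export
gin_config <- function(n_layers = 4L, hidden_channels = 8L, kernel_size = 1L,
                       alpha = NULL, seed = NULL) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (hidden_channels < 1L) stop("hidden_channels must be >= 1")
  if (!(kernel_size %in% c(1L, 3L))) stop("kernel_size must be 1 or 3")
  if (!is.null(alpha) && (alpha < 0 || alpha > 1)) stop("alpha must be in [0, 1]")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_channels = as.integer(hidden_channels),
                 kernel_size = as.integer(kernel_size),
                 alpha = alpha, seed = seed),
            class = "dg_gin_config")
}

#' Sample a random shallow intensity-remapping network
#'
#' Draws fresh weights for the `n_layers` convolutions (He-scaled normal
#' initialisation, leaky-rectifier nonlinearities between layers, edge
#' replication at the borders so spatially constant inputs stay constant).
#' The network output is z-normalised and rescaled to the input's mean and
#' standard deviation, keeping augmented images in a trainable range.
#'
#' @param cfg a [gin_config()].
#' @return An object of class `dg_gin_network`; apply it with
#'   [gin_apply()].
#' @export
sample_gin_network <- function(cfg = gin_config()) {
  k <- cfg$kernel_size
  chans <- c(1L, rep(cfg$hidden_channels, max(cfg$n_layers - 1L, 0L)), 1L)
  if (cfg$n_layers == 1L) chans <- c(1L, 1L)
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    cin <- chans[l]; cout <- chans[l + 1L]
    fan_in <- cin * k^3
    layers[[l]] <- list(
      w = array(rnorm(cout * cin * k^3, sd = sqrt(2 / fan_in)),
                dim = c(cout, cin, k, k, k)),
      b = rnorm(cout, sd = 0.1))
  }
  structure(list(layers = layers, kernel_size = k), class = "dg_gin_network")
}

#' Apply a sampled GIN network to a volume
#'
#' @param net a [sample_gin_network()] result.
#' @param x a `dg_volume` or 3D array.
#' @return Remapped field of the same type and grid as `x`.
#' @export
gin_apply <- function(net, x) {
  arr <- if (inherits(x, "dg_volume")) x$data else x
  dm <- dim(arr)
  h <- array(arr, dim = c(1L, dm))
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    ly <- net$layers[[l]]
    h <- .cpp_conv3d_forward(h, dim(h), ly$w, dim(ly$w), ly$b, 1L)
    if (l < nl) h <- .lrelu(h, 0.2)
  }
  g <- array(h, dim = dm)
  gs <- sd(g)
  if (!is.finite(gs) || gs < 1e-8) {
    g <- array(mean(arr), dim = dm)  # degenerate (e.g. constant) input
  } else {
    g <- (g - mean(g)) / gs * sd(arr) + mean(arr)
  }
  if (inherits(x, "dg_volume")) as_volume(g, spacing = x$spacing, affine = x$affine)
  else g
}

#' GIN-augment a volume
#'
#' Draws a fresh random shallow network `g` and a blend weight `alpha`, and
#' returns the convex blend `alpha * g(x) + (1 - alpha) * x` on the grid of
#' `x`. With `cfg$alpha = 0` this is exactly `x`; with `cfg$alpha = 1` it is
#' exactly the remapped image.
#'
#' @param x a `dg_volume` or 3D array with finite values.
#' @param cfg a [gin_config()].
#' @return Augmented field of the same type and grid as `x`, with the drawn
#'   blend weight attached as attribute `"alpha"`.
#' @export
gin_augment <- function(x, cfg = gin_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  net <- sample_gin_network(cfg)
  alpha <- if (is.null(cfg$alpha)) runif(1) else cfg$alpha
  g <- gin_apply(net, x)
  if (inherits(x, "dg_volume")) {
    out <- as_volume(alpha * g$data + (1 - alpha) * x$data,
                     spacing = x$spacing, affine = x$affine)
  } else {
    out <- alpha * g + (1 - alpha) * x
  }
  attr(out, "alpha") <- alpha
  out
}

.lrelu <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
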