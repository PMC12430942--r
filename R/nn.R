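# Compact 3D encoder-decoder segmentation network with hand-written forward
# and backward passes. Three resolution levels (two 2x average-poolings), one
# 3x3x3 convolution block per level with instance normalisation and a leaky
# rectifier, nearest-neighbour upsampling with skip concatenation, and a
# softmax head. The backbone is deliberately small: the method under study
# lives in the input-feature pipeline and the adaptation loop, not in the
# backbone, and a compact network keeps the full pipeline trainable on a CPU.
#
# Parameters are a flat named list of arrays ("enc1.w", "in1.gamma", ...),
# which keeps the AdamW update and parameter-subset selection trivial.

.conv_fwd <- function(x, w, b) .cpp_conv3d_forward(x, dim(x), w, dim(w), b, 0L)
.conv_bwd <- function(x, w, gy) .cpp_conv3d_backward(x, dim(x), w, dim(w), gy, 0L)

.pool2 <- function(x) {
  d <- dim(x)
  x <- (x[, seq(1L, d[2L], 2L), , , drop = FALSE] +
        x[, seq(2L, d[2L], 2L), , , drop = FALSE]) / 2
  x <- (x[, , seq(1L, d[3L], 2L), , drop = FALSE] +
        x[, , seq(2L, d[3L], 2L), , drop = FALSE]) / 2
  (x[, , , seq(1L, d[4L], 2L), drop = FALSE] +
   x[, , , seq(2L, d[4L], 2L), drop = FALSE]) / 2
}

.pool2_bwd <- function(g) {
  d <- dim(g)
  g <- g[, rep(seq_len(d[2L]), each = 2L), , , drop = FALSE] / 2
  g <- g[, , rep(seq_len(d[3L]), each = 2L), , drop = FALSE] / 2
  g[, , , rep(seq_len(d[4L]), each = 2L), drop = FALSE] / 2
}

.up2 <- function(x) {
  d <- dim(x)
  x <- x[, rep(seq_len(d[2L]), each = 2L), , , drop = FALSE]
  x <- x[, , rep(seq_len(d[3L]), each = 2L), , drop = FALSE]
  x[, , , rep(seq_len(d[4L]), each = 2L), drop = FALSE]
}

.up2_bwd <- function(g) {
  d <- dim(g)
  g <- g[, seq(1L, d[2L], 2L), , , drop = FALSE] +
       g[, seq(2L, d[2L], 2L), , , drop = FALSE]
  g <- g[, , seq(1L, d[3L], 2L), , drop = FALSE] +
       g[, , seq(2L, d[3L], 2L), , drop = FALSE]
  g[, , , seq(1L, d[4L], 2L), drop = FALSE] +
    g[, , , seq(2L, d[4L], 2L), drop = FALSE]
}

.inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  C <- dim(x)[1L]
  flat <- matrix(x, nrow = C)
  mu <- rowMeans(flat)
  xc <- flat - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xn <- xc * inv
  out <- array(xn * gamma + beta, dim(x))
  list(out = out, xn = xn, inv = inv)
}

.inorm_bwd <- function(cache, gamma, gy) {
  C <- nrow(cache$xn)
  gyf <- matrix(gy, nrow = C)
  dxn <- gyf * gamma
  dgamma <- rowSums(gyf * cache$xn)
  dbeta <- rowSums(gyf)
  dx <- cache$inv * (dxn - rowMeans(dxn) - cache$xn * rowMeans(dxn * cache$xn))
  list(gx = array(dx, dim(gy)), ggamma = dgamma, gbeta = dbeta)
}

.lrelu_bwd <- function(pre, g, slope = 0.01) {
  g[pre < 0] <- g[pre < 0] * slope
  g
}

.softmax4 <- function(z) {
  K <- dim(z)[1L]
  zm <- matrix(z, nrow = K)
  mx <- zm[1L, ]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, zm[k, ])
  ez <- exp(sweep(zm, 2L, mx))
  array(sweep(ez, 2L, colSums(ez), `/`), dim(z))
}

# Backprop an upstream gradient on probabilities through the softmax.
.softmax_bwd <- function(p, gp) {
  K <- dim(p)[1L]
  pf <- matrix(p, nrow = K); gf <- matrix(gp, nrow = K)
  dot <- colSums(pf * gf)
  array(pf * sweep(gf, 2L, dot), dim(p))
}

#' Initialise the compact 3D segmentation network
#'
#' @param in_channels network input channels (1 for raw intensities, 12 for
#'   the self-similarity descriptor).
#' @param n_classes output classes including background.
#' @param base_filters channels of the first level (doubled below).
#' @param norm `"instance"` for instance normalisation (the `"batch"` alias
#'   behaves identically at batch size one) or `"none"`.
#' @return Flat named parameter list of class `dg_net_params`.
#' @export
net_init <- function(in_channels, n_classes, base_filters = 8L,
                     norm = c("none", "instance", "batch")) {
  norm <- match.arg(norm)
  f <- as.integer(base_filters); f2 <- 2L * f
  he <- function(cout, cin) {
    array(rnorm(cout * cin * 27, sd = sqrt(2 / (cin * 27))),
          dim = c(cout, cin, 3L, 3L, 3L))
  }
  p <- list()
  specs <- list(enc1 = c(f, in_channels), enc2 = c(f2, f), bott = c(f2, f2),
                dec2 = c(f2, 2L * f2), dec1 = c(f, f2 + f), head = c(n_classes, f))
  for (nm in names(specs)) {
    p[[paste0(nm, ".w")]] <- he(specs[[nm]][1L], specs[[nm]][2L])
    p[[paste0(nm, ".b")]] <- numeric(specs[[nm]][1L])
  }
  if (norm != "none") {
    widths <- c(in1 = f, in2 = f2, in3 = f2, in4 = f2, in5 = f)
    for (nm in names(widths)) {
      p[[paste0(nm, ".gamma")]] <- rep(1, widths[[nm]])
      p[[paste0(nm, ".beta")]] <- rep(0, widths[[nm]])
    }
  }
  attr(p, "norm") <- norm
  attr(p, "in_channels") <- as.integer(in_channels)
  attr(p, "n_classes") <- as.integer(n_classes)
  class(p) <- "dg_net_params"
  p
}

# One conv -> (instance norm) -> leaky ReLU block with cache.
.block_fwd <- function(p, x, conv, norm_name, use_norm) {
  z <- .conv_fwd(x, p[[paste0(conv, ".w")]], p[[paste0(conv, ".b")]])
  if (use_norm) {
    n <- .inorm_fwd(z, p[[paste0(norm_name, ".gamma")]], p[[paste0(norm_name, ".beta")]])
    h <- .lrelu(n$out)
    list(out = h, x = x, z = z, n = n, pre = n$out)
  } else {
    list(out = .lrelu(z), x = x, z = z, n = NULL, pre = z)
  }
}

.block_bwd <- function(p, cache, conv, norm_name, use_norm, gout, grads) {
  g <- .lrelu_bwd(cache$pre, gout)
  if (use_norm) {
    nb <- .inorm_bwd(cache$n, p[[paste0(norm_name, ".gamma")]], g)
    grads[[paste0(norm_name, ".gamma")]] <- grads[[paste0(norm_name, ".gamma")]] + nb$ggamma
    grads[[paste0(norm_name, ".beta")]] <- grads[[paste0(norm_name, ".beta")]] + nb$gbeta
    g <- nb$gx
  }
  cb <- .conv_bwd(cache$x, p[[paste0(conv, ".w")]], g)
  grads[[paste0(conv, ".w")]] <- grads[[paste0(conv, ".w")]] + cb$gw
  grads[[paste0(conv, ".b")]] <- grads[[paste0(conv, ".b")]] + cb$gb
  list(gx = cb$gx, grads = grads)
}

#' Forward pass of the segmentation network
#'
#' @param params a [net_init()] parameter list.
#' @param x channel-major input array (C x D x H x W); spatial extents must be
#'   multiples of 4.
#' @param want_cache keep intermediates for [net_backward()].
#' @return List with `probs` (softmax output, simplex per voxel), `logits`,
#'   and (optionally) `cache`.
#' @export
net_forward <- function(params, x, want_cache = FALSE) {
  if (length(dim(x)) != 4L) stop("input must be channel-major 4D")
  if (dim(x)[1L] != attr(params, "in_channels"))
    stop("input has ", dim(x)[1L], " channels but the network expects ",
         attr(params, "in_channels"))
  if (any(dim(x)[-1L] %% 4L != 0L))
    stop("spatial extent must be a multiple of 4")
  un <- attr(params, "norm") != "none"
  b1 <- .block_fwd(params, x, "enc1", "in1", un)
  p1 <- .pool2(b1$out)
  b2 <- .block_fwd(params, p1, "enc2", "in2", un)
  p2 <- .pool2(b2$out)
  b3 <- .block_fwd(params, p2, "bott", "in3", un)
  u2 <- .up2(b3$out)
  c2 <- .concat_ch(u2, b2$out)
  b4 <- .block_fwd(params, c2, "dec2", "in4", un)
  u1 <- .up2(b4$out)
  c1 <- .concat_ch(u1, b1$out)
  b5 <- .block_fwd(params, c1, "dec1", "in5", un)
  z <- .conv_fwd(b5$out, params[["head.w"]], params[["head.b"]])
  probs <- .softmax4(z)
  out <- list(probs = probs, logits = z)
  if (want_cache)
    out$cache <- list(b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5,
                      u_split = c(dim(u2)[1L], dim(u1)[1L]))
  out
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1L] + db[1L], da[-1L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}

#' Backward pass: gradients of a scalar loss with respect to all parameters
#'
#' @param params parameter list used in the forward pass.
#' @param fwd result of `net_forward(..., want_cache = TRUE)`.
#' @param grad_probs upstream gradient with respect to the softmax output
#'   (same shape as `fwd$probs`).
#' @return Named list of gradients matching `params`.
#' @export
net_backward <- function(params, fwd, grad_probs) {
  un <- attr(params, "norm") != "none"
  cache <- fwd$cache
  if (is.null(cache)) stop("forward pass was run without want_cache = TRUE")
  grads <- lapply(params, function(a) a * 0)
  gz <- .softmax_bwd(fwd$probs, grad_probs)
  hb <- .conv_bwd(cache$b5$out, params[["head.w"]], gz)
  grads[["head.w"]] <- grads[["head.w"]] + hb$gw
  grads[["head.b"]] <- grads[["head.b"]] + hb$gb
  r5 <- .block_bwd(params, cache$b5, "dec1", "in5", un, hb$gx, grads)
  grads <- r5$grads
  n_u1 <- cache$u_split[2L]
  g_u1 <- r5$gx[seq_len(n_u1), , , , drop = FALSE]
  g_b1skip <- r5$gx[-seq_len(n_u1), , , , drop = FALSE]
  g_b4 <- .up2_bwd(g_u1)
  r4 <- .block_bwd(params, cache$b4, "dec2", "in4", un, g_b4, grads)
  grads <- r4$grads
  n_u2 <- cache$u_split[1L]
  g_u2 <- r4$gx[seq_len(n_u2), , , , drop = FALSE]
  g_b2skip <- r4$gx[-seq_len(n_u2), , , , drop = FALSE]
  g_b3 <- .up2_bwd(g_u2)
  r3 <- .block_bwd(params, cache$b3, "bott", "in3", un, g_b3, grads)
  grads <- r3$grads
  g_b2 <- .pool2_bwd(r3$gx) + g_b2skip
  r2 <- .block_bwd(params, cache$b2, "enc2", "in2", un, g_b2, grads)
  grads <- r2$grads
  g_b1 <- .pool2_bwd(r2$gx) + g_b1skip
  r1 <- .block_bwd(params, cache$b1, "enc1", "in1", un, g_b1, grads)
  r1$grads
}

# ---- optimiser ------------------------------------------------------------

#' Initialise AdamW optimiser state for a parameter list
#' @param params a [net_init()] parameter list.
#' @return Opaque state list for [adamw_step()].
#' @export
adamw_init <- function(params) {
  list(m = lapply(params, function(a) a * 0),
       v = lapply(params, function(a) a * 0),
       t = 0L)
}

#' One decoupled-weight-decay Adam update
#'
#' @param params parameter list.
#' @param grads gradient list from [net_backward()].
#' @param state optimiser state from [adamw_init()].
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param beta1,beta2,eps Adam moment coefficients and stabiliser.
#' @param subset optional character vector of parameter names to update;
#'   all others are frozen.
#' @return List with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, subset = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- if (is.null(subset)) names(params) else intersect(names(params), subset)
  for (nm in upd) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Resolve a parameter-subset name to concrete parameter names
#'
#' `"all"` adapts everything, `"normalization_only"` just the instance-norm
#' scale/shift parameters, `"encoder_only"` the encoder and bottleneck blocks.
#'
#' @param params parameter list.
#' @param which `"all"`, `"normalization_only"` or `"encoder_only"`.
#' @return Character vector of parameter names.
#' @export
param_subset_names <- function(params, which = c("all", "normalization_only",
                                                 "encoder_only")) {
  which <- match.arg(which)
  nms <- names(params)
  switch(which,
         all = nms,
         normalization_only = grep("^in[0-9]+\\.", nms, value = TRUE),
         encoder_only = grep("^(enc[0-9]+|bott|in[123])\\.", nms, value = TRUE))
}

# Supervised Dice + cross-entropy loss on one patch, with gradient wrt probs.
# onehot: C x D x H x W target; probabilities from the softmax head.
.dice_ce_loss <- function(probs, onehot, eps = 1e-5) {
  C <- dim(probs)[1L]
  nvox <- prod(dim(probs)[-1L])
  pf <- matrix(probs, nrow = C); yf <- matrix(onehot, nrow = C)
  pc <- pmax(pf, 1e-12)
  ce <- -sum(yf * log(pc)) / nvox
  g_ce <- -(yf / pc) / nvox
  num <- 2 * rowSums(pf * yf) + eps
  den <- rowSums(pf^2 + yf^2) + eps
  dice <- 1 - mean(num / den)
  g_dice <- -(2 * yf * den - num * 2 * pf) / den^2 / C
  list(loss = ce + dice,
       grad_probs = array(g_ce + g_dice, dim(probs)))
}
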