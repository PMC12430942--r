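# Domain-generalised supervised pre-training: a pluggable input-feature
# pipeline (raw / GIN / SSC / GIN+SSC) in front of the compact 3D network,
# class-balanced patch sampling, and a Dice + cross-entropy objective.

#' Input feature pipeline
#'
#' `"none"` feeds raw intensities; `"gin"` applies the random-network
#' intensity augmentation at training time only; `"ssc"` feeds the 12-channel
#' self-similarity descriptor at both training and test time (it changes the
#' input channel count); `"gin+ssc"` composes them as SSC(GIN(x)) at training
#' time and SSC(x) at test time, so the augmentation enriches the descriptor
#' space seen during training.
#'
#' @param mode one of `"none"`, `"gin"`, `"ssc"`, `"gin+ssc"`.
#' @param gin_cfg a [gin_config()] for the GIN stage.
#' @param ssc_patch_size,ssc_patch_distance descriptor parameters.
#' @return An object of class `dg_feature_pipeline`.
#' @export
feature_pipeline <- function(mode = c("none", "gin", "ssc", "gin+ssc"),
                             gin_cfg = gin_config(),
                             ssc_patch_size = 1L, ssc_patch_distance = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, gin_cfg = gin_cfg,
                 ssc_patch_size = as.integer(ssc_patch_size),
                 ssc_patch_distance = as.integer(ssc_patch_distance),
                 in_channels = if (mode %in% c("ssc", "gin+ssc")) 12L else 1L),
            class = "dg_feature_pipeline")
}

#' Apply the feature pipeline to a volume
#'
#' Descriptor channels are z-scored per volume: the self-similarity values
#' live in a narrow band around 0.5 and need conditioning to train. Raw
#' intensities are fed unchanged — any per-volume statistic depends on how
#' much foreground the volume happens to contain, and normalising with it
#' would shift the class intensity levels from volume to volume.
#'
#' @param x a `dg_volume` or 3D array.
#' @param fp a [feature_pipeline()].
#' @param phase `"train"` (GIN active, freshly randomised) or `"test"`
#'   (GIN inactive).
#' @return Channel-major network input array (C x D x H x W).
#' @export
apply_feature_pipeline <- function(x, fp, phase = c("train", "test")) {
  phase <- match.arg(phase)
  arr <- if (inherits(x, "dg_volume")) x$data else x
  gin_on <- phase == "train" && fp$mode %in% c("gin", "gin+ssc")
  if (gin_on) arr <- gin_augment(arr, fp$gin_cfg)
  if (fp$mode %in% c("ssc", "gin+ssc"))
    .znorm_channels(.ssc_array(arr, fp$ssc_patch_size, fp$ssc_patch_distance))
  else array(arr, dim = c(1L, dim(arr)))
}

# Per-channel z-scoring over the volume; constant channels map to zero.
.znorm_channels <- function(inp) {
  C <- dim(inp)[1L]
  flat <- matrix(inp, nrow = C)
  mu <- rowMeans(flat)
  s <- sqrt(rowMeans(sweep(flat, 1L, mu)^2))
  s[s < 1e-8] <- 1
  array(sweep(flat, 1L, mu) / s, dim(inp))
}

# Class-balanced patch origin: pick a class present in the labels uniformly,
# then a random voxel of that class, and centre the patch there (clamped).
.balanced_patch_origin <- function(labels, patch) {
  dm <- dim(labels)
  present <- sort(unique(as.vector(labels)))
  cls <- present[sample.int(length(present), 1L)]
  vox <- which(labels == cls)
  v <- vox[sample.int(length(vox), 1L)] - 1L
  ctr <- c(v %% dm[1L],
           (v %/% dm[1L]) %% dm[2L],
           v %/% (dm[1L] * dm[2L]))
  org <- pmin(pmax(ctr - patch %/% 2L, 0L), dm - patch)
  as.integer(org)
}

.round_up4 <- function(n) as.integer((n + 3L) %/% 4L * 4L)

# Separable raised-cosine weight over a tile, strictly positive everywhere.
.tile_weight <- function(patch) {
  w1 <- function(n) 0.05 + 0.95 * sin(pi * (seq_len(n) - 0.5) / n)^2
  outer(outer(w1(patch[1L]), w1(patch[2L])), w1(patch[3L]))
}

.extract_patch4 <- function(arr4, org, patch) {
  arr4[, org[1L] + seq_len(patch[1L]), org[2L] + seq_len(patch[2L]),
       org[3L] + seq_len(patch[3L]), drop = FALSE]
}

#' Pre-train the segmentation network on labeled source volumes
#'
#' The fitting function of the package. Trains the compact 3D network with
#' the selected input features on the labeled source dataset using
#' class-balanced random patches and a Dice + cross-entropy loss (Adam).
#' Training is deterministic under `seed`.
#'
#' @param volumes list of `dg_volume` training images.
#' @param labels list of aligned `dg_label_map`s.
#' @param features feature mode, see [feature_pipeline()], or a ready
#'   `dg_feature_pipeline`.
#' @param classes ordered class ids including background; defaults to the ids
#'   present in the labels.
#' @param patch_size voxel triple, each a multiple of 4.
#' @param epochs training epochs.
#' @param patches_per_volume patches drawn per volume per epoch.
#' @param lr,weight_decay Adam learning rate and decoupled weight decay.
#' @param base_filters first-level channel count of the network.
#' @param norm normalisation layer: `"none"` (default), `"instance"` or the
#'   `"batch"` alias. The compact backbone trains the phantom tasks most
#'   reliably without per-patch normalisation, since small patches often
#'   cover a single structure and instance statistics then cancel the
#'   absolute-intensity cue.
#' @param seed integer seed controlling all training randomness.
#' @param verbose print the per-epoch loss.
#' @return A fitted model of class `dg_segnet` with the parameters, the
#'   feature pipeline, the configuration and the per-epoch loss trace.
#' @export
dg_pretrain <- function(volumes, labels, features = "none", classes = NULL,
                        patch_size = c(16L, 16L, 16L), epochs = 8L,
                        patches_per_volume = 2L, lr = 1e-3,
                        weight_decay = 1e-4, base_filters = 8L,
                        norm = "none", seed = 1L, verbose = FALSE) {
  if (!length(volumes)) stop("empty training set")
  if (length(volumes) != length(labels))
    stop("volumes and labels must have equal length")
  for (i in seq_along(volumes))
    if (!identical(dim(volumes[[i]]$data), dim(labels[[i]]$data)))
      stop("volume/label shape mismatch at sample ", i)
  fp <- if (inherits(features, "dg_feature_pipeline")) features
        else feature_pipeline(features)
  present <- sort(unique(unlist(lapply(labels, function(l) unique(as.vector(l$data))))))
  if (is.null(classes)) classes <- present
  classes <- as.integer(classes)
  if (length(setdiff(present, classes)))
    stop("labels contain ids outside the configured classes: ",
         paste(setdiff(present, classes), collapse = ", "))
  patch_size <- rep_len(as.integer(patch_size), 3L)
  if (any(patch_size %% 4L != 0L)) stop("patch_size must be multiples of 4")
  for (v in volumes)
    if (any(dim(v$data) < patch_size)) stop("patch does not fit inside a training volume")

  set.seed(seed)
  params <- net_init(fp$in_channels, length(classes), base_filters, norm)
  opt <- adamw_init(params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(volumes))
    losses <- c()
    for (i in ord) {
      # GIN (when enabled) is re-randomised per visit; SSC is computed on the
      # full volume before patch extraction so borders see true neighbourhoods.
      input <- apply_feature_pipeline(volumes[[i]], fp, phase = "train")
      for (r in seq_len(patches_per_volume)) {
        org <- .balanced_patch_origin(labels[[i]]$data, patch_size)
        xp <- .extract_patch4(input, org, patch_size)
        yp <- labels[[i]]$data[org[1L] + seq_len(patch_size[1L]),
                               org[2L] + seq_len(patch_size[2L]),
                               org[3L] + seq_len(patch_size[3L])]
        oh <- .one_hot(yp, classes)
        fwd <- net_forward(params, xp, want_cache = TRUE)
        l <- .dice_ce_loss(fwd$probs, oh)
        grads <- net_backward(params, fwd, l$grad_probs)
        st <- adamw_step(params, grads, opt, lr = lr, weight_decay = weight_decay)
        params <- st$params; opt <- st$state
        losses <- c(losses, l$loss)
      }
    }
    trace[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, trace[ep]))
  }
  structure(list(params = params, feature_pipeline = fp, classes = classes,
                 patch_size = patch_size, norm = norm,
                 loss_trace = trace,
                 config = list(epochs = epochs,
                               patches_per_volume = patches_per_volume,
                               lr = lr, weight_decay = weight_decay,
                               base_filters = base_filters, seed = seed,
                               n_train = length(volumes))),
            class = "dg_segnet")
}

#' @export
print.dg_segnet <- function(x, ...) {
  cat(sprintf("<dg_segnet> features '%s', %d classes, patch %s, %d parameters\n",
              x$feature_pipeline$mode, length(x$classes),
              paste(x$patch_size, collapse = "x"),
              sum(vapply(x$params, length, 1L))))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              length(x$loss_trace), utils::tail(x$loss_trace, 1L)))
  if (!is.null(x$tta_trace))
    cat(sprintf("  test-time adapted: %d steps, consistency loss %.4f -> %.4f\n",
                length(x$tta_trace), x$tta_trace[1L],
                utils::tail(x$tta_trace, 1L)))
  invisible(x)
}

#' @export
summary.dg_segnet <- function(object, ...) {
  print(object)
  cat("  per-epoch loss:", paste(sprintf("%.3f", object$loss_trace), collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.dg_segnet <- function(object, ...) object$params

#' Plot the training (and adaptation) loss trace
#' @param x a `dg_segnet`.
#' @param ... passed to [plot()].
#' @export
plot.dg_segnet <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
       xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Whole-volume prediction
#'
#' Applies the feature pipeline in test phase and runs the fully
#' convolutional network over the volume. Volumes up to `max_tile` voxels per
#' axis are predicted in a single forward pass; larger volumes are tiled with
#' 50% overlap and the overlapping softmax outputs are averaged. Extents are
#' padded to multiples of 4 by edge replication and cropped back.
#'
#' @param object a fitted `dg_segnet`.
#' @param newdata a `dg_volume`.
#' @param max_tile largest single-pass extent per axis (default 64).
#' @param input optional precomputed network input (channel-major array) to
#'   reuse across calls; overrides the feature pipeline.
#' @param ... unused.
#' @return A [probability_map()] over the volume grid.
#' @export
predict.dg_segnet <- function(object, newdata, max_tile = 64L, input = NULL, ...) {
  arr_dim <- dim(newdata$data)
  inp <- if (is.null(input))
    apply_feature_pipeline(newdata, object$feature_pipeline, phase = "test")
  else input
  dm <- dim(inp)[-1L]
  patch <- pmin(.round_up4(dm), max_tile)
  pad <- pmax(.round_up4(dm) - dm, 0L)
  if (any(pad > 0L)) {
    padded <- array(0, dim = c(dim(inp)[1L], dm + pad))
    padded[, seq_len(dm[1L]), seq_len(dm[2L]), seq_len(dm[3L])] <- inp
    for (ax in which(pad > 0L)) {
      # replicate the last in-bounds slab
      idx <- rep(dm[ax], pad[ax])
      if (ax == 1L) padded[, dm[1L] + seq_len(pad[1L]), , ] <- padded[, idx, , , drop = FALSE]
      if (ax == 2L) padded[, , dm[2L] + seq_len(pad[2L]), ] <- padded[, , idx, , drop = FALSE]
      if (ax == 3L) padded[, , , dm[3L] + seq_len(pad[3L])] <- padded[, , , idx, drop = FALSE]
    }
    inp <- padded
    dm <- dim(inp)[-1L]
  }
  stride <- pmax(patch %/% 2L, 1L)
  starts <- function(n, p, s) {
    if (n <= p) return(0L)
    st <- seq.int(0L, n - p, by = s)
    if (utils::tail(st, 1L) != n - p) st <- c(st, n - p)
    st
  }
  sx <- starts(dm[1L], patch[1L], stride[1L])
  sy <- starts(dm[2L], patch[2L], stride[2L])
  sz <- starts(dm[3L], patch[3L], stride[3L])
  K <- length(object$classes)
  acc <- array(0, dim = c(K, dm))
  cnt <- array(0, dim = dm)
  # centre-weighted tile averaging: down-weights tile borders, where the
  # truncated convolution context makes predictions least reliable
  wgt <- .tile_weight(patch)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    org <- c(ox, oy, oz)
    xp <- .extract_patch4(inp, org, patch)
    pr <- net_forward(object$params, xp)$probs
    ix <- org[1L] + seq_len(patch[1L]); iy <- org[2L] + seq_len(patch[2L])
    iz <- org[3L] + seq_len(patch[3L])
    for (k in seq_len(K)) pr[k, , , ] <- pr[k, , , ] * wgt
    acc[, ix, iy, iz] <- acc[, ix, iy, iz] + pr
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + wgt
  }
  for (k in seq_len(K)) acc[k, , , ] <- acc[k, , , ] / cnt
  acc <- acc[, seq_len(arr_dim[1L]), seq_len(arr_dim[2L]), seq_len(arr_dim[3L]),
             drop = FALSE]
  probability_map(acc, object$classes, spacing = newdata$spacing,
                  affine = newdata$affine)
}

#' Hard segmentation from a fitted model
#'
#' Convenience wrapper: [predict.dg_segnet()] followed by per-voxel argmax.
#'
#' @param object a fitted `dg_segnet`.
#' @param newdata a `dg_volume`.
#' @param ... passed to [predict.dg_segnet()].
#' @return A [label_map()].
#' @export
segment <- function(object, newdata, ...) {
  pm <- predict(object, newdata, ...)
  label_map(.argmax_labels(pm$data, object$classes),
            class_ids = setdiff(object$classes, 0L),
            spacing = newdata$spacing, affine = newdata$affine)
}

#' Save / load a model checkpoint
#'
#' Checkpoints serialise the parameters, feature pipeline and configuration;
#' reloading reproduces predictions bit-exactly.
#'
#' @param model a `dg_segnet`.
#' @param path checkpoint file path.
#' @return `dg_save` returns `path` invisibly; `dg_load` the model.
#' @export
dg_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname dg_save
#' @export
dg_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dg_segnet")) stop("not a dg_segnet checkpoint: ", path)
  m
}
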