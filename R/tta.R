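# Source-free per-sample test-time adaptation. For a single unlabeled target
# volume, each optimisation step draws random patches, pushes two differently
# spatially-augmented views of every patch through the network, inverse-warps
# the two softmax outputs back to the common frame, masks inversion artifacts,
# and minimises the consistency Dice loss. Gradients are accumulated over the
# patches into exactly one AdamW update per step; by default only branch A
# backpropagates (branch B acts as a fixed target), both branches are
# spatially augmented, and intensity augmentation is off — the configuration
# found to be the best trade-off between conventionally and domain-generalized
# pre-trained models.

#' Test-time adaptation configuration
#'
#' Defaults follow the published optimisation strategy: AdamW with learning
#' rate 1e-5 and weight decay 0.01, no scheduling, exactly 12 steps, gradients
#' accumulated over 16 randomly drawn patches per step, an ensemble of three
#' models, backpropagation through branch A only, affine spatial augmentation
#' in both branches, and no intensity augmentation during adaptation.
#'
#' @param learning_rate AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param steps number of optimisation steps.
#' @param patches_per_step patches whose gradients are accumulated per step.
#' @param ensemble_size models in the final inference ensemble.
#' @param grad_branches which branches backpropagate: `"A"`, `"B"` or `"AB"`.
#' @param intensity_aug apply GIN intensity augmentation inside the branches.
#' @param spatial_aug_branches branches receiving affine spatial augmentation.
#' @param parameter_subset `"all"`, `"normalization_only"` or `"encoder_only"`.
#' @param loss a [dice_loss_config()].
#' @param spatial an [affine_ranges()].
#' @param patch_size adaptation patch size; defaults to the training patch.
#' @param seed optional integer seed for the adaptation randomness.
#' @return An object of class `dg_tta_config`.
#' @export
tta_config <- function(learning_rate = 1e-5, weight_decay = 0.01,
                       steps = 12L, patches_per_step = 16L,
                       ensemble_size = 3L,
                       grad_branches = c("A", "B", "AB"),
                       intensity_aug = FALSE,
                       spatial_aug_branches = c("AB", "A", "B", "none"),
                       parameter_subset = c("all", "normalization_only",
                                            "encoder_only"),
                       loss = dice_loss_config(), spatial = affine_ranges(),
                       patch_size = NULL, seed = NULL) {
  grad_branches <- match.arg(grad_branches)
  spatial_aug_branches <- match.arg(spatial_aug_branches)
  parameter_subset <- match.arg(parameter_subset)
  if (steps < 1L || patches_per_step < 1L) stop("steps and patches_per_step must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 steps = as.integer(steps),
                 patches_per_step = as.integer(patches_per_step),
                 ensemble_size = as.integer(ensemble_size),
                 grad_branches = grad_branches, intensity_aug = intensity_aug,
                 spatial_aug_branches = spatial_aug_branches,
                 parameter_subset = parameter_subset, loss = loss,
                 spatial = spatial, patch_size = patch_size, seed = seed),
            class = "dg_tta_config")
}

# Draw the per-step randomness: patch origins (uniform over valid origins —
# no labels exist at test time, so no foreground bias) and one affine pair
# per patch for the enabled branches.
.draw_tta_plan <- function(input_dim, patch, cfg) {
  lapply(seq_len(cfg$patches_per_step), function(i) {
    org <- vapply(1:3, function(ax) {
      hi <- input_dim[ax] - patch[ax]
      if (hi <= 0L) 0L else sample.int(hi + 1L, 1L) - 1L
    }, 1L)
    t_a <- if (cfg$spatial_aug_branches %in% c("A", "AB"))
      sample_affine(patch, cfg$spatial) else identity_affine(patch)
    t_b <- if (cfg$spatial_aug_branches %in% c("B", "AB"))
      sample_affine(patch, cfg$spatial) else identity_affine(patch)
    list(origin = as.integer(org), t_a = t_a, t_b = t_b)
  })
}

.branch_intensity_aug <- function(xp, cfg) {
  if (!cfg$intensity_aug) return(xp)
  # One freshly sampled remapping network, applied channel-wise.
  net <- sample_gin_network(cfg$gin_cfg %||% gin_config())
  alpha <- runif(1)
  for (c in seq_len(dim(xp)[1L])) {
    ch <- array(xp[c, , , ], dim(xp)[-1L])
    xp[c, , , ] <- alpha * gin_apply(net, ch) + (1 - alpha) * ch
  }
  xp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Loss and parameter gradient contributed by one patch of the plan.
# Returns NULL loss when the consistency mask is empty.
.tta_patch_eval <- function(params, input, entry, cfg, loss_scale = 1) {
  patch <- entry$patch
  xp <- .extract_patch4(input, entry$origin, patch)
  grad_a <- cfg$grad_branches %in% c("A", "AB")
  grad_b <- cfg$grad_branches %in% c("B", "AB")
  xa <- .warp_array(xp, entry$t_a$matrix)
  xb <- .warp_array(xp, entry$t_b$matrix)
  fa <- net_forward(params, .branch_intensity_aug(xa$data, cfg),
                    want_cache = grad_a)
  fb <- net_forward(params, .branch_intensity_aug(xb$data, cfg),
                    want_cache = grad_b)
  # validity of the forward-warped inputs propagates through the inversion:
  # network outputs over fill regions carry no real image content
  wa <- .warp_array(fa$probs, entry$t_a$inverse_matrix, structure = TRUE,
                    src_valid = xa$valid)
  wb <- .warp_array(fb$probs, entry$t_b$inverse_matrix, structure = TRUE,
                    src_valid = xb$valid)
  m <- wa$valid & wb$valid
  if (!any(m)) return(NULL)
  dl <- consistency_dice(wa$data, wb$data, mask = m, cfg = cfg$loss, grad = TRUE)
  grads <- NULL
  bp <- function(fwd, wstr, gwarped) {
    C <- dim(gwarped)[1L]
    gp <- array(0, dim(fwd$probs))
    for (c in seq_len(C)) {
      gch <- as.vector(gwarped[c, , , ]) * loss_scale
      gp[c, , , ] <- .scatter_trilinear(gch, wstr, dim(fwd$probs)[-1L])
    }
    net_backward(params, fwd, gp)
  }
  if (grad_a) grads <- bp(fa, wa$structure, dl$grad_a)
  if (grad_b) {
    gb <- bp(fb, wb$structure, dl$grad_b)
    grads <- if (is.null(grads)) gb else mapply(`+`, grads, gb, SIMPLIFY = FALSE)
  }
  list(loss = dl$loss, grads = grads)
}

#' Accumulated or batched gradients of the mean patch consistency loss
#'
#' Two algebraically equivalent routes to the gradient of the mean loss over
#' a fixed patch plan: `"accumulate"` computes each patch's full gradient and
#' averages afterwards; `"batched"` scales each patch's loss-level gradient by
#' `1 / n` before backpropagation and sums. Exposed so the equivalence can be
#' verified directly.
#'
#' @param model a fitted `dg_segnet`.
#' @param input channel-major network input of the target volume.
#' @param plan patch/transform plan as drawn inside [tta_step()].
#' @param cfg a [tta_config()].
#' @param mode `"accumulate"` or `"batched"`.
#' @return List with `loss` (mean over the plan) and `grads`.
#' @export
tta_gradients <- function(model, input, plan, cfg,
                          mode = c("accumulate", "batched")) {
  mode <- match.arg(mode)
  n <- length(plan)
  total <- NULL
  losses <- numeric(0)
  for (entry in plan) {
    entry$patch <- entry$t_a$dim
    ev <- .tta_patch_eval(model$params, input, entry, cfg,
                          loss_scale = if (mode == "batched") 1 / n else 1)
    if (is.null(ev)) { losses <- c(losses, 0); next }
    losses <- c(losses, ev$loss)
    if (!is.null(ev$grads))
      total <- if (is.null(total)) ev$grads
               else mapply(`+`, total, ev$grads, SIMPLIFY = FALSE)
  }
  if (!is.null(total) && mode == "accumulate")
    total <- lapply(total, function(g) g / n)
  list(loss = if (length(losses)) sum(losses) / n else NA_real_, grads = total,
       n_effective = sum(losses != 0))
}

#' One test-time adaptation step
#'
#' Draws `patches_per_step` random patches, accumulates their consistency
#' gradients and applies exactly one AdamW update restricted to the configured
#' parameter subset. If every patch yields an empty consistency mask the step
#' is skipped with a warning.
#'
#' @param model a `dg_segnet`.
#' @param input precomputed channel-major network input of the target volume.
#' @param cfg a [tta_config()].
#' @param opt AdamW state from [adamw_init()].
#' @return List with updated `model`, `opt` and the step `loss`.
#' @export
tta_step <- function(model, input, cfg, opt) {
  patch <- rep_len(as.integer(cfg$patch_size %||% model$patch_size), 3L)
  plan <- .draw_tta_plan(dim(input)[-1L], patch, cfg)
  g <- tta_gradients(model, input, plan, cfg, mode = "accumulate")
  if (is.null(g$grads)) {
    warning("all patches yielded empty consistency masks; step skipped")
    return(list(model = model, opt = opt, loss = g$loss))
  }
  subset <- param_subset_names(model$params, cfg$parameter_subset)
  st <- adamw_step(model$params, g$grads, opt, lr = cfg$learning_rate,
                   weight_decay = cfg$weight_decay, subset = subset)
  attrs <- attributes(model$params)
  model$params <- st$params
  attributes(model$params) <- attrs
  list(model = model, opt = st$state, loss = g$loss)
}

#' Adapt a pre-trained model to one unlabeled target volume
#'
#' Runs exactly `cfg$steps` optimisation steps of [tta_step()] on a copy of
#' the model; the input model object is not modified, and the adaptation
#' never sees any training data (it accepts only the model and the single
#' target volume). The adapted copy carries the per-step consistency loss
#' trace in `$tta_trace`.
#'
#' @param model a fitted `dg_segnet`.
#' @param x_t the single target `dg_volume` (preprocessed like the training
#'   inputs, e.g. resampled to the training spacing).
#' @param cfg a [tta_config()].
#' @return The adapted `dg_segnet`.
#' @export
tta_adapt <- function(model, x_t, cfg = tta_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  input <- apply_feature_pipeline(x_t, model$feature_pipeline, phase = "test")
  adapted <- model
  opt <- adamw_init(adapted$params)
  trace <- numeric(cfg$steps)
  for (s in seq_len(cfg$steps)) {
    st <- tta_step(adapted, input, cfg, opt)
    adapted <- st$model; opt <- st$opt
    trace[s] <- st$loss
  }
  adapted$tta_trace <- trace
  adapted$tta_config <- cfg
  adapted
}

#' Adapt an ensemble and predict the final segmentation
#'
#' Each model is adapted independently on the target volume (independent
#' random streams derived from `cfg$seed`), the adapted softmax outputs are
#' averaged, and the per-voxel argmax yields the final label map. The adapted
#' weights are discarded; only the prediction persists.
#'
#' @param models list of independently pre-trained `dg_segnet`s.
#' @param x_t the target `dg_volume`.
#' @param cfg a [tta_config()].
#' @return A [label_map()] over the target grid.
#' @export
adapt_and_predict_ensemble <- function(models, x_t, cfg = tta_config()) {
  if (!length(models)) stop("ensemble of size 0")
  acc <- NULL
  classes <- models[[1L]]$classes
  for (i in seq_along(models)) {
    cfg_i <- cfg
    if (!is.null(cfg$seed)) cfg_i$seed <- cfg$seed + i - 1L
    ad <- tta_adapt(models[[i]], x_t, cfg_i)
    pm <- predict(ad, x_t)
    acc <- if (is.null(acc)) pm$data else acc + pm$data
  }
  acc <- acc / length(models)
  label_map(.argmax_labels(acc, classes), class_ids = setdiff(classes, 0L),
            spacing = x_t$spacing, affine = x_t$affine)
}
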