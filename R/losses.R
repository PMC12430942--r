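# Consistency Dice loss between two re-aligned branch predictions. With
# exponent d = 2 in the denominator, identical predictions incur exactly zero
# loss (the loss landscape is zero along the diagonal); with d = 1 the loss
# additionally rewards confident (binary) predictions, which is not wanted
# when the two branches are both soft.

#' Consistency Dice loss configuration
#'
#' @param exponent_d denominator exponent, 1 or 2 (default 2).
#' @param epsilon small positive stabiliser added to numerator and denominator.
#' @param class_subset class ids entering the loss; `NULL` (default) means all
#'   foreground classes (the background channel is excluded).
#' @return An object of class `dg_dice_config`.
#' @export
dice_loss_config <- function(exponent_d = 2L, epsilon = 1e-5, class_subset = NULL) {
  if (!(exponent_d %in% c(1L, 2L))) stop("exponent_d must be 1 or 2")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(exponent_d = as.integer(exponent_d), epsilon = epsilon,
                 class_subset = class_subset),
            class = "dg_dice_config")
}

# Resolve which channel indices of a probability map enter the loss.
.loss_channels <- function(class_ids, cfg) {
  if (is.null(cfg$class_subset)) {
    ch <- which(class_ids != 0L)
    if (!length(ch)) ch <- seq_along(class_ids)
  } else {
    ch <- match(cfg$class_subset, class_ids)
    if (anyNA(ch)) stop("class_subset contains ids absent from the map")
  }
  ch
}

#' Masked consistency Dice loss between two probability maps
#'
#' Computes `1 - mean_C[(2 * sum(a*b) + e) / (sum(a^d + b^d) + e)]` over the
#' selected channels, with all voxel sums restricted to the consistency mask.
#' An empty mask yields zero loss with a warning (no voxels to compare).
#'
#' @param y_a,y_b `dg_prob_map`s (or channel-major arrays) on one grid.
#' @param mask logical array / [consistency_mask()]; `NULL` means all voxels.
#' @param cfg a [dice_loss_config()].
#' @param grad also return gradients of the loss with respect to `y_a` and
#'   `y_b` (channel-major arrays, zero outside the mask).
#' @return Scalar loss, or (with `grad = TRUE`) a list with `loss`,
#'   `grad_a`, `grad_b`.
#' @export
consistency_dice <- function(y_a, y_b, mask = NULL, cfg = dice_loss_config(),
                             grad = FALSE) {
  a <- if (inherits(y_a, "dg_prob_map")) y_a$data else y_a
  b <- if (inherits(y_b, "dg_prob_map")) y_b$data else y_b
  if (!identical(dim(a), dim(b))) stop("probability maps must share one shape")
  class_ids <- if (inherits(y_a, "dg_prob_map")) y_a$class_ids
               else seq_len(dim(a)[1L]) - 1L
  ch <- .loss_channels(class_ids, cfg)
  C <- dim(a)[1L]
  nvox <- prod(dim(a)[-1L])
  m <- if (is.null(mask)) rep(TRUE, nvox) else {
    if (!identical(dim(unclass(mask)), dim(a)[-1L])) stop("mask shape mismatch")
    as.vector(mask)
  }
  if (!any(m)) {
    warning("empty consistency mask: no voxels to compare, returning zero loss")
    if (!grad) return(0)
    z <- array(0, dim(a))
    return(list(loss = 0, grad_a = z, grad_b = z))
  }
  af <- matrix(a, nrow = C)[, m, drop = FALSE]
  bf <- matrix(b, nrow = C)[, m, drop = FALSE]
  d <- cfg$exponent_d; e <- cfg$epsilon
  num <- 2 * rowSums(af * bf) + e
  den <- rowSums(af^d + bf^d) + e
  loss <- 1 - mean(num[ch] / den[ch])
  if (!grad) return(loss)
  ga <- matrix(0, C, sum(m)); gb <- matrix(0, C, sum(m))
  k <- length(ch)
  for (c in ch) {
    # d/da of -(num/den)/k : quotient rule per masked voxel
    dnum_a <- 2 * bf[c, ]; dnum_b <- 2 * af[c, ]
    dden_a <- d * af[c, ]^(d - 1); dden_b <- d * bf[c, ]^(d - 1)
    ga[c, ] <- -(dnum_a * den[c] - num[c] * dden_a) / den[c]^2 / k
    gb[c, ] <- -(dnum_b * den[c] - num[c] * dden_b) / den[c]^2 / k
  }
  grad_a <- matrix(0, C, nvox); grad_b <- matrix(0, C, nvox)
  grad_a[, m] <- ga; grad_b[, m] <- gb
  list(loss = loss, grad_a = array(grad_a, dim(a)), grad_b = array(grad_b, dim(a)))
}

#' Assembled test-time consistency loss for two branch outputs
#'
#' Inverse-warps both branch predictions back to the unaugmented frame,
#' intersects the two validity masks into the consistency mask, and evaluates
#' [consistency_dice()] on the masked, re-aligned fields.
#'
#' @param model_out_a,model_out_b `dg_prob_map`s (or channel-major arrays)
#'   predicted from the two augmented views of one region.
#' @param aug_a,aug_b the `dg_affine` transforms that produced the views.
#' @param cfg a [dice_loss_config()].
#' @return Scalar loss value.
#' @export
tta_loss <- function(model_out_a, model_out_b, aug_a, aug_b,
                     cfg = dice_loss_config()) {
  a <- if (inherits(model_out_a, "dg_prob_map")) model_out_a$data else model_out_a
  b <- if (inherits(model_out_b, "dg_prob_map")) model_out_b$data else model_out_b
  dm <- dim(a)[-1L]
  wa <- .warp_array(a, aug_a$inverse_matrix,
                    src_valid = .affine_valid_mask(aug_a$matrix, dm))
  wb <- .warp_array(b, aug_b$inverse_matrix,
                    src_valid = .affine_valid_mask(aug_b$matrix, dm))
  m <- consistency_mask(wa$valid, wb$valid)
  class_ids <- if (inherits(model_out_a, "dg_prob_map")) model_out_a$class_ids
               else seq_len(dim(a)[1L]) - 1L
  consistency_dice(probability_map(pmin(pmax(wa$data, 0), 1), class_ids),
                   probability_map(pmin(pmax(wb$data, 0), 1), class_ids),
                   mask = m, cfg = cfg)
}
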