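# Segmentation quality metrics: per-class Dice overlap (percent), the 95th
# percentile of the symmetric surface distance set (HD95, mm), and one-sided
# paired Wilcoxon signed-rank testing of score improvements.

#' Dice overlap between prediction and ground truth for one class
#'
#' `100 * 2|P & G| / (|P| + |G|)`. When the class is absent from both maps
#' the score is defined as 100 (flagged with attribute `"both_empty"`); when
#' it is absent from exactly one, the score is 0.
#'
#' @param pred,gt `dg_label_map`s (or integer arrays) on one grid.
#' @param class_id class to score.
#' @return Dice percentage in `[0, 100]`.
#' @export
dice_score <- function(pred, gt, class_id) {
  p <- if (inherits(pred, "dg_label_map")) pred$data else pred
  g <- if (inherits(gt, "dg_label_map")) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("prediction and ground truth grids differ")
  pm <- p == class_id; gm <- g == class_id
  np <- sum(pm); ng <- sum(gm)
  if (np == 0L && ng == 0L) return(structure(100, both_empty = TRUE))
  100 * 2 * sum(pm & gm) / (np + ng)
}

# Boundary voxels of a binary mask: mask voxels with at least one 6-neighbour
# outside the mask (volume edges count as outside).
.surface_voxels <- function(mask) {
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[1L + seq_len(dm[1L]), 1L + seq_len(dm[2L]), 1L + seq_len(dm[3L])] <- mask
  interior <- pad[seq_len(dm[1L]), 1L + seq_len(dm[2L]), 1L + seq_len(dm[3L])] &
    pad[2L + seq_len(dm[1L]), 1L + seq_len(dm[2L]), 1L + seq_len(dm[3L])] &
    pad[1L + seq_len(dm[1L]), seq_len(dm[2L]), 1L + seq_len(dm[3L])] &
    pad[1L + seq_len(dm[1L]), 2L + seq_len(dm[2L]), 1L + seq_len(dm[3L])] &
    pad[1L + seq_len(dm[1L]), 1L + seq_len(dm[2L]), seq_len(dm[3L])] &
    pad[1L + seq_len(dm[1L]), 1L + seq_len(dm[2L]), 2L + seq_len(dm[3L])]
  which(mask & !interior, arr.ind = TRUE)
}

# Minimum Euclidean distance from each row of `a` to the point set `b`
# (both n x 3, physical mm), chunked to bound memory.
.min_dists <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  bt <- t(b)
  bsq <- colSums(bt^2)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), bsq, `+`) - 2 * blk %*% bt
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' 95th percentile Hausdorff distance for one class, in mm
#'
#' Surfaces are the boundary voxels of the binary class masks; distances from
#' the prediction surface to the ground-truth surface and vice versa are
#' pooled, and the 95th percentile (linear interpolation between order
#' statistics) of the pooled set is returned in physical units. When the
#' class is absent from either map the distance is undefined and `NA` is
#' returned (such cases are excluded from means, with the count reported).
#'
#' @param pred,gt `dg_label_map`s (or integer arrays) on one grid.
#' @param class_id class to score.
#' @param spacing voxel size in mm; defaults to the prediction's spacing.
#' @return HD95 in mm, or `NA` when undefined.
#' @export
hd95 <- function(pred, gt, class_id, spacing = NULL) {
  p <- if (inherits(pred, "dg_label_map")) pred$data else pred
  g <- if (inherits(gt, "dg_label_map")) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("prediction and ground truth grids differ")
  if (is.null(spacing))
    spacing <- if (inherits(pred, "dg_label_map")) pred$spacing else c(1, 1, 1)
  pm <- p == class_id; gm <- g == class_id
  if (!any(pm) || !any(gm)) return(NA_real_)
  sp <- .surface_voxels(pm); sg <- .surface_voxels(gm)
  a <- sweep(sp, 2L, spacing, `*`)
  b <- sweep(sg, 2L, spacing, `*`)
  pooled <- c(.min_dists(a, b), .min_dists(b, a))
  as.numeric(quantile(pooled, 0.95, type = 7))
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests the alternative "`scores_b` is greater than `scores_a`" on paired
#' samples. When every difference is zero the test is degenerate and `p = 1`
#' is returned.
#'
#' @param scores_a,scores_b paired numeric vectors of equal length (>= 5).
#' @return List with `p_value` and significance `stars`
#'   (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @export
wilcoxon_one_sided <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("paired samples differ in length")
  if (length(scores_a) < 5L) stop("need at least 5 pairs")
  if (all(scores_b == scores_a)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(scores_b, scores_a, paired = TRUE,
                  alternative = "greater")$p.value)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(p_value = p, stars = stars)
}

#' Evaluate a set of predicted segmentations
#'
#' Per-class Dice (percent) and HD95 (mm) for each sample, plus per-class and
#' overall means. Classes absent from both maps contribute Dice 100 (flagged);
#' classes absent from one side have undefined HD95 and are excluded from
#' HD95 means, with the exclusion count reported.
#'
#' @param preds,gts lists of `dg_label_map`s (or a single pair).
#' @param class_ids classes to score; defaults to the ground-truth classes.
#' @param spacing voxel spacing in mm; defaults to each ground truth's.
#' @return An object of class `dg_eval`: a list with `per_sample`
#'   (data.frame: sample, class, dice_pct, hd95_mm), `per_class_dice`,
#'   `per_class_hd95`, `mean_dice`, `mean_hd95`, `n_samples`,
#'   `n_hd95_undefined`.
#' @export
evaluate_segmentation <- function(preds, gts, class_ids = NULL, spacing = NULL) {
  if (inherits(preds, "dg_label_map")) preds <- list(preds)
  if (inherits(gts, "dg_label_map")) gts <- list(gts)
  if (length(preds) != length(gts)) stop("prediction/ground-truth count mismatch")
  if (is.null(class_ids)) class_ids <- gts[[1L]]$class_ids
  rows <- list()
  for (i in seq_along(preds)) {
    sp <- spacing %||% gts[[i]]$spacing
    for (k in class_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = i, class = k,
        dice_pct = as.numeric(dice_score(preds[[i]], gts[[i]], k)),
        hd95_mm = hd95(preds[[i]], gts[[i]], k, spacing = sp))
    }
  }
  tab <- do.call(rbind, rows)
  per_class_dice <- tapply(tab$dice_pct, tab$class, mean)
  per_class_hd95 <- tapply(tab$hd95_mm, tab$class, mean, na.rm = TRUE)
  structure(list(per_sample = tab,
                 per_class_dice = per_class_dice,
                 per_class_hd95 = per_class_hd95,
                 mean_dice = mean(tab$dice_pct),
                 mean_hd95 = mean(tab$hd95_mm, na.rm = TRUE),
                 n_samples = length(preds),
                 n_hd95_undefined = sum(is.na(tab$hd95_mm))),
            class = "dg_eval")
}

#' @export
print.dg_eval <- function(x, ...) {
  cat(sprintf("<dg_eval> %d samples: mean Dice %.1f%%, mean HD95 %.2f mm (%d undefined)\n",
              x$n_samples, x$mean_dice, x$mean_hd95, x$n_hd95_undefined))
  cat("  per-class Dice:",
      paste(sprintf("%s=%.1f", names(x$per_class_dice), x$per_class_dice),
            collapse = "  "), "\n")
  invisible(x)
}
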