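test_that("Dice matches hand counts and handles empty sets", {
  dm <- c(16, 16, 16)
  gt <- array(0L, dm); gt[1:8, 1:8, 1:8] <- 1L
  pred <- array(0L, dm); pred[5:12, 1:8, 1:8] <- 1L  # half-overlapping 8^3 cubes
  expect_equal(dice_score(pred, gt, 1L), 50)
  expect_equal(dice_score(gt, gt, 1L), 100)
  expect_equal(dice_score(pred, gt, 1L), dice_score(gt, pred, 1L))
  disj <- array(0L, dm); disj[9:16, 9:16, 9:16] <- 1L
  expect_equal(dice_score(disj, gt, 1L), 0)
  both_empty <- dice_score(pred, gt, 5L)
  expect_equal(as.numeric(both_empty), 100)
  expect_true(attr(both_empty, "both_empty"))
  expect_equal(dice_score(pred, array(0L, dm), 1L), 0)
  expect_error(dice_score(pred, array(0L, c(8, 8, 8)), 1L), "differ")
})

test_that("HD95 matches analytic distances and physical units", {
  dm <- c(10, 10, 10)
  a <- array(0L, dm); a[, , 3] <- 1L
  b <- array(0L, dm); b[, , 5] <- 1L   # parallel planes two voxels apart
  expect_equal(hd95(a, b, 1L, spacing = c(1.5, 1.5, 1.5)), 3.0)
  expect_equal(hd95(a, b, 1L, spacing = c(1, 1, 1)), 2.0)
  expect_equal(hd95(a, a, 1L, spacing = c(1, 1, 1)), 0)
  expect_true(is.na(hd95(a, array(0L, dm), 1L, spacing = c(1, 1, 1))))
  expect_equal(hd95(a, b, 1L, spacing = c(1.5, 1.5, 1.5)),
               hd95(b, a, 1L, spacing = c(1.5, 1.5, 1.5)))
})

test_that("HD95 agrees with an all-pairs brute-force oracle on random blobs", {
  set.seed(50)
  dm <- c(12, 12, 12)
  for (r in 1:3) {
    a <- array(0L, dm); b <- array(0L, dm)
    ca <- sample(4:9, 3); cb <- sample(4:9, 3)
    for (i in 1:12) for (j in 1:12) for (k in 1:12) {
      if (sum((c(i, j, k) - ca)^2) <= 9) a[i, j, k] <- 1L
      if (sum((c(i, j, k) - cb)^2) <= 16) b[i, j, k] <- 1L
    }
    spacing <- c(1.5, 1.5, 1.5)
    got <- hd95(a, b, 1L, spacing = spacing)
    # independent oracle: explicit surface extraction + full distance matrix
    surf <- function(m) {
      keep <- matrix(0L, 0, 3)
      for (i in 1:12) for (j in 1:12) for (k in 1:12) {
        if (m[i, j, k] == 0) next
        nb <- c(if (i > 1) m[i - 1, j, k] else 0L, if (i < 12) m[i + 1, j, k] else 0L,
                if (j > 1) m[i, j - 1, k] else 0L, if (j < 12) m[i, j + 1, k] else 0L,
                if (k > 1) m[i, j, k - 1] else 0L, if (k < 12) m[i, j, k + 1] else 0L,
                if (i == 1 || i == 12 || j == 1 || j == 12 || k == 1 || k == 12) 0L)
        if (any(nb == 0L)) keep <- rbind(keep, c(i, j, k))
      }
      sweep(keep, 2, spacing, `*`)
    }
    sa <- surf(a); sb <- surf(b)
    dmat <- as.matrix(dist(rbind(sa, sb)))[seq_len(nrow(sa)),
                                           nrow(sa) + seq_len(nrow(sb))]
    pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
    expect_equal(got, as.numeric(quantile(pooled, 0.95)), tolerance = 1e-6)
  }
})

test_that("one-sided signed-rank test detects direction and degeneracy", {
  a <- c(10, 12, 9, 14, 11, 13, 10, 12, 11, 9)
  w <- wilcoxon_one_sided(a, a + 1)
  expect_lt(w$p_value, 0.01)
  expect_true(w$stars %in% c("**", "***"))
  expect_equal(wilcoxon_one_sided(a, a)$p_value, 1)
  flip <- wilcoxon_one_sided(a + 1, a)
  expect_gt(flip$p_value, 0.9)
  expect_error(wilcoxon_one_sided(a, a[1:5]), "length")
  expect_error(wilcoxon_one_sided(a[1:3], a[1:3]), "at least 5")
})

test_that("evaluation aggregates per-class scores and flags undefined distances", {
  set.seed(51)
  dm <- c(12, 12, 12)
  gt <- array(0L, dm); gt[3:6, 3:6, 3:6] <- 1L; gt[8:11, 8:11, 8:11] <- 2L
  pred <- array(0L, dm); pred[3:6, 3:6, 4:7] <- 1L   # class 2 entirely missed
  gtm <- label_map(gt, spacing = c(1.5, 1.5, 1.5))
  prm <- label_map(pred, class_ids = 1:2, spacing = c(1.5, 1.5, 1.5))
  ev <- evaluate_segmentation(prm, gtm)
  expect_s3_class(ev, "dg_eval")
  expect_equal(nrow(ev$per_sample), 2L)
  expect_equal(ev$per_sample$dice_pct[1], 75)  # 4^3 cubes shifted by 1 voxel
  expect_equal(ev$per_sample$dice_pct[2], 0)
  expect_equal(ev$n_hd95_undefined, 1L)
  expect_output(print(ev), "mean Dice")
})
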