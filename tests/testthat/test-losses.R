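test_that("squared-denominator loss is zero along the diagonal", {
  pm <- probability_map(random_simplex_map(4, c(6, 6, 6), seed = 20), 0:3)
  expect_lt(abs(consistency_dice(pm, pm)), 1e-6)
  # binary fields too
  hard <- array(0, c(2, 4, 4, 4)); hard[1, , , ] <- 1
  expect_lt(abs(consistency_dice(hard, hard,
                                 cfg = dice_loss_config(class_subset = 0:1))), 1e-6)
})

test_that("single-voxel disagreement matches the closed form", {
  e <- 1e-5
  ya <- array(c(0, 1), c(2, 1, 1, 1))
  yb <- array(c(0, 0), c(2, 1, 1, 1))
  expect_equal(consistency_dice(ya, yb, cfg = dice_loss_config(epsilon = e)),
               1 - e / (1 + e), tolerance = 1e-12)
})

test_that("exponent 1 penalises soft agreement while exponent 2 does not", {
  u <- array(0.5, c(2, 4, 4, 4))
  l1 <- consistency_dice(u, u, cfg = dice_loss_config(exponent_d = 1L))
  l2 <- consistency_dice(u, u, cfg = dice_loss_config(exponent_d = 2L))
  expect_gt(l1, 0.4)
  expect_lt(abs(l2), 1e-6)
})

test_that("loss is symmetric, bounded, and decreases toward agreement", {
  set.seed(21)
  a <- random_simplex_map(3, c(5, 5, 5))
  b <- random_simplex_map(3, c(5, 5, 5))
  expect_equal(consistency_dice(a, b), consistency_dice(b, a))
  expect_gte(consistency_dice(a, b), 0)
  expect_lte(consistency_dice(a, b), 1 + 1e-4)
  prev <- Inf
  for (lam in c(0, 0.3, 0.6, 0.9)) {
    cur <- consistency_dice(a, (1 - lam) * b + lam * a)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("empty masks yield zero loss with a warning; shapes are checked", {
  a <- random_simplex_map(2, c(4, 4, 4), seed = 22)
  expect_warning(l <- consistency_dice(a, a, mask = array(FALSE, c(4, 4, 4))),
                 "empty")
  expect_equal(l, 0)
  expect_error(consistency_dice(a, random_simplex_map(2, c(5, 4, 4))), "shape")
  expect_error(consistency_dice(a, a, mask = array(TRUE, c(3, 3, 3))), "mask")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(23)
  a <- random_simplex_map(3, c(4, 4, 4))
  b <- random_simplex_map(3, c(4, 4, 4))
  mask <- array(runif(64) > 0.2, c(4, 4, 4))
  cfg <- dice_loss_config()
  g <- consistency_dice(a, b, mask = mask, cfg = cfg, grad = TRUE)
  h <- 1e-6
  for (probe in 1:8) {
    i <- sample(length(a), 1)
    ap <- a; ap[i] <- ap[i] + h
    am <- a; am[i] <- am[i] - h
    num <- (consistency_dice(ap, b, mask = mask, cfg = cfg) -
              consistency_dice(am, b, mask = mask, cfg = cfg)) / (2 * h)
    expect_equal(g$grad_a[i], num, tolerance = 1e-4)
  }
})

test_that("the assembled test-time loss equals a manual warp-mask-dice composition", {
  set.seed(24)
  dm <- c(8, 8, 8)
  a <- random_simplex_map(3, dm)
  b <- random_simplex_map(3, dm)
  ta <- sample_affine(dm); tb <- sample_affine(dm)
  got <- tta_loss(a, b, ta, tb)
  wa <- dgtta:::.warp_array(a, ta$inverse_matrix,
                            src_valid = dgtta:::.affine_valid_mask(ta$matrix, dm))
  wb <- dgtta:::.warp_array(b, tb$inverse_matrix,
                            src_valid = dgtta:::.affine_valid_mask(tb$matrix, dm))
  m <- consistency_mask(wa$valid, wb$valid)
  manual <- consistency_dice(pmin(pmax(wa$data, 0), 1),
                             pmin(pmax(wb$data, 0), 1), mask = m)
  expect_equal(got, manual, tolerance = 1e-12)
  # identical outputs under identity transforms: zero loss
  ti <- identity_affine(dm)
  expect_lt(abs(tta_loss(a, a, ti, ti)), 1e-6)
})

test_that("differences confined to masked-out voxels do not contribute", {
  set.seed(25)
  dm <- c(8, 8, 8)
  a <- random_simplex_map(2, dm)
  b <- a
  b[, 1, , ] <- rev(b[, 1, , ])   # corrupt one border slab
  mask <- array(TRUE, dm); mask[1, , ] <- FALSE
  expect_lt(abs(consistency_dice(a, b, mask = mask)), 1e-6)
})
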