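test_that("pair enumeration yields the 12 diagonal neighbour pairs", {
  pairs <- ssc_pair_offsets(1L)
  expect_length(pairs, 12L)
  for (p in pairs) {
    expect_equal(sum(abs(p$a)), 1)
    expect_equal(sum(abs(p$b)), 1)
    expect_false(all(p$a + p$b == 0))       # never opposite neighbours
    expect_equal(sum(p$a * p$b), 0)          # always orthogonal axes
  }
  expect_equal(descriptor_channel_count("six"), 12L)
  expect_error(descriptor_channel_count("eighteen"), "unsupported")
})

test_that("patch SSD field matches hand computations", {
  # constant volume: identical patches everywhere
  expect_true(all(patch_ssd_field(array(3, c(5, 5, 5)), c(1, 0, 0), c(0, 1, 0)) == 0))
  expect_error(patch_ssd_field(array(1, c(5, 5, 5)), c(1, 0, 0), c(1, 0, 0)),
               "differ")
  # single bright voxel, brute-force oracle on 5^3
  x <- array(0, c(5, 5, 5)); x[3, 3, 3] <- 1
  off_a <- c(1, 0, 0); off_b <- c(0, 1, 0)
  expected <- array(0, c(5, 5, 5))
  gv <- function(i, j, k) x[min(max(i, 1), 5), min(max(j, 1), 5), min(max(k, 1), 5)]
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expected[i, j, k] <- (gv(i + 1, j, k) - gv(i, j + 1, k))^2
  got <- patch_ssd_field(x, off_a, off_b)
  expect_equal(got, expected)
  expect_true(any(got != 0))
  # SSD is symmetric in its two offsets
  set.seed(4)
  y <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(patch_ssd_field(y, off_a, off_b), patch_ssd_field(y, off_b, off_a))
})

test_that("noise estimate is the floored per-voxel mean of the 12 distances", {
  dm <- c(4, 4, 4)
  zeros <- replicate(12, array(0, dm), simplify = FALSE)
  expect_true(all(noise_estimate(zeros) > 0))
  consts <- replicate(12, array(3.5, dm), simplify = FALSE)
  expect_equal(noise_estimate(consts), array(3.5, dm))
  set.seed(5)
  fields <- replicate(12, array(abs(rnorm(prod(dm))), dm), simplify = FALSE)
  expect_equal(noise_estimate(fields), Reduce(`+`, fields) / 12, tolerance = 1e-12)
  bad <- fields; bad[[12]] <- array(0, c(5, 5, 5))
  expect_error(noise_estimate(bad), "grid")
  expect_error(noise_estimate(fields[1:6]), "12")
})

test_that("descriptor equals a naive per-voxel loop implementation", {
  set.seed(6)
  for (dm in list(c(7, 7, 7), c(9, 8, 7))) {
    x <- array(rnorm(prod(dm)), dm)
    fast <- compute_ssc(x)$data
    slow <- naive_ssc(x)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("descriptor has 12 channels, values in (0, 1], and constant inputs map to 1", {
  set.seed(7)
  s <- compute_ssc(as_volume(array(rnorm(6^3), c(6, 6, 6))))
  expect_equal(dim(s$data)[1L], descriptor_channel_count("six"))
  expect_true(all(s$data > 0 & s$data <= 1))
  expect_true(all(compute_ssc(array(5, c(5, 5, 5)))$data == 1))
  expect_error(compute_ssc(array(1, c(2, 5, 5))), "at least 3")
})

test_that("descriptor is invariant to affine intensity changes a*x + b", {
  set.seed(8)
  for (r in 1:20) {
    x <- array(rnorm(16^3), c(16, 16, 16))
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    d0 <- compute_ssc(x)$data
    d1 <- compute_ssc(a * x + b)$data
    expect_lt(max(abs(d0 - d1)), 1e-5)
  }
})

test_that("changing one voxel only perturbs the descriptor locally", {
  set.seed(9)
  x <- array(rnorm(9^3), c(9, 9, 9))
  y <- x; y[5, 5, 5] <- y[5, 5, 5] + 10
  d <- abs(compute_ssc(x)$data - compute_ssc(y)$data)
  changed <- apply(d > 1e-12, 2:4, any)
  idx <- which(changed, arr.ind = TRUE)
  radius <- 1L + 1L  # patch_distance + patch extent
  expect_true(all(abs(idx[, 1] - 5) <= radius &
                    abs(idx[, 2] - 5) <= radius &
                    abs(idx[, 3] - 5) <= radius))
  expect_true(any(changed))
})

test_that("global-sigma mode also yields values in (0, 1]", {
  set.seed(10)
  s <- compute_ssc(array(rnorm(6^3), c(6, 6, 6)), sigma_mode = "global")
  expect_true(all(s$data > 0 & s$data <= 1))
})
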