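make_train_set <- function(n, grid = 32L, seed0 = 300L) {
  ph <- tiny_phantom_set(n, seed0 + seq_len(n), grid = grid)
  list(vols = lapply(ph, `[[`, "source"), labs = lapply(ph, `[[`, "label"))
}

test_that("feature pipeline composes raw, augmentation and descriptor stages", {
  set.seed(30)
  x <- as_volume(array(rnorm(12^3), c(12, 12, 12)))
  # raw mode is the identity (up to the channel axis)
  fp0 <- feature_pipeline("none")
  out0 <- apply_feature_pipeline(x, fp0, "test")
  expect_equal(dim(out0), c(1L, 12L, 12L, 12L))
  expect_identical(array(out0, dim(x$data)), x$data)
  # descriptor mode: 12 channels at train and test time
  fps <- feature_pipeline("ssc")
  expect_equal(fps$in_channels, 12L)
  expect_equal(dim(apply_feature_pipeline(x, fps, "train"))[1L], 12L)
  # gin+ssc at test time equals ssc (augmentation inactive at inference)
  fpg <- feature_pipeline("gin+ssc")
  expect_identical(apply_feature_pipeline(x, fpg, "test"),
                   apply_feature_pipeline(x, fps, "test"))
  # train phase composes descriptor-after-augmentation, verified manually
  fpg2 <- feature_pipeline("gin+ssc", gin_cfg = gin_config(seed = 77))
  got <- apply_feature_pipeline(x, fpg2, "train")
  aug <- gin_augment(x$data, gin_config(seed = 77))
  manual <- dgtta:::.znorm_channels(compute_ssc(aug)$data)
  expect_lt(max(abs(got - manual)), 1e-12)
})

test_that("training runs deterministically and the loss trend is downward", {
  ts <- make_train_set(2)
  m1 <- dg_pretrain(ts$vols, ts$labs, features = "none", epochs = 6,
                    patches_per_volume = 2, seed = 5)
  m2 <- dg_pretrain(ts$vols, ts$labs, features = "none", epochs = 6,
                    patches_per_volume = 2, seed = 5)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_lt(mean(tail(m1$loss_trace, 2)), mean(head(m1$loss_trace, 2)))
})

test_that("training contracts are enforced", {
  ts <- make_train_set(1)
  expect_error(dg_pretrain(list(), list()), "empty")
  expect_error(dg_pretrain(ts$vols, list()), "equal length")
  expect_error(dg_pretrain(ts$vols, ts$labs, classes = c(0L, 1L)), "outside")
  expect_error(dg_pretrain(ts$vols, ts$labs, patch_size = c(10, 10, 10)),
               "multiples of 4")
  expect_error(dg_pretrain(ts$vols, ts$labs, patch_size = c(64, 64, 64)),
               "fit")
})

test_that("checkpoints reload bit-exactly", {
  ts <- make_train_set(1)
  m <- dg_pretrain(ts$vols, ts$labs, epochs = 2, patches_per_volume = 1, seed = 2)
  tf <- withr::local_tempfile(fileext = ".rds")
  dg_save(m, tf)
  m2 <- dg_load(tf)
  p1 <- predict(m, ts$vols[[1]])
  p2 <- predict(m2, ts$vols[[1]])
  expect_identical(p1$data, p2$data)
})

test_that("whole-volume prediction is a simplex and tiling stays consistent", {
  ts <- make_train_set(2)
  m <- dg_pretrain(ts$vols, ts$labs, epochs = 8, patches_per_volume = 3, seed = 3)
  pm <- predict(m, ts$vols[[1]])
  sums <- apply(pm$data, 2:4, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # tiled against single-pass inference
  tiled <- predict(m, ts$vols[[1]], max_tile = 16L)
  expect_lt(mean(abs(tiled$data - pm$data)), 0.01)
  # volumes smaller than a tile are padded and cropped back
  small <- as_volume(ts$vols[[1]]$data[1:10, 1:10, 1:10])
  ps <- predict(m, small)
  expect_equal(dim(ps$data)[-1L], c(10L, 10L, 10L))
  # hard segmentation matches the argmax of the probabilities
  seg <- segment(m, ts$vols[[1]])
  expect_true(all(seg$data %in% m$classes))
})

test_that("model methods print, summarise, plot and expose coefficients", {
  ts <- make_train_set(1)
  m <- dg_pretrain(ts$vols, ts$labs, epochs = 2, patches_per_volume = 1, seed = 4)
  expect_output(print(m), "dg_segnet")
  expect_output(summary(m), "per-epoch loss")
  expect_type(coef(m), "list")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(m); grDevices::dev.off()
  expect_true(file.exists(tf))
})
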