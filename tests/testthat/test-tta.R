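tta_fixture <- function() {
  ph <- tiny_phantom_set(2, c(401, 402), grid = 32L)
  m <- dg_pretrain(lapply(ph, `[[`, "source"), lapply(ph, `[[`, "label"),
                   epochs = 3, patches_per_volume = 2, seed = 6)
  list(model = m, targets = lapply(ph, `[[`, "target"))
}

test_that("zero learning rate leaves the model unchanged but reports a loss", {
  fx <- tta_fixture()
  cfg <- tta_config(learning_rate = 0, steps = 2L, patches_per_step = 2L, seed = 1)
  ad <- tta_adapt(fx$model, fx$targets[[1]], cfg)
  expect_identical(ad$params, fx$model$params)
  expect_length(ad$tta_trace, 2L)
  expect_true(all(is.finite(ad$tta_trace)))
})

test_that("adaptation is deterministic under a fixed seed and leaves the input model intact", {
  fx <- tta_fixture()
  cfg <- tta_config(steps = 3L, patches_per_step = 3L, seed = 2)
  before <- fx$model$params
  a1 <- tta_adapt(fx$model, fx$targets[[1]], cfg)
  a2 <- tta_adapt(fx$model, fx$targets[[1]], cfg)
  expect_identical(a1$tta_trace, a2$tta_trace)
  expect_identical(a1$params, a2$params)
  expect_identical(fx$model$params, before)
})

test_that("per-sample adaptation is isolated: sample order does not leak state", {
  fx <- tta_fixture()
  cfg <- tta_config(steps = 2L, patches_per_step = 2L, seed = 3)
  tta_adapt(fx$model, fx$targets[[1]], cfg)       # adapt sample 1, discard
  a2_after <- tta_adapt(fx$model, fx$targets[[2]], cfg)
  a2_alone <- tta_adapt(fx$model, fx$targets[[2]], cfg)
  expect_identical(a2_after$params, a2_alone$params)
})

test_that("accumulated patch gradients equal the batched mean-loss gradient", {
  fx <- tta_fixture()
  cfg <- tta_config(patches_per_step = 4L)
  input <- apply_feature_pipeline(fx$targets[[1]], fx$model$feature_pipeline, "test")
  set.seed(4)
  plan <- dgtta:::.draw_tta_plan(dim(input)[-1L], fx$model$patch_size, cfg)
  ga <- tta_gradients(fx$model, input, plan, cfg, mode = "accumulate")
  gb <- tta_gradients(fx$model, input, plan, cfg, mode = "batched")
  expect_equal(ga$loss, gb$loss, tolerance = 1e-12)
  for (nm in names(ga$grads))
    expect_lt(max(abs(ga$grads[[nm]] - gb$grads[[nm]])), 1e-6)
  # and the resulting optimiser updates coincide
  sa <- adamw_step(fx$model$params, ga$grads, adamw_init(fx$model$params),
                   lr = 1e-5, weight_decay = 0.01)
  sb <- adamw_step(fx$model$params, gb$grads, adamw_init(fx$model$params),
                   lr = 1e-5, weight_decay = 0.01)
  for (nm in names(sa$params))
    expect_lt(max(abs(sa$params[[nm]] - sb$params[[nm]])), 1e-6)
})

test_that("branch gradients decompose: A-only plus B-only equals both-branch", {
  fx <- tta_fixture()
  input <- apply_feature_pipeline(fx$targets[[1]], fx$model$feature_pipeline, "test")
  cfgA <- tta_config(grad_branches = "A", patches_per_step = 2L)
  cfgB <- tta_config(grad_branches = "B", patches_per_step = 2L)
  cfgAB <- tta_config(grad_branches = "AB", patches_per_step = 2L)
  set.seed(5)
  plan <- dgtta:::.draw_tta_plan(dim(input)[-1L], fx$model$patch_size, cfgA)
  gA <- tta_gradients(fx$model, input, plan, cfgA)
  gB <- tta_gradients(fx$model, input, plan, cfgB)
  gAB <- tta_gradients(fx$model, input, plan, cfgAB)
  for (nm in names(gAB$grads))
    expect_lt(max(abs(gA$grads[[nm]] + gB$grads[[nm]] - gAB$grads[[nm]])), 1e-9)
  # detaching branch B changes the gradient, not the loss
  expect_equal(gA$loss, gAB$loss, tolerance = 1e-12)
  expect_gt(max(abs(gA$grads[["head.w"]] - gAB$grads[["head.w"]])), 0)
})

test_that("patches with fully disjoint fields of view are skipped", {
  fx <- tta_fixture()
  cfg <- tta_config(patches_per_step = 1L)
  input <- apply_feature_pipeline(fx$targets[[1]], fx$model$feature_pipeline, "test")
  patch <- fx$model$patch_size
  far <- diag(4); far[1, 4] <- 2 * patch[1]
  plan <- list(list(origin = c(0L, 0L, 0L),
                    t_a = affine_augmentation(far, patch),
                    t_b = identity_affine(patch)))
  g <- tta_gradients(fx$model, input, plan, cfg)
  expect_null(g$grads)
})

test_that("ensembles validate size and reduce to a single model when size one", {
  fx <- tta_fixture()
  expect_error(adapt_and_predict_ensemble(list(), fx$targets[[1]]), "size 0")
  cfg <- tta_config(steps = 2L, patches_per_step = 2L, seed = 7)
  ens <- adapt_and_predict_ensemble(list(fx$model), fx$targets[[1]], cfg)
  single <- tta_adapt(fx$model, fx$targets[[1]], cfg)
  pm <- predict(single, fx$targets[[1]])
  manual <- dgtta:::.argmax_labels(pm$data, fx$model$classes)
  expect_identical(ens$data, array(as.integer(manual), dim(manual)))
})

test_that("the consistency objective is driven down over adaptation steps", {
  fx <- tta_fixture()
  cfg <- tta_config(steps = 6L, patches_per_step = 4L, seed = 8,
                    learning_rate = 1e-3)
  ad <- tta_adapt(fx$model, fx$targets[[1]], cfg)
  expect_lt(mean(tail(ad$tta_trace, 2)), mean(head(ad$tta_trace, 2)))
})
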