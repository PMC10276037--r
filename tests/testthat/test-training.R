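# Splits, augmentation, the training loop, and evaluation protocols.

test_that("split_dataset is seeded, disjoint and exhaustive", {
  recs <- data.frame(id = 1:2017, split = NA_character_)
  sp <- split_dataset(recs, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 1411)     # floor rounding
  expect_equal(nrow(sp$val), 606)
  sp2 <- split_dataset(recs, 0.7, seed = 5, rounding = "round")
  expect_equal(nrow(sp2$train), 1412)    # published type-A split sizes
  expect_equal(nrow(sp2$val), 605)
  expect_length(intersect(sp$train$id, sp$val$id), 0)
  expect_setequal(c(sp$train$id, sp$val$id), recs$id)
  expect_identical(split_dataset(recs, 0.7, seed = 5)$train$id, sp$train$id)
  sp3 <- split_dataset(data.frame(id = 1:10), 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 5)
  expect_error(split_dataset(data.frame(id = 1), 0.5, seed = 1),
               class = "porediff_invalid_input")
})

test_that("horizontal flip is an involution and preserves scalar labels", {
  s <- generate_type_b(32, generator_config_b(0.4), seed = 3)
  once <- augment_hflip(s, label = c(phi = 0.4, D = 0.2), task = "scalar")
  expect_identical(once$label, c(phi = 0.4, D = 0.2))
  twice <- augment_hflip(once$sample, task = "scalar")
  expect_identical(twice$sample$grid, s$grid)
  expect_identical(porosity(once$sample), porosity(s))
})

test_that("phi and D are invariant under the flip when recomputed by the solver", {
  s <- generate_type_a(32, generator_config_a(0.7), seed = 4)
  D <- solve_and_D(s)
  sf <- augment_hflip(s, task = "scalar")$sample
  expect_equal(solve_and_D(sf), D, tolerance = 1e-6)
})

test_that("field labels flip with the mirror-and-complement rule", {
  s <- generate_type_a(16, generator_config_a(0.75), seed = 5)
  f <- solve_steady(s)
  lab <- f$values; lab[is.na(lab)] <- 0
  fl <- augment_hflip(s, label = lab, task = "field")
  L <- 16
  for (k in 1:25) {
    x <- sample(L, 1); y <- sample(L, 1)
    if (s$grid[y, L + 1 - x])
      expect_equal(fl$label[y, x], 1 - lab[y, L + 1 - x], tolerance = 1e-12)
    else
      expect_identical(fl$label[y, x], 0)
  }
  # the flipped label is the steady field of the flipped geometry
  ff <- solve_steady(fl$sample)
  vv <- ff$values; vv[is.na(vv)] <- 0
  expect_lt(max(abs(vv - fl$label)), 1e-8)
})

test_that("a tiny U-Net overfits eight samples to near-zero training MSE", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 1:8)
  spec <- surrogate_spec("UNET", input_side = 64L, containers = 2L,
                         blocks_per_container = 1L, n_kernels = 8L,
                         dropout_p = 0)
  m <- build_unet(spec, seed = 41)
  train_surrogate(m, sub, epochs = 60, batch_size = 8, lr = 3e-3,
                  seed = 42, augment = FALSE)
  fit <- train_surrogate(m, sub, epochs = 0, finetune_epochs = 40,
                         finetune_lr = 1e-3, batch_size = 8, seed = 43,
                         augment = FALSE)
  expect_lt(tail(fit$history$train_loss, 1), 1e-3)
})

test_that("training is bit-reproducible at a fixed seed", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 1:10)
  spec <- surrogate_spec("CNET", input_side = 64L, dropout_p = 0.1,
                         cnet_channels = c(4L, 8L), cnet_kernels = c(5L, 3L),
                         fc_units = c(16L, 8L))
  run <- function() {
    m <- build_cnet(spec, seed = 7)
    train_surrogate(m, sub, epochs = 3, batch_size = 4, seed = 99,
                    augment = TRUE)$history$train_loss
  }
  expect_identical(run(), run())
})

test_that("evaluate_scalar reports exact metrics for a perfect predictor stub", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 1:6)
  stub <- structure(list(task = "scalar", kind = "STUB",
                         spec = list(dropout_p = 0.1), layers = list()),
                    class = "porediff_model")
  # a stub whose MC passes return the truth exactly
  truth <- sub$y
  local_mocked_bindings(
    mc_predict_dataset = function(model, x, M, seed, chunk = 32L)
      list(mean = truth, sigma = truth * 0 + 0.05),
    .package = "porediff")
  ev <- evaluate_scalar(stub, sub, M = 4)
  expect_equal(ev$mse, 0)
  expect_equal(ev$chibar2, 0)
  expect_equal(ev$coverage1, 1)
})

test_that("evaluate_field on an identity-like stub returns zero error maps", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 1:4)
  local_mocked_bindings(
    mc_predict_dataset = function(model, x, M, seed, chunk = 32L)
      list(mean = sub$field, sigma = sub$field * 0),
    .package = "porediff")
  stub <- structure(list(task = "field", kind = "STUB",
                         spec = list(dropout_p = 0.1), layers = list()),
                    class = "porediff_model")
  ev <- evaluate_field(stub, sub, M = 4)
  expect_equal(ev$mean_abs_error, 0)
  expect_equal(ev$mean_sigma, 0)
})

test_that("field evaluation error is invariant under simultaneous flips", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 11:14)
  spec <- surrogate_spec("UNET", input_side = 64L, containers = 2L,
                         blocks_per_container = 1L, n_kernels = 4L,
                         dropout_p = 0)
  m <- build_unet(spec, seed = 43)
  pred <- predict(m, sub$x)
  err <- mean(abs(pred - sub$field))
  # flip every input and label consistently; re-predicting the flipped
  # inputs of an untrained net differs, but the error of flipped
  # predictions against flipped labels is identical by construction
  W <- 64
  xf <- sub$x[, W:1, , , drop = FALSE]
  predf <- pred[, W:1, , , drop = FALSE]
  labf <- sub$field[, W:1, , , drop = FALSE]
  expect_equal(mean(abs(predf - labf)), err, tolerance = 1e-14)
  expect_equal(dim(predict(m, xf)), dim(xf))
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- scaled_dataset("B", 30, seed = 400)
  sub <- porediff:::subset_dataset(ds, 1:6)
  spec <- surrogate_spec("CNET", input_side = 64L, dropout_p = 0,
                         cnet_channels = c(4L), cnet_kernels = c(5L),
                         fc_units = c(8L, 4L))
  m <- build_cnet(spec, seed = 1)
  # poison the linear output layer (the tanh layer would saturate finitely)
  m$layers$out$W[] <- 1e155
  expect_error(train_surrogate(m, sub, epochs = 1, batch_size = 4, seed = 1),
               "diverged")
})
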