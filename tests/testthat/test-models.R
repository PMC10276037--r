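# Architecture arithmetic, the SN module, and MC-dropout inference.

test_that("the C-Net conv/pool chain flattens to 400 features at 128x128", {
  m <- build_cnet(surrogate_spec("CNET", input_side = 128L), seed = 1)
  expect_equal(m$flatten_length, 400L)   # 100 channels x 2 x 2
  # structural walk: five conv sections with the published kernel counts
  df <- local({ sink(tempfile()); on.exit(sink()); model_describe(m) })
  convs <- df[df$type == "conv", ]
  expect_equal(nrow(convs), 5L)
  expect_equal(unname(vapply(paste0("conv", 1:5),
                             function(nm) dim(m$layers[[nm]]$W)[4], 0L)),
               c(10L, 20L, 40L, 80L, 100L))
  expect_equal(unname(vapply(paste0("conv", 1:5),
                             function(nm) dim(m$layers[[nm]]$W)[1], 0L)),
               c(5L, 4L, 3L, 3L, 2L))
  # forward pass on a real geometry: finite 2-vector
  g <- generate_type_a(128, generator_config_a(0.7), seed = 2)
  out <- predict(m, 1 - g$grid)
  expect_equal(dim(out), c(2L, 1L))
  expect_true(all(is.finite(out)))
})

test_that("incompatible C-Net input sides are rejected at spec time", {
  expect_error(surrogate_spec("CNET", input_side = 64L),
               class = "porediff_invalid_input")
  expect_error(surrogate_spec("UNET", input_side = 100L),
               class = "porediff_invalid_input")
})

test_that("the U-Net bottleneck is 2x2 after six poolings and output matches input", {
  spec <- surrogate_spec("UNET", input_side = 128L)
  m <- build_unet(spec, seed = 3)
  expect_equal(m$bottleneck, c(2L, 2L))
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  out <- predict(m, x)
  expect_equal(dim(out), dim(x))
  # parameter count lands in the right order of magnitude (~1e6)
  total <- sum(vapply(m$layers, porediff:::n_params, 0))
  expect_gt(total, 3e5); expect_lt(total, 1e7)
})

test_that("U-Net skip connections join tensors of matching shape", {
  spec <- surrogate_spec("UNET", input_side = 32L, containers = 3L,
                         blocks_per_container = 2L, n_kernels = 8L)
  m <- build_unet(spec, seed = 4)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_equal(dim(predict(m, x)), dim(x))
  # decoder conv at each concat point takes 2x the kernel count
  expect_equal(dim(m$layers$dec2_b1_conv$W)[3], 16L)
  expect_equal(dim(m$layers$dec1_b1_conv$W)[3], 8L)    # bottleneck, no concat
  expect_equal(dim(m$layers$final_b1_conv$W)[3], 16L)  # concat with enc1
})

test_that("U-Net-Half shares the encoder and the scalar head", {
  spec <- surrogate_spec("UNET_HALF", input_side = 64L, containers = 3L,
                         blocks_per_container = 2L, n_kernels = 8L,
                         fc_units = c(32L, 10L))
  m <- build_unet_half(spec, seed = 5)
  expect_equal(m$flatten_length, 8L * 8L * 8L)
  out <- predict(m, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_equal(dim(out), c(2L, 1L))
})

test_that("sn_transform identities hold", {
  r <- sn_transform(c(0.5, 0.8), c(0, 0))
  expect_equal(r$output, c(0.5, 0.8))     # sigma(0) = 1/2 -> factors 1
  expect_equal(r$penalty, 0)
  # saturation limit: factors -> 2, penalty -> 2
  r2 <- sn_transform(c(1, 1), c(50, 50))
  expect_equal(r2$factors, c(2, 2), tolerance = 1e-10)
  expect_equal(r2$penalty, 2, tolerance = 1e-9)
  # hand-evaluated point: sigma(ln 3) = 3/4
  r3 <- sn_transform(c(1, 1), c(log(3), 0))
  expect_equal(r3$factors[1], 1.5, tolerance = 1e-12)
  expect_equal(r3$penalty, 0.25, tolerance = 1e-12)
  # factors always inside (0, 2); penalty 0 iff both factors are 1
  z <- rnorm(100, sd = 5)
  f <- sn_transform(rep(1, 100), z)$factors
  expect_true(all(f > 0 & f < 2))
  expect_true(all((1 - f)^2 > 0 | z == 0))
})

test_that("the SN head reduces to the top branch at zero pre-activations", {
  spec <- surrogate_spec("CNET", input_side = 16L, dropout_p = 0,
                         sn_enabled = TRUE, cnet_channels = c(4L),
                         cnet_kernels = c(3L), fc_units = c(8L, 4L))
  m <- build_cnet(spec, seed = 6)
  sn <- m$layers$sn
  sn$Wb[] <- 0; sn$bb[] <- 0    # force bottom pre-activations to zero
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  out <- predict(m, x)
  top <- sn$Wt %*% m$layers$head_drop$fw(
    m$layers$fc1$fw(m$layers$flatten$fw(
      m$layers$drop1$fw(m$layers$pool1$fw(m$layers$bn1$fw(
        m$layers$conv1$fw(x, "eval"), "eval"), "eval"), "eval"),
      "eval"), "eval"), "eval") + sn$bt
  expect_equal(unname(out), unname(top), tolerance = 1e-12)
})

test_that("MC dropout mean/std behave as a Monte Carlo estimator", {
  spec <- surrogate_spec("CNET", input_side = 16L, dropout_p = 0.2,
                         cnet_channels = c(4L), cnet_kernels = c(3L),
                         fc_units = c(16L, 8L))
  m <- build_cnet(spec, seed = 7)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  r1 <- mc_dropout_predict(m, x, M = 20, seed = 11)
  r2 <- mc_dropout_predict(m, x, M = 20, seed = 11)
  expect_identical(r1$mean, r2$mean)       # bit-reproducible at fixed seed
  expect_identical(r1$sigma, r2$sigma)
  expect_true(all(r1$sigma >= 0))
  expect_false(identical(r1$mean, mc_dropout_predict(m, x, M = 20, seed = 12)$mean))

  # p = 0: zero spread, mean equals the deterministic pass, with a warning
  spec0 <- surrogate_spec("CNET", input_side = 16L, dropout_p = 0,
                          cnet_channels = c(4L), cnet_kernels = c(3L),
                          fc_units = c(16L, 8L))
  m0 <- build_cnet(spec0, seed = 8)
  expect_warning(r0 <- mc_dropout_predict(m0, x, M = 5, seed = 1),
                 "identically zero")
  expect_equal(max(r0$sigma), 0)
  expect_equal(unname(r0$mean), unname(predict(m0, x)), tolerance = 1e-12)
  expect_error(mc_dropout_predict(m, x, M = 1), class = "porediff_invalid_input")
})

test_that("the MC-dropout std stabilizes as M grows", {
  # toy 2-layer model: dropout between two dense layers
  spec <- surrogate_spec("CNET", input_side = 8L, dropout_p = 0.3,
                         cnet_channels = c(2L), cnet_kernels = c(3L),
                         fc_units = c(12L, 6L))
  m <- build_cnet(spec, seed = 9)
  x <- array(runif(64), c(8, 8, 1, 1))
  s500 <- mean(mc_dropout_predict(m, x, M = 500, seed = 2)$sigma)
  s1000 <- mean(mc_dropout_predict(m, x, M = 1000, seed = 3)$sigma)
  expect_lt(abs(s1000 - s500) / s1000, 0.10)
})

test_that("eval-mode forward passes are deterministic", {
  spec <- surrogate_spec("UNET", input_side = 16L, containers = 2L,
                         blocks_per_container = 1L, n_kernels = 4L,
                         dropout_p = 0.3)
  m <- build_unet(spec, seed = 10)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(predict(m, x), predict(m, x))
})
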