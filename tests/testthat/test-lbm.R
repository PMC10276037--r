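# Steady diffusion solver, convergence bookkeeping, and the discrete
# Fick's-law estimator.

test_that("an obstacle-free domain relaxes to the linear profile with D = 1", {
  s <- porous_sample(matrix(TRUE, 32, 32))
  f <- solve_steady(s)
  expect_true(f$converged)
  expect_lt(max(abs(f$values - linear_profile(32))), 1e-6)
  expect_equal(effective_diffusion(f, s), 1, tolerance = 1e-6)
  expect_equal(effective_diffusion(f, s, normalization = "total"), 1,
               tolerance = 1e-6)
})

test_that("straight channels along x give D = D0 at any porosity (pore norm)", {
  g <- matrix(TRUE, 32, 32)
  g[seq(2, 32, 4), ] <- FALSE          # porosity 0.75
  f <- solve_steady(porous_sample(g))
  expect_equal(effective_diffusion(f, g), 1, tolerance = 1e-6)
  expect_equal(effective_diffusion(f, g, normalization = "total"), 0.75,
               tolerance = 1e-6)
})

test_that("a full transverse barrier equilibrates each side and gives D = 0", {
  g <- matrix(TRUE, 32, 32); g[, 16] <- FALSE
  expect_warning(f <- solve_steady(porous_sample(g)), "percolate")
  expect_true(all(abs(f$values[, 1:15] - 0) < 1e-9))
  expect_true(all(abs(f$values[, 17:32] - 1) < 1e-9))
  expect_equal(effective_diffusion(f, g), 0, tolerance = 1e-6)
})

test_that("the kinetic solver agrees with the sparse finite-volume oracle", {
  for (i in 1:5) {
    sa <- generate_type_a(32, generator_config_a(runif(1, 0.5, 0.9)), seed = i)
    sb <- generate_type_b(32, generator_config_b(runif(1, 0.2, 0.6)), seed = i)
    for (s in list(sa, sb)) {
      f <- solve_steady(s)
      o <- laplace_oracle(s)
      expect_lt(max(abs(f$values - o$values), na.rm = TRUE), 1e-6)
      expect_lt(abs(effective_diffusion(f, s) - effective_diffusion(o, s)),
                1e-4 * max(effective_diffusion(o, s), 1e-3))
    }
  }
})

test_that("converged fields respect the discrete maximum principle", {
  s <- generate_type_b(32, generator_config_b(0.4), seed = 21)
  f <- solve_steady(s)
  v <- f$values[!is.na(f$values)]
  expect_true(all(v >= -1e-9 & v <= 1 + 1e-9))
})

test_that("mirror symmetries map the field as expected and leave D unchanged", {
  s <- generate_type_a(32, generator_config_a(0.7), seed = 31)
  f <- solve_steady(s)
  D <- effective_diffusion(f, s)
  # top-bottom mirror of the geometry mirrors the field
  gm <- s$grid[32:1, ]
  fm <- solve_steady(porous_sample(gm))
  expect_lt(max(abs(fm$values - f$values[32:1, ]), na.rm = TRUE), 1e-9)
  # left-right flip with swapped boundary values maps c -> 1 - c, same D
  gf <- porediff:::hflip_matrix(s$grid)
  ff <- solve_steady(porous_sample(gf))
  expect_lt(max(abs(ff$values - (1 - f$values[, 32:1])), na.rm = TRUE), 1e-8)
  expect_equal(effective_diffusion(ff, gf), D, tolerance = 1e-6)
  # relabeling (c_in, c_out) = (1, 0) flips the sign convention only
  fr <- solve_steady(s, boundary_spec(1, 0))
  expect_equal(effective_diffusion(fr, s, boundary_spec(1, 0)), D,
               tolerance = 1e-6)
})

test_that("adding solid nodes never increases D", {
  set.seed(41)
  g <- generate_type_a(32, generator_config_a(0.8), seed = 41)$grid
  D1 <- solve_and_D(porous_sample(g))
  g2 <- g
  fl <- which(g2)
  g2[sample(fl, 40)] <- FALSE
  if (percolates(g2)) {
    D2 <- suppressWarnings(solve_and_D(porous_sample(g2)))
    expect_lte(D2, D1 + 1e-9)
  } else succeed("degenerate draw")
})

test_that("convergence_delta is the max change over fluid nodes only", {
  a <- matrix(0.5, 8, 8); b <- a
  mask <- matrix(TRUE, 8, 8); mask[1, 1] <- FALSE
  expect_identical(convergence_delta(a, b, mask), 0)
  b[2, 2] <- b[2, 2] + 1e-12
  expect_equal(convergence_delta(a, b, mask), 1e-12)
  b2 <- a; b2[1, 1] <- 99   # change only on a solid node
  expect_identical(convergence_delta(a, b2, mask), 0)
  expect_error(convergence_delta(a, matrix(0, 4, 4), mask),
               class = "porediff_invalid_input")
})

test_that("the delta envelope decays geometrically after the initial transient", {
  s <- porous_sample(matrix(TRUE, 32, 32))
  run <- function(n) solve_steady(s, cfg = solver_config(
    tolerance = 1e-300, max_iterations = n))$final_delta
  d1 <- run(1000); d2 <- run(2000)
  # the slowest mode decays like exp(-D0 pi^2 / L^2) per sweep, so another
  # 1000 iterations should shrink the envelope by orders of magnitude
  expect_lt(d2, 1e-2 * d1)
})

test_that("isolated fluid pockets keep the initial value in both solvers", {
  g <- matrix(TRUE, 16, 16)
  g[, 8] <- FALSE            # right side disconnected from the inlet
  g[5:8, 11] <- FALSE
  g[4, 9:16] <- FALSE; g[9, 9:16] <- FALSE  # carve an enclosed pocket
  g[5:8, 9:10] <- TRUE; g[5:8, 12:16] <- TRUE
  pocket <- matrix(FALSE, 16, 16); pocket[5:8, 9:10] <- TRUE
  pocket <- pocket & g
  f <- suppressWarnings(solve_steady(porous_sample(g)))
  o <- laplace_oracle(porous_sample(g))
  if (any(pocket)) {
    expect_true(all(abs(f$values[pocket] - 0) < 1e-12))
    expect_true(all(abs(o$values[pocket] - 0) < 1e-12))
  }
  expect_lt(max(abs(f$values - o$values), na.rm = TRUE), 1e-6)
})

test_that("solver configuration ties the relaxation time to D0", {
  cfg <- solver_config()
  expect_equal(cfg$relaxation_time, 3.5)
  expect_equal(cfg$D0, 1)
  expect_error(solver_config(relaxation_time = 2), "inconsistent",
               class = "porediff_invalid_input")
  expect_error(solver_config(tolerance = 0), class = "porediff_invalid_input")
  expect_error(boundary_spec(1, 1), class = "porediff_invalid_input")
})
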