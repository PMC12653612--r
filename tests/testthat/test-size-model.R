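test_that("derived size parameters match their defining identities", {
  p <- ref_size
  expect_equal(p$b, p$A / (1 + p$B), tolerance = 1e-12)
  expect_equal(p$c, p$B / p$A, tolerance = 1e-12)
  expect_equal(p$le0, p$a * p$b, tolerance = 1e-12)
  expect_equal(p$lemax, p$a / p$c, tolerance = 1e-12)
  # reconstruction of (A, B) from (b, c) is the inverse map
  expect_equal(p$b / (1 - p$b * p$c), p$A, tolerance = 1e-10)
  expect_equal(p$b * p$c / (1 - p$b * p$c), p$B, tolerance = 1e-10)
})

test_that("the reference fit yields the published derived values", {
  p <- ref_size
  expect_equal(p$b, 4989883.14035894, tolerance = 1e-10)
  expect_equal(p$c, 4.05505505343353e-10, tolerance = 1e-10)
  expect_equal(p$le0, 1009.39930220508, tolerance = 1e-10)
  expect_equal(p$lemax, 498856.770121871, tolerance = 1e-10)
})

test_that("degenerate shape parameters are rejected", {
  expect_error(size_model_params(5e6, 0, 2e-4, 149, 137475), "domain error")
  expect_error(size_model_params(5e6, -0.1, 2e-4, 149, 137475),
               "domain error")
  expect_error(size_model_params(-1, 0.1, 2e-4, 149, 137475), "positive")
})

test_that("the closed-form size curve passes through the minimal genome", {
  expect_equal(s_of_g(ref_size$g0, ref_size), ref_size$s0,
               tolerance = 1e-12)
  expect_error(s_of_g(100, ref_size), "g >= g0")
})

test_that("the size curve is increasing and approaches its asymptote", {
  # below the double-precision saturation of the logistic term
  g <- seq(149, 1.2e5, length.out = 400)
  s <- s_of_g(g, ref_size)
  expect_true(all(diff(s) > 0))
  cap <- ref_size$s0 + ref_size$A / ref_size$B -
    ref_size$A / (1 + ref_size$B)
  expect_true(all(s <= cap))
  expect_equal(s_of_g(1e8, ref_size), cap, tolerance = 1e-8)
})

test_that("closed form matches numerical integration of the size ODE", {
  p <- ref_size
  rhs <- function(g, s, parms)
    list(p$a * ((s - p$s0) + p$b) * (1 - p$c * ((s - p$s0) + p$b)))
  g_grid <- c(149, seq(500, 60000, by = 500))
  num <- deSolve::ode(y = c(s = p$s0), times = g_grid, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-4)
  expect_equal(s_of_g(g_grid, p), unname(num[, "s"]), tolerance = 1e-6)
})

test_that("the closed form satisfies the ODE pointwise", {
  p <- ref_size
  g <- seq(200, 80000, length.out = 200)
  h <- 1e-3
  deriv <- (s_of_g(g + h, p) - s_of_g(g - h, p)) / (2 * h)
  s <- s_of_g(g, p)
  rhs <- p$a * ((s - p$s0) + p$b) * (1 - p$c * ((s - p$s0) + p$b))
  expect_equal(deriv, rhs, tolerance = 1e-5)
})

test_that("extensive-gene length is linear in size and clamps at lemax", {
  p <- ref_size
  expect_equal(le_of_s(p$s0, p), p$le0)
  expect_error(le_of_s(p$s0 - 1, p), "s >= s0")
  # published worked example: at 2.5e8 bp the ratio rounds to 0.1
  expect_equal(round(le_of_s(2.5e8, p) / p$lemax, 1), 0.1)
  # beyond the validity range the raw value exceeds the ceiling
  expect_gt(le_of_s(2.5e9, p, clamp = FALSE), p$lemax)
  expect_equal(le_of_s(2.5e9, p, clamp = TRUE), p$lemax)
})

test_that("extensive fraction of new genes stays in [0,1] and decreases", {
  p <- ref_size
  expect_equal(dge_fraction(p$s0 + (p$lemax - p$le0) / p$a, p), 0)
  expect_equal(dge_fraction(p$s0, p), 1 - p$le0 / p$lemax)
  expect_equal(round(dge_fraction(2.5e8, p), 1), 0.9)
  s <- seq(p$s0, 1e9, length.out = 300)
  f <- dge_fraction(s, p)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) <= 0))
})

test_that("size-model fit recovers noise-free parameters", {
  cfg <- simulation_config(n_genomes = 2000, seed = 5, size_noise_sigma = 0)
  rec <- simulate_genome_records(cfg)
  fit <- fit_size_model(rec, seed = 1, g0 = ref_size$g0, s0 = ref_size$s0)
  expect_true(fit$converged)
  expect_equal(fit$params$A, ref_size$A, tolerance = 0.01)
  expect_equal(fit$params$B, ref_size$B, tolerance = 0.01)
  expect_equal(fit$params$a, ref_size$a, tolerance = 0.01)
})

test_that("size-model boundary defaults to the minimal record", {
  rec <- make_records(c(600L, 300L, 1000L, 2000L, 4000L),
                      size = c(9e5, 5e5, 1.2e6, 2.4e6, 4.4e6))
  fit <- fit_size_model(rec, seed = 1, restarts = 2)
  expect_equal(fit$params$g0, 300)
  expect_equal(fit$params$s0, 5e5)
})

test_that("residuals on noisy synthetic sizes track the injected noise", {
  cfg <- simulation_config(n_genomes = 1500, seed = 9,
                           size_noise_sigma = 0.1)
  rec <- simulate_genome_records(cfg)
  fit <- fit_size_model(rec, seed = 1, loss = "log")
  expect_true(fit$converged)
  # log-loss RMSE should sit near the injected 0.1-decade scatter
  expect_lt(abs(fit$rmse - 0.1), 0.03)
})

test_that("density transform rescales without moving the maximum", {
  bd <- exact_density(ref_mixture)
  t1 <- transform_density(bd, p1 = 1000, p2 = 1)
  t2 <- transform_density(bd, p1 = 1000, p2 = 15.953324)
  expect_equal(which.max(t1$density), which.max(t2$density))
  expect_equal(t2$density, 15.953324 * t1$density)
  expect_equal(t1$log10_size, log10(1000 * t1$gene_number))
})

test_that("maximum-matching calibration recovers the density scale", {
  bd <- exact_density(ref_mixture)
  p2_true <- 12.5
  pred <- transform_density(bd, p1 = 1000, p2 = 1)
  observed <- p2_true * pred$density
  expect_equal(calibrate_p2(pred, observed), p2_true, tolerance = 1e-12)
})

test_that("size parameters serialize with fitted/derived labels", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_size_params(ref_size, path)
  lines <- readLines(path)
  expect_length(grep("# fitted", lines), 5L)
  expect_length(grep("# derived", lines), 4L)
})
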