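test_that("shifted Poisson mass matches a direct factorial series", {
  expect_equal(poisson_component(5, 3, k0 = 7), 0)       # below support
  expect_equal(poisson_component(7, 3, k0 = 7), exp(-3)) # zero-count mass
  lam <- 6.133813
  direct <- lam^10 * exp(-lam) / factorial(10)
  expect_equal(poisson_component(10, lam, k0 = 0), direct,
               tolerance = 1e-12)
  expect_error(poisson_component(2.5, 3), "integers")
})

test_that("each shifted Poisson mass sums to 1 over its support", {
  for (i in seq_len(nrow(ref_mixture$poisson))) {
    lam <- ref_mixture$poisson$lambda[i]
    k0 <- ref_mixture$poisson$k0[i]
    s <- sum(poisson_component(k0:(k0 + 2000), lam, k0))
    expect_lt(abs(s - 1), 1e-9)
  }
})

test_that("step component is zero before the plateau and continuous at decay", {
  st <- ref_mixture$step
  plateau <- 1 / (29 + 1 / 0.045683)
  expect_equal(step_component(29, st), 0)
  expect_equal(step_component(30, st), plateau)
  expect_equal(step_component(58, st), plateau)
  expect_equal(step_component(59, st), plateau)  # e^0 at the decay start
  expect_equal(step_component(60, st), plateau * exp(-st$gamma))
})

test_that("step discrete mass is within 2% of its continuous normalization", {
  st <- ref_mixture$step
  s <- sum(step_component(0:5000, st))
  expect_lt(abs(s - 1), 0.02)
})

test_that("step mean offset follows its closed formula", {
  st <- ref_mixture$step
  expect_equal(step_mean(st), (29^2 / 2 + 1 / 0.045683) /
                                (29 + 1 / 0.045683))
  # plateau-only limit: gamma large -> mean ~ L_s/2
  st2 <- list(k_start = 0L, L_s = 40L, gamma = 1e6)
  expect_equal(step_mean(st2), 20, tolerance = 1e-3)
  st3 <- list(k_start = 0L, L_s = 1L, gamma = 0.5)
  expect_equal(step_mean(st3), (0.5 + 2) / (1 + 2))
})

test_that("the mixture evaluates to zero when all coefficients are zero", {
  p <- mixture_params(a_bg = 0, L = 10L,
                      poisson = data.frame(a = 0, lambda = 2, k0 = 0L))
  expect_equal(evaluate_mixture(0:20, p)$class_mass, rep(0, 21))
})

test_that("reference component shares at class 10 round to 47/23/30", {
  d <- decompose_mixture(10L, ref_mixture)[1L, ]
  shares <- 100 * d / sum(d)
  expect_equal(round(unname(shares[c("P1", "P3", "P4")])), c(47, 23, 30))
  expect_lt(sum(shares[c("bg", "P2", "P5", "S")]), 1)
})

test_that("total mixture mass equals the coefficient sum", {
  coef_sum <- ref_mixture$a_bg + sum(ref_mixture$poisson$a) +
    ref_mixture$step$a_s
  expect_equal(coef_sum, 0.992297, tolerance = 1e-9)
  total <- sum(evaluate_mixture(0:10000, ref_mixture)$class_mass)
  # the step's discrete mass exceeds its continuous normalizer by ~1%,
  # shifting the total by a_s * (sum(S) - 1); account for it exactly
  step_excess <- ref_mixture$step$a_s *
    (sum(step_component(0:10000, ref_mixture$step)) - 1)
  expect_equal(total, coef_sum + step_excess, tolerance = 1e-9)
  expect_lt(abs(total - coef_sum), 1e-3)
})

test_that("decomposition sums exactly to the mixture and stays non-negative", {
  k <- 0:300
  m <- decompose_mixture(k, ref_mixture)
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), evaluate_mixture(k, ref_mixture)$class_mass)
  # at class 0 only the background and P1 have started
  at0 <- decompose_mixture(0L, ref_mixture)[1L, ]
  expect_true(all(at0[c("bg", "P1")] > 0))
  expect_equal(unname(at0[c("P2", "P3", "P4", "P5", "S")]), rep(0, 5))
})

test_that("negative classes are rejected by evaluate_mixture", {
  expect_error(evaluate_mixture(-1L, ref_mixture), "non-negative")
})

test_that("dominant component matches a brute-force argmax per class", {
  expect_equal(dominant_component(10L, ref_mixture), "P1")
  ids <- dominant_component(0:199, ref_mixture)
  m <- decompose_mixture(0:199, ref_mixture)
  brute <- colnames(m)[apply(m, 1, function(r) which(r == max(r))[1L])]
  expect_equal(ids, brute)
  solo <- mixture_params(a_bg = 0, L = 10L,
                         poisson = data.frame(a = 0.5, lambda = 3,
                                              k0 = 2L))
  expect_equal(dominant_component(5L, solo), "P1")
})

test_that("geometric model reproduces its defining formula", {
  expect_equal(geometric_model(0, 5.2, 2.3), 5.2)
  expect_equal(geometric_model(0:5, 2, 1), rep(2, 6))
  # the published real-data fit explodes ("catastrophic" growth)
  expect_gt(geometric_model(20, 5.2, 2.3), 1e7)
})

test_that("rate summary orders rates by component start class", {
  rs <- rate_summary(ref_mixture)
  expect_equal(rs$component, c("P1", "P2", "P3", "P4", "S", "P5"))
  expect_equal(rs$start_class, c(0, 2, 4, 6, 30, 44))
  expect_equal(rs$rate[c(1:4, 6)],
               c(6.133813, 23.092150, 9.513952, 2.071796, 16.900607))
  expect_equal(rs$rate[5], step_mean(ref_mixture$step))
  expect_equal(order(rs$start_class), seq_len(nrow(rs)))
  solo <- mixture_params(a_bg = 0, L = 10L,
                         poisson = data.frame(a = 1, lambda = 2, k0 = 0L))
  expect_equal(nrow(rate_summary(solo)), 1L)
})

test_that("mixture parameters round-trip through the key-value file", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_mixture_params(ref_mixture, path)
  got <- read_mixture_params(path)
  expect_equal(got$a_bg, ref_mixture$a_bg)
  expect_equal(got$poisson, ref_mixture$poisson)
  expect_equal(got$step, ref_mixture$step)
})
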