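test_that("a single minimal genome is all-extensive iff the baseline counts", {
  rec <- make_records(149L, pc = 140L, ps = 2L, size = 137476)
  on <- cumulative_extensive_fraction(rec, ref_size,
                                      count_baseline_as_extensive = TRUE)
  off <- cumulative_extensive_fraction(rec, ref_size,
                                       count_baseline_as_extensive = FALSE)
  expect_equal(on$ge_over_g, 1)
  expect_equal(off$ge_over_g, 0)
})

test_that("cumulative fractions match a step-by-step accumulation oracle", {
  rec <- make_records(c(2000L, 500L, 10000L),
                      size = c(2.2e6, 6e5, 1.1e7))
  got <- cumulative_extensive_fraction(rec, ref_size)
  # independent accumulation over the sorted series (500, 2000, 10000)
  g <- c(500, 2000, 10000)
  g_prev <- c(ref_size$g0, 500, 2000)
  num <- ref_size$g0
  expected <- numeric(3)
  for (i in 1:3) {
    s_prev <- s_of_g(g_prev[i], ref_size)
    le <- min(ref_size$a * (s_prev - ref_size$s0) + ref_size$le0,
              ref_size$lemax)
    num <- num + (1 - le / ref_size$lemax) * (g[i] - g_prev[i])
    expected[i] <- num / g[i]
  }
  expect_equal(got$gene_number, g)
  expect_equal(got$ge_over_g, expected)
  expect_equal(got$gi_over_g, 1 - got$ge_over_g)
})

test_that("fractions stay in [0,1] and use model (not observed) sizes", {
  set.seed(14)
  tot <- sort(sample(149:60000, 300))
  rec <- make_records(tot, size = round(10^runif(300, 5.5, 10)))
  fr <- cumulative_extensive_fraction(rec, ref_size)
  expect_true(all(fr$ge_over_g >= 0 & fr$ge_over_g <= 1))
  expect_equal(fr$ge_over_g + fr$gi_over_g, rep(1, 300))
  # identical gene counts give identical fractions regardless of the
  # scattered observed sizes (the series is driven by model sizes)
  rec2 <- make_records(tot, size = round(10^runif(300, 5.5, 10)))
  fr2 <- cumulative_extensive_fraction(rec2, ref_size)
  expect_equal(fr$ge_over_g, fr2$ge_over_g)
})

test_that("unsorted input is sorted internally and empties are rejected", {
  rec <- make_records(c(5000L, 200L, 900L))
  fr <- cumulative_extensive_fraction(rec, ref_size)
  expect_equal(fr$gene_number, c(200, 900, 5000))
  expect_error(cumulative_extensive_fraction(rec[0, ], ref_size),
               "no genome records")
  low <- make_records(100L)
  expect_error(cumulative_extensive_fraction(low, ref_size), "g0")
})

test_that("the balance identity holds for every increment", {
  # (lemax - le) dgi = le dge with dge = (1 - le/lemax) dg, dgi = (le/lemax) dg
  s <- seq(ref_size$s0, 2e9, length.out = 200)
  le <- le_of_s(s, ref_size, clamp = TRUE)
  dge <- (1 - le / ref_size$lemax)
  dgi <- le / ref_size$lemax
  expect_equal((ref_size$lemax - le) * dgi, le * dge, tolerance = 1e-12)
})

test_that("empirical fractions match direct per-row arithmetic", {
  rec <- make_records(1000L, pc = 850L, ps = 50L)
  ef <- empirical_fractions(rec)
  expect_equal(ef$pc_ps, 0.9)
  expect_equal(ef$nc, 0.1)
  full <- make_records(1000L, pc = 980L, ps = 20L)
  expect_equal(empirical_fractions(full)$nc, 0)

  set.seed(30)
  tot <- sample(500:20000, 50)
  pc <- round(0.8 * tot); ps <- round(0.05 * tot)
  many <- make_records(tot, pc = pc, ps = ps)
  ef <- empirical_fractions(many)
  expect_equal(ef$pc, pc / tot)
  expect_equal(ef$ps, ps / tot)
  expect_equal(ef$nc, (tot - pc - ps) / tot)
  expect_equal(ef$pc_ps + ef$nc, rep(1, 50))
})

test_that("predicted-vs-empirical comparison is zero on identical series", {
  rec <- make_records(c(300L, 1500L, 8000L))
  fr <- cumulative_extensive_fraction(rec, ref_size)
  fr$empirical_pc_ps <- fr$ge_over_g
  fr$empirical_nc <- fr$gi_over_g
  cmp <- compare_predicted_vs_empirical(fr)
  expect_equal(nrow(cmp$per_genome), 3L)
  expect_equal(cmp$per_genome$diff_extensive, rep(0, 3))
  expect_equal(cmp$summary["extensive", "mean_abs"], 0)
})

test_that("comparison differences sit below the injected split noise", {
  cfg <- simulation_config(n_genomes = 1500, seed = 17,
                           fraction_noise_sigma = 0.04)
  rec <- simulate_genome_records(cfg)
  fr <- cumulative_extensive_fraction(rec, cfg$size_params)
  cmp <- compare_predicted_vs_empirical(fr)
  # mean absolute difference ~ E|N(0, 0.04)| plus rounding, well under sigma
  expect_lt(cmp$summary["extensive", "mean_abs"], 0.04)
  expect_equal(nrow(cmp$per_genome), nrow(rec))
})

test_that("fraction series export round-trips through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- make_records(c(300L, 1500L))
  fr <- cumulative_extensive_fraction(rec, ref_size)
  write_fraction_series(fr, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab), names(fr))
  expect_equal(tab$ge_over_g, fr$ge_over_g, tolerance = 1e-10)
})
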