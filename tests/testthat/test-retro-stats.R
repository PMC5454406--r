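test_that("frequency is His+ over CFU with fraction scaling", {
  expect_equal(frequency(0, 5e6), 0)
  expect_equal(frequency(10, 5e6), 2e-6)
  expect_equal(frequency(10, 5e6, his_fraction = 0.5, cfu_fraction = 0.5),
               frequency(10, 5e6, his_fraction = 0.25, cfu_fraction = 0.25))
  expect_equal(frequency(10, 5e6, his_fraction = 0.1, cfu_fraction = 1e-5),
               (10 / 0.1) / (5e6 / 1e-5))
  expect_error(frequency(1, 0), "positive")
})

test_that("the order-statistic interval brackets the median as expected", {
  s <- median_ci(rep(3.5, 7))
  expect_equal(s$median, 3.5)
  expect_equal(c(s$ci_lower, s$ci_upper), c(3.5, 3.5))

  s7 <- median_ci(as.numeric(1:7))
  expect_equal(s7$median, 4)
  expect_equal(c(s7$ci_lower, s7$ci_upper), c(1, 7))
  expect_gte(s7$achieved_coverage, 0.95)

  # midpoint median for even n
  expect_equal(median_ci(as.numeric(1:8))$median, 4.5)

  # permutation invariance
  set.seed(5)
  x <- rlnorm(7)
  a <- median_ci(x); b <- median_ci(sample(x))
  expect_equal(a$median, b$median)
  expect_equal(c(a$ci_lower, a$ci_upper), c(b$ci_lower, b$ci_upper))

  expect_warning(s3 <- median_ci(c(1, 2, 3)), "full range")
  expect_equal(c(s3$ci_lower, s3$ci_upper), c(1, 3))
})

test_that("the selected order index is monotone in sample size", {
  ks <- vapply(6:40, function(n)
    median_ci(as.numeric(seq_len(n)))$k, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("the n = 7 interval achieves its nominal coverage by simulation", {
  set.seed(1234)
  hits <- 0L
  n_draws <- 2000L
  for (d in seq_len(n_draws)) {
    x <- rlnorm(7, meanlog = -13, sdlog = 1)   # frequencies around 2e-6
    s <- median_ci(x)
    true_med <- exp(-13)
    if (s$ci_lower <= true_med && true_med <= s$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits / n_draws, 0.95)
})

test_that("percent of reference behaves like a ratio of medians", {
  wt <- median_ci(c(1.5, 1.8, 2.1, 1.9, 1.7, 2.0, 1.8) * 1e-6)
  expect_equal(percent_of_reference(wt, wt), 100)
  half <- median_ci(wt$frequencies / 2)
  expect_equal(percent_of_reference(half, wt), 50)
  zero <- median_ci(rep(0, 7))
  expect_error(percent_of_reference(wt, zero), "positive")
})

test_that("a planted relative frequency is estimated without bias", {
  set.seed(99)
  true_rel <- 0.05
  wt_freq <- 2e-6
  est <- replicate(200, {
    wt <- gen_colony_counts(wt_freq, cfu_mean = 1e8, n = 7,
                            seed = sample.int(1e6, 1))
    mu <- gen_colony_counts(wt_freq * true_rel, cfu_mean = 1e8, n = 7,
                            seed = sample.int(1e6, 1))
    s_wt <- median_ci(frequency(wt$his_positive, wt$cfu))
    s_mu <- median_ci(frequency(mu$his_positive, mu$cfu))
    percent_of_reference(s_mu, s_wt)
  })
  expect_lt(abs(mean(est) - 100 * true_rel), 1)
})

test_that("colony count simulation respects its truth", {
  z <- gen_colony_counts(0, seed = 4)
  expect_true(all(z$his_positive == 0L))
  a <- gen_colony_counts(2e-6, seed = 11)
  b <- gen_colony_counts(2e-6, seed = 11)
  expect_identical(a, b)
})

test_that("strain summaries flow from a culture table", {
  counts <- rbind(gen_colony_counts(1.82e-6, n = 7, seed = 1, strain = "WT"),
                  gen_colony_counts(1.82e-6 * 0.04, n = 7, seed = 2,
                                    strain = "M1"))
  tf <- tempfile(fileext = ".tsv")
  write.table(counts, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarize_strains(read_culture_tsv(tf), "WT")
  expect_equal(summ$percent_of_reference[summ$strain == "WT"], 100)
  expect_lt(summ$percent_of_reference[summ$strain == "M1"], 20)
  expect_true(all(summ$ci_lower <= summ$median & summ$median <= summ$ci_upper))
})
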