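test_that("raw reactivity is the treated-minus-control difference", {
  expect_equal(compute_raw_reactivity(c(3, 4, 5), c(3, 4, 5)), c(0, 0, 0))
  expect_equal(compute_raw_reactivity(c(3, 4, 5), c(0, 0, 0)), c(3, 4, 5))
  expect_equal(compute_raw_reactivity(c(5, 2, 9), c(1, 3, 4)), c(4, -1, 5))
  expect_error(compute_raw_reactivity(1:3, 1:4), "length")
  expect_error(compute_raw_reactivity(c(-1, 2), c(0, 0)), "nonnegative")
})

test_that("boxplot normalization matches an independent quantile oracle", {
  raw <- as.numeric(1:100)
  bn <- boxplot_normalize(raw)
  # oracle: stats::quantile type 7 + direct sorting
  q <- unname(stats::quantile(raw, c(0.25, 0.75), type = 7))
  fence <- q[2] + 1.5 * (q[2] - q[1])
  out_oracle <- which(raw > fence)
  keep <- setdiff(seq_along(raw), out_oracle)
  top <- sort(raw[keep], decreasing = TRUE)[seq_len(ceiling(0.1 * length(keep)))]
  expect_equal(sort(bn$outliers), out_oracle)
  expect_equal(bn$scale_factor, mean(top))
  expect_equal(bn$values, raw / mean(top))
})

test_that("normalization handles constant and degenerate inputs", {
  expect_equal(boxplot_normalize(rep(2.5, 20))$values, rep(1, 20))
  expect_error(boxplot_normalize(rep(0, 20)), "degenerate")
  expect_error(boxplot_normalize(c(1, 2, 3)), "at least 10")
})

test_that("normalization is invariant to positive rescaling and its top set averages 1", {
  set.seed(42)
  for (rep_i in 1:20) {
    raw <- rgamma(60, shape = 1, rate = 2) - 0.05  # includes negatives
    bn1 <- boxplot_normalize(raw)
    bn2 <- boxplot_normalize(raw * 37.5)
    expect_equal(bn1$values, bn2$values, tolerance = 1e-12)
    expect_lt(abs(mean(bn1$values[bn1$top_set]) - 1), 1e-9)
  }
})

test_that("SD filter excludes exactly the positions above threshold", {
  # sd of (x - d, x, x + d) across three replicates is exactly d
  base <- c(0.5, 0.8)
  d <- c(0.71, 0.69)
  reps <- lapply(c(-1, 0, 1), function(s) base + s * d)
  mask <- filter_by_sd(reps, threshold = 0.7)
  expect_identical(mask, c(TRUE, FALSE))
  expect_false(any(filter_by_sd(reps, threshold = Inf)))
  ident <- list(c(1, 2, 3), c(1, 2, 3))
  expect_false(any(filter_by_sd(ident)))
  expect_warning(m1 <- filter_by_sd(matrix(1:5)), "single replicate")
  expect_false(any(m1))
})

test_that("SD filter is monotone in its threshold", {
  set.seed(7)
  reps <- replicate(3, rnorm(50, sd = 0.8), simplify = FALSE)
  thresholds <- c(0.1, 0.3, 0.5, 0.7, 1.2, 2)
  masks <- lapply(thresholds, function(th) filter_by_sd(reps, th))
  for (t in seq_along(thresholds)[-1])
    expect_true(all(masks[[t]] <= masks[[t - 1]]))
})

test_that("composite merge averages overlaps and leaves gaps missing", {
  p1 <- rep(0.2, 100)
  expect_equal(composite_merge(list(p1), 1L)$values, p1)

  a <- rep(0.4, 100); b <- rep(0.8, 51)
  merged <- composite_merge(list(a, b), c(1L, 50L))
  expect_equal(merged$values[50:100], rep((0.4 + 0.8) / 2, 51))
  expect_equal(merged$values[1:49], rep(0.4, 49))

  disj <- composite_merge(list(rep(1, 10), rep(2, 10)), c(1L, 21L))
  expect_true(all(is.na(disj$values[11:20])))
  expect_equal(disj$values[1:10], rep(1, 10))
  # coverage conservation: non-missing implies covered
  expect_true(all(disj$n_contrib[!is.na(disj$values)] >= 1L))
  expect_true(all(is.na(disj$values[disj$n_contrib == 0L])))
})

test_that(".shape files round-trip with -999 for missing positions", {
  v <- c(0.1, NA, 1.4, -0.2, NA)
  tf <- tempfile(fileext = ".shape")
  write_shape(v, tf)
  back <- read_shape(tf)
  expect_equal(back$values, v, tolerance = 1e-6)
  lines <- readLines(tf)
  expect_match(lines[2], "-999")
})

test_that("the replicate processing chain runs end to end", {
  set.seed(11)
  truth <- gen_structured_sequence(seed = 3)
  sim <- simulate_shape(truth, seed = 5)
  proc <- process_replicates(sim$replicates)
  expect_length(proc$values, nchar(truth$seq))
  expect_equal(length(proc$scale_factors), 3L)
  expect_true(all(proc$scale_factors > 0))
  # normalized reactivity tracks unpairedness (rank correlation > 0)
  ok <- !is.na(proc$values)
  rho <- cor(proc$values[ok], as.numeric(sim$unpaired)[ok],
             method = "spearman")
  expect_gt(rho, 0.5)
})
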