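test_that("energy_of scores an isolated helix as stacks plus hairpin", {
  seq <- "GGGGAAACCCC"
  st <- rna_structure(cbind(1:4, 11:8), 11)
  model <- default_energy_model()
  hand <- 3 * model$stack["GC", "GC"] + hairpin_penalty(3, model)
  expect_equal(energy_of(st, seq, model), hand)
  expect_equal(energy_of(rna_structure(NULL, 11), seq, model), 0)
  expect_error(energy_of(rna_structure(cbind(1, 7), 11), seq, model),
               "illegal")
})

test_that("a homopolymer folds to no pairs and empty input to an empty structure", {
  f <- mfe_fold(strrep("A", 30))
  expect_equal(n_pairs(f), 0L)
  expect_equal(attr(f, "energy"), 0)
  f0 <- mfe_fold("")
  expect_equal(f0$length, 0L)
  expect_equal(attr(f0, "energy"), 0)
})

test_that("DP minimum equals exhaustive enumeration on random short sequences", {
  set.seed(101)
  model <- default_energy_model()
  for (case_i in 1:40) {
    n <- sample(5:16, 1)
    seq <- random_rna(n)
    shape <- if (case_i %% 2 == 0) round(runif(n, 0, 2), 2) else NULL
    f <- mfe_fold(seq, model, shape = shape)
    oracle <- brute_min_energy(seq, model, shape = shape)
    expect_equal(attr(f, "energy"), oracle$energy, tolerance = 1e-6,
                 info = seq)
    # the DP's structure rescored by the standalone scorer gives its energy
    expect_equal(energy_of(f, seq, model, shape = shape),
                 attr(f, "energy"), tolerance = 1e-6, info = seq)
  }
})

test_that("folding is deterministic", {
  set.seed(55)
  seq <- random_rna(60)
  f1 <- mfe_fold(seq); f2 <- mfe_fold(seq)
  expect_identical(f1$pairs, f2$pairs)
  s1 <- shapeknots_fold(seq); s2 <- shapeknots_fold(seq)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("high reactivity on one strand opens a hairpin the unrestrained fold keeps", {
  # 9-bp AU-rich hairpin: stable without restraints, marginal with them
  stem5 <- "GAUAUAUAU"
  hp <- paste0(stem5, "CAAC", rna_revcomp(stem5))
  f0 <- mfe_fold(hp)
  expect_gt(n_pairs(f0), 6L)
  shape <- rep(0, nchar(hp))
  shape[1:9] <- 2.0
  f1 <- mfe_fold(hp, shape = shape)
  expect_lt(n_pairs(f1), n_pairs(f0))
})

test_that("raising reactivity on a helix strand never increases its presence", {
  stem5 <- "GGAUAUAUG"
  hp <- paste0("AA", stem5, "AAAC", rna_revcomp(stem5), "CA")
  strand <- 3:11
  helix_pairs <- function(f) {
    p <- partner_vector(f)
    sum(p[strand] > 0)
  }
  counts <- vapply(seq(0, 3, by = 0.25), function(s) {
    shape <- rep(0, nchar(hp)); shape[strand] <- s
    helix_pairs(mfe_fold(hp, shape = shape))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the pseudoknot heuristic never returns worse than the nested fold", {
  set.seed(77)
  for (case_i in 1:10) {
    seq <- random_rna(sample(30:60, 1))
    en_nested <- attr(mfe_fold(seq), "energy")
    en_pk <- attr(shapeknots_fold(seq), "energy")
    expect_lte(en_pk, en_nested + 1e-9)
  }
})

test_that("a sequence with no crossing-compatible helix folds identically either way", {
  seq <- "GGGGAAACCCCAAAAA"   # single hairpin, nothing to cross
  f <- mfe_fold(seq)
  s <- shapeknots_fold(seq)
  expect_identical(s$pairs, f$pairs)
  expect_null(attr(s, "pk_helix"))
})

test_that("the heuristic is optimal over its forced-helix search space on short sequences", {
  set.seed(303)
  model <- default_energy_model()
  for (case_i in 1:12) {
    n <- sample(12:16, 1)
    seq <- random_rna(n, bases = c("G", "C", "A", "U", "G", "C"))
    sk <- shapeknots_fold(seq, max_candidates = 1000L)
    best <- brute_min_energy(seq, model)$energy
    chars <- rna_chars(seq)
    # every structure made of one forced maximal-run helix plus a nested
    # remainder: helix stacks summed by hand, remainder scored by energy_of,
    # one pseudoknot initiation charge
    for (run in maximal_runs_oracle(seq, model$min_hairpin)) {
      hel <- cbind(run[["i"]] + 0:(run[["len"]] - 1L),
                   run[["j"]] - 0:(run[["len"]] - 1L))
      hel_e <- 0
      if (nrow(hel) >= 2L) for (r in seq_len(nrow(hel) - 1L))
        hel_e <- hel_e + stack_energy(
          pair_class(chars[hel[r, 1]], chars[hel[r, 2]]),
          pair_class(chars[hel[r + 1, 1]], chars[hel[r + 1, 2]]), model)
      rest_ok <- setdiff(seq_len(n), c(hel))
      for (p in enum_nested_structures(seq, model$min_hairpin)) {
        if (!is.null(p) && !all(c(p) %in% rest_ok)) next
        rest_e <- energy_of(rna_structure(p, n,
                                          min_hairpin = model$min_hairpin),
                            seq, model)
        best <- min(best, rest_e + hel_e + model$pk_init_penalty)
      }
    }
    expect_true(attr(sk, "energy") <= best + 1e-6, info = seq)
  }
})

test_that("a planted pseudoknot with informative SHAPE is recovered", {
  truth <- gen_structured_sequence(seed = 42)
  sim <- simulate_shape(truth, seed = 42)
  proc <- process_replicates(sim$replicates)
  fold <- shapeknots_fold(truth$seq, shape = proc$values)
  got <- paste(fold$pairs[, 1], fold$pairs[, 2])
  want <- paste(truth$pk_pairs[, 1], truth$pk_pairs[, 2])
  expect_gt(mean(want %in% got), 0.9)
  expect_true(has_crossing(fold))
})
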