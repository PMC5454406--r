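test_that("apical windows cover the loop plus k stem pairs", {
  # stem 1..5 : 20..16, loop 6..15? no: make loop 3 nt: pairs (1..5, 13..9)
  st <- rna_structure(cbind(1:5, 13:9), 13)
  seq <- "GGGGGAAACCCCC"
  m2 <- apical_motif(st, seq, 1, k = 2)
  expect_equal(m2$window, c(4L, 10L))
  expect_equal(nchar(m2$seq), 7L)          # 3-nt loop + 2 pairs
  m0 <- apical_motif(st, seq, 1, k = 0)
  expect_equal(m0$window, c(6L, 8L))       # loop only
  expect_error(apical_motif(st, seq, 1, k = 6), "exceeds")
})

test_that("a 4-nt loop with k = 3 gives a 10-nt window", {
  st <- rna_structure(cbind(1:4, 12:9), 14)
  seq <- "GGGGAAAACCCCAA"
  m <- apical_motif(st, seq, 1, k = 3)
  expect_equal(diff(m$window) + 1L, 10L)   # loop + 2k
})

test_that("the printed apical motifs form a full 7-bp duplex under strict WC", {
  d <- duplex_score("AUUCUGU", "ACAGAAU", allow_wobble = FALSE)
  expect_equal(d$duplex_length, 7L)
  expect_equal(nrow(d$map), 7L)
  expect_false(d$wobble_used)
  expect_equal(duplex_score("AAAA", "AAAA")$duplex_length, 0L)
})

test_that("duplex scoring matches the exhaustive oracle and is symmetric", {
  set.seed(23)
  for (case_i in 1:50) {
    a <- random_rna(7); b <- random_rna(7)
    d_ab <- duplex_score(a, b)
    expect_equal(d_ab$duplex_length, duplex_oracle(a, b), info = paste(a, b))
    expect_equal(duplex_score(b, a)$duplex_length, d_ab$duplex_length)
    # with wobble disabled every reported pairing is strict WC
    if (nrow(d_ab$map)) {
      cls <- pair_class(rna_chars(a)[d_ab$map[, 1]],
                        rna_chars(b)[d_ab$map[, 2]])
      expect_true(all(cls %in% c("GC", "AU")))
    }
    expect_gte(duplex_score(a, b, allow_wobble = TRUE)$duplex_length,
               d_ab$duplex_length)
  }
})

test_that("the planted complementary motif pair is found as a symmetric complex", {
  truth <- gen_structured_sequence(seed = 9)
  win_a <- substr(truth$seq, truth$motif_a[1], truth$motif_a[2])
  win_b <- substr(truth$seq, truth$motif_b[1], truth$motif_b[2])
  expect_equal(duplex_score(win_a, win_b)$duplex_length, nchar(win_a))

  hits <- scan_kissing_pairs(truth$structure, truth$seq)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_equal(top$duplex_length, 7L)
  expect_true(top$symmetric_complex)
  # the top candidate joins the two planted hairpins
  expect_true(top$window_a_start <= truth$motif_a[2] &&
                top$window_a_end >= truth$motif_a[1])
  expect_true(top$window_b_start <= truth$motif_b[2] &&
                top$window_b_end >= truth$motif_b[1])
})

test_that("a single non-self-complementary hairpin yields no candidates", {
  st <- rna_structure(cbind(1:5, 13:9), 13)
  hits <- scan_kissing_pairs(st, "GGGGGAAACCCCC")
  expect_equal(nrow(hits), 0L)
})

test_that("min_len gates candidates at the duplex length", {
  # two hairpins whose 7-nt apical windows (GCAAAGC and ACUUUGU) share
  # exactly 5 consecutive WC pairs: CAAAG against CUUUG
  seq <- paste0("AA", "AUGC", "AAA", "GCAU",       # hairpin A (3..13)
                "AAAA", "GCAC", "UUU", "GUGC", "AA")  # hairpin B (18..28)
  pairs <- rbind(cbind(3:6, 13:10), cbind(18:21, 28:25))
  st <- rna_structure(pairs, nchar(seq))
  h5 <- scan_kissing_pairs(st, seq, min_len = 5L)
  h6 <- scan_kissing_pairs(st, seq, min_len = 6L)
  cross <- function(h) h[h$hairpin_a != h$hairpin_b, , drop = FALSE]
  expect_equal(max(0L, cross(h5)$duplex_length), 5L)
  expect_equal(nrow(cross(h6)), 0L)
})

test_that("scan ranking is stable under molecule-copy relabeling", {
  truth <- gen_structured_sequence(seed = 31)
  h1 <- scan_kissing_pairs(truth$structure, truth$seq,
                           x2 = truth$structure, seq2 = truth$seq)
  h2 <- scan_kissing_pairs(truth$structure, truth$seq,
                           x2 = truth$structure, seq2 = truth$seq)
  expect_identical(h1, h2)
  sym <- h1[h1$symmetric_complex, , drop = FALSE]
  expect_gte(nrow(sym), 1L)
})

test_that("palindrome scanning matches the exhaustive window oracle", {
  expect_equal(palindrome_scan("GAAUUC")$length, 6L)
  expect_equal(nrow(palindrome_scan(strrep("A", 30))), 0L)
  set.seed(47)
  for (case_i in 1:20) {
    seq <- random_rna(sample(20:60, 1))
    got <- palindrome_scan(seq, min_len = 6L)
    want <- palindrome_oracle(seq, min_len = 6L)
    expect_equal(nrow(got), length(want), info = seq)
    if (length(want)) {
      want_df <- do.call(rbind, want)
      expect_equal(got$start, unname(want_df[, "start"]), info = seq)
      expect_equal(got$end, unname(want_df[, "end"]), info = seq)
    }
  }
  expect_error(palindrome_scan("ACGU", min_len = 5L), "even")
})
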