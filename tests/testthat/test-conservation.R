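make_aln <- function(seqs, groups, ref = names(seqs)[1]) {
  grouped_alignment(seqs, setNames(groups, names(seqs)), ref)
}

test_that("column mapping follows the reference's gaps", {
  aln <- make_aln(c(r = "ACGU", s = "ACGU"), c("g1", "g1"))
  expect_equal(map_columns_to_reference(aln), 1:4)

  aln2 <- make_aln(c(r = "A-CG", s = "AACG"), c("g1", "g1"))
  expect_equal(map_columns_to_reference(aln2), c(1L, NA, 2L, 3L))
})

test_that("identical sequences are ALL_CONSERVED everywhere", {
  aln <- make_aln(c(a = "ACGUACGU", b = "ACGUACGU", c = "ACGUACGU"),
                  c("f", "f", "o"))
  track <- classify_conservation(aln, "f")
  expect_true(all(track == "ALL_CONSERVED"))
})

test_that("the three categories separate focal and non-focal variation", {
  #          pos: 12345
  aln <- make_aln(c(f1 = "ACGUA",
                    f2 = "ACGUC",      # focal sub at 5 -> VARIABLE
                    o1 = "AGGUC"),     # non-focal subs at 2, 5
                  c("focal", "focal", "other"))
  track <- classify_conservation(aln, "focal")
  expect_equal(as.character(track),
               c("ALL_CONSERVED", "GROUP_CONSERVED", "ALL_CONSERVED",
                 "ALL_CONSERVED", "VARIABLE"))
})

test_that("gaps fail the conservation tests strictly", {
  aln <- make_aln(c(f1 = "ACGU", f2 = "AC-U", o1 = "ACGU"),
                  c("f", "f", "o"))
  track <- classify_conservation(aln, "f")
  expect_equal(as.character(track)[3], "VARIABLE")

  aln2 <- make_aln(c(f1 = "ACGU", f2 = "ACGU", o1 = "AC-U"),
                   c("f", "f", "o"))
  expect_equal(as.character(classify_conservation(aln2, "f"))[3],
               "GROUP_CONSERVED")
})

test_that("comparison ignores case and the T/U distinction", {
  aln <- make_aln(c(f1 = "acgt", f2 = "ACGU", o1 = "AcGu"),
                  c("f", "f", "o"))
  expect_true(all(classify_conservation(aln, "f") == "ALL_CONSERVED"))
})

test_that("classification is invariant to sequence order", {
  gen <- gen_alignment(ref_length = 60L, seed = 13)
  t1 <- classify_conservation(gen$alignment, c("Ty1_S288C", "Ty1_other"))
  perm <- sample(length(gen$alignment$seqs))
  aln2 <- grouped_alignment(gen$alignment$seqs[perm],
                            gen$alignment$groups[perm],
                            gen$alignment$reference_id)
  t2 <- classify_conservation(aln2, c("Ty1_S288C", "Ty1_other"))
  expect_equal(as.character(t1), as.character(t2))
})

test_that("planted conservation categories are recovered exactly", {
  for (seed in 1:10) {
    gen <- gen_alignment(ref_length = 80L, seed = seed)
    track <- classify_conservation(gen$alignment,
                                   c("Ty1_S288C", "Ty1_other"))
    expect_equal(as.character(track), as.character(gen$truth_track),
                 info = paste("seed", seed))
  }
})

test_that("interval summaries count every position exactly once", {
  gen <- gen_alignment(ref_length = 100L, seed = 3)
  track <- classify_conservation(gen$alignment, c("Ty1_S288C", "Ty1_other"))
  for (iv in list(c(1L, 100L), c(10L, 62L), c(42L, 42L))) {
    s <- summarize_interval(track, iv)
    expect_equal(sum(s$count), iv[2] - iv[1] + 1L)
    expect_equal(sum(s$fraction), 1)
  }
  s1 <- summarize_interval(track, c(42L, 42L))
  expect_true(all(s1$count %in% 0:1))
  # planted counts match the truth over an interval
  iv <- c(11L, 63L)
  s <- summarize_interval(track, iv)
  want <- table(factor(gen$truth_track[iv[1]:iv[2]],
                       levels = levels(gen$truth_track)))
  expect_equal(s$count, as.integer(want))
})

test_that("alignment files round-trip through the fasta reader", {
  gen <- gen_alignment(ref_length = 40L, seed = 8)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(gen$alignment$seqs), "\n",
                    gen$alignment$seqs), fa)
  mf <- tempfile(fileext = ".tsv")
  write.table(gen$manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- read_grouped_alignment(fa, mf, gen$alignment$reference_id)
  expect_equal(length(aln$seqs), 102L)
  expect_equal(sum(aln$groups %in% c("Ty1_S288C", "Ty1_other")), 66L)
  t1 <- classify_conservation(aln, c("Ty1_S288C", "Ty1_other"))
  expect_equal(as.character(t1), as.character(gen$truth_track))
})
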