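test_that("a single hairpin decomposes into one stem and one loop", {
  st <- rna_structure(cbind(1:4, 12:9), 12)
  el <- enumerate_elements(st)
  expect_equal(nrow(el$stems), 1L)
  expect_equal(el$stems$length, 4L)
  expect_length(el$hairpins, 1L)
  expect_equal(el$hairpins[[1]]$positions, 5:8)
  expect_length(el$bulges, 0L)
  expect_length(el$internals, 0L)
  expect_length(el$multibranch, 0L)
})

test_that("a single bulged nucleotide splits a stem unless collapsed", {
  # helix (1..3 : 20..18), bulge at 4, helix (5..7 : 17..15)
  pairs <- rbind(cbind(1:3, 20:18), cbind(5:7, 17:15))
  st <- rna_structure(pairs, 20)
  el <- enumerate_elements(st)
  expect_equal(nrow(el$stems), 2L)
  expect_length(el$bulges, 1L)
  expect_equal(el$bulges[[1]]$positions, 4L)
  el2 <- enumerate_elements(st, collapse_single_bulges = TRUE)
  expect_equal(nrow(el2$stems), 1L)
  expect_equal(el2$stems$length, 6L)
})

test_that("every position lands in exactly one element of a nested structure", {
  set.seed(19)
  for (case_i in 1:25) {
    n <- sample(15:40, 1)
    st <- random_nested_structure(n)
    el <- enumerate_elements(st)
    loop_pos <- unlist(lapply(c(el$hairpins, el$bulges, el$internals,
                                el$multibranch), `[[`, "positions"))
    paired <- c(st$pairs)
    everything <- sort(c(loop_pos, el$exterior, paired))
    expect_identical(everything, 1:n)

    # hairpin loops verified against a direct innermost-pair check
    p <- partner_vector(st)
    for (h in el$hairpins) {
      i <- h$closing[1]; j <- h$closing[2]
      expect_true(all(p[(i + 1):(j - 1)] == 0))
    }
  }
})

test_that("the printed pseudoknot coordinates yield the S1/L2/S2 core", {
  pairs <- rbind(cbind(1:7, 271L - (1:7)), cbind(255:262, 581L - (255:262)))
  st <- rna_structure(pairs, 340)
  core <- pseudoknot_core(st)
  expect_equal(core$S1_length, 7L)
  expect_equal(core$S2_length, 8L)
  expect_equal(core$L2_positions, 263L)
  expect_equal(core$span_3prime, 326L)
  expect_equal(core$L1_span, c(8L, 254L))
  expect_equal(core$L3_span, c(271L, 318L))
})

test_that("a lengthened interhelical loop leaves the stems unchanged", {
  # the L2-insertion variant: S1 shifted 3 nt downstream, L2 = 4 nt
  pairs <- rbind(cbind(1:7, 274L - (1:7)), cbind(255:262, 584L - (255:262)))
  st <- rna_structure(pairs, 340)
  core <- pseudoknot_core(st)
  expect_equal(core$S1_length, 7L)
  expect_equal(core$S2_length, 8L)
  expect_equal(core$L2_positions, 263:266)
})

test_that("core extraction is invariant under coordinate shifts", {
  base <- rbind(cbind(1:7, 271L - (1:7)), cbind(255:262, 581L - (255:262)))
  core0 <- pseudoknot_core(rna_structure(base, 340))
  shift <- 17L
  core1 <- pseudoknot_core(rna_structure(base + shift, 360))
  expect_equal(core1$S1_length, core0$S1_length)
  expect_equal(core1$S2_length, core0$S2_length)
  expect_equal(core1$L2_positions, core0$L2_positions + shift)
  expect_equal(core1$span_3prime, core0$span_3prime + shift)
})

test_that("nested structures have no pseudoknot core", {
  st <- rna_structure(cbind(1:4, 12:9), 12)
  expect_null(pseudoknot_core(st))
})

test_that("more than one crossing family is rejected", {
  pairs <- rbind(cbind(1:3, 20:18), cbind(10:12, 28:26),
                 cbind(40:42, 60:58), cbind(50:52, 70:68))
  st <- rna_structure(pairs, 80)
  expect_error(pseudoknot_core(st), "unsupported")
})

test_that("motif intervals validate and measure correctly", {
  mot <- annotate_motifs(data.frame(name = c("CYC5", "single", "PBS"),
                                    start = c(155L, 5L, 95L),
                                    end = c(168L, 5L, 104L)),
                         seq_length = 400L)
  expect_equal(mot$length, c(14L, 1L, 10L))
  expect_error(annotate_motifs(data.frame(name = "x", start = 390L,
                                          end = 410L), 400L),
               "out of range")
})

test_that("BED export converts to 0-based half-open coordinates", {
  tf <- tempfile(fileext = ".bed")
  export_bed(data.frame(name = "m", start = 155L, end = 168L), tf)
  f <- read.table(tf, sep = "\t")
  expect_equal(f$V2, 154L)
  expect_equal(f$V3, 168L)
  expect_equal(f$V3 - f$V2, 14L)
})
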