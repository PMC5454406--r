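#!/usr/bin/env Rscript
# Stage 4: scan the predicted structure for complementary apical motif
# pairs (kissing-loop candidates) and palindromic runs.

suppressPackageStartupMessages(library(tipirt))
seq <- as.character(Biostrings::readBStringSet("results/simdata/leader.fasta")[[1]])
fold <- read_ct("results/structure.ct")$structure
shape <- read_shape("results/reactivity.shape")

kiss <- scan_kissing_pairs(fold, seq, k = 2L, min_len = 6L,
                           reactivity = shape)
write.table(kiss, "results/kissing_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pal <- palindrome_scan(seq, min_len = 6L)
write.table(pal, "results/palindromes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Kissing candidates (duplex >= 6 bp): %d, symmetric: %d\n",
            nrow(kiss), sum(kiss$symmetric_complex)))
if (nrow(kiss)) {
  top <- kiss[1, ]
  cat(sprintf("  top: %s (%d-%d) x %s (%d-%d), %d bp duplex\n",
              top$seq_a, top$window_a_start, top$window_a_end,
              top$seq_b, top$window_b_start, top$window_b_end,
              top$duplex_length))
}
cat(sprintf("Palindromic runs >= 6 nt: %d\n", nrow(pal)))
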