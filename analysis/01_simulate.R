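#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
# A structured sequence with the planted S1/L2/S2 pseudoknot and the
# complementary apical motif pair, three replicate SHAPE intensity tables,
# a 102-sequence grouped alignment with planted conservation categories,
# and colony counts for a wild-type and a mutant strain.

suppressPackageStartupMessages(library(tipirt))
SEED <- 1L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- gen_structured_sequence(seed = SEED)
writeLines(c(">synthetic_leader", truth$seq), file.path(out, "leader.fasta"))
jsonlite::write_json(
  list(seed = SEED, length = nchar(truth$seq),
       pk_pairs = apply(truth$pk_pairs, 1, function(p) list(i = p[1], j = p[2])),
       motif_a = truth$motif_a, motif_b = truth$motif_b,
       elements = truth$elements),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

sim <- simulate_shape(truth, seed = SEED)
for (r in seq_along(sim$replicates))
  write.table(sim$replicates[[r]],
              file.path(out, sprintf("intensities_rep%d.tsv", r)),
              sep = "\t", quote = FALSE, row.names = FALSE)

gen <- gen_alignment(reference = truth$seq, seed = SEED)
writeLines(paste0(">", names(gen$alignment$seqs), "\n", gen$alignment$seqs),
           file.path(out, "alignment.fasta"))
write.table(gen$manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_conservation_tsv(gen$truth_track, file.path(out, "truth_conservation.tsv"))

counts <- rbind(gen_colony_counts(1.82e-6, n = 7, seed = SEED, strain = "WT"),
                gen_colony_counts(1.82e-6 * 0.04, n = 7, seed = SEED + 100L,
                                  strain = "S1_mut"),
                gen_colony_counts(1.82e-6 * 0.07, n = 7, seed = SEED + 200L,
                                  strain = "SL3a_mut"))
write.table(counts, file.path(out, "colony_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated bundle written to", out, "\n")
cat(sprintf("  sequence: %d nt, %d planted pairs (%d in the pseudoknot)\n",
            nchar(truth$seq), n_pairs(truth$structure), nrow(truth$pk_pairs)))
cat(sprintf("  alignment: %d sequences, %d focal\n",
            length(gen$alignment$seqs),
            sum(gen$alignment$groups %in% c("Ty1_S288C", "Ty1_other"))))
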