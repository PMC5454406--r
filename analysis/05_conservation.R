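#!/usr/bin/env Rscript
# Stage 5: map the grouped alignment onto reference coordinates, classify
# each position into the three conservation categories and summarize the
# motif windows.

suppressPackageStartupMessages(library(tipirt))
manifest <- read.table("results/simdata/manifest.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
aln <- read_grouped_alignment("results/simdata/alignment.fasta", manifest,
                              reference_id = manifest$id[1])
focal <- c("Ty1_S288C", "Ty1_other")
track <- classify_conservation(aln, focal)
write_conservation_tsv(track, "results/conservation.tsv")
write_conservation_bed(track, "results/conservation.bed")

truth <- read.table("results/simdata/truth_conservation.tsv", header = TRUE,
                    sep = "\t")
cat(sprintf("Classified %d positions over %d sequences (%d focal)\n",
            length(track), length(aln$seqs), sum(aln$groups %in% focal)))
cat(sprintf("  exact agreement with the planted categories: %.1f%%\n",
            100 * mean(as.character(track) == truth$category)))
print(summarize_interval(track, c(1L, min(53L, length(track)))))
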