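#!/usr/bin/env Rscript
# Stage 3: SHAPE-restrained folding with pseudoknot discovery, then
# structural annotation: stems/loops, the S1/L2/S2 pseudoknot core, and a
# comparison against the planted truth.

suppressPackageStartupMessages(library(tipirt))
seq <- as.character(Biostrings::readBStringSet("results/simdata/leader.fasta")[[1]])
shape <- read_shape("results/reactivity.shape")

fold <- shapeknots_fold(seq, shape = shape)
write_ct(fold, seq, "results/structure.ct")
writeLines(c(">synthetic_leader", seq, as_dotbracket(fold)),
           "results/structure.db")

core <- pseudoknot_core(fold)
el <- enumerate_elements(fold)
export_bed(data.frame(name = paste0("stem", seq_len(nrow(el$stems))),
                      start = el$stems$i5, end = el$stems$j3),
           "results/stems.bed")
jsonlite::write_json(
  list(energy = attr(fold, "energy"), n_pairs = n_pairs(fold),
       pseudoknotted = has_crossing(fold),
       S1_length = core$S1_length, S2_length = core$S2_length,
       L2 = core$L2_positions,
       L1_span = core$L1_span, L3_span = core$L3_span,
       span_3prime = core$span_3prime),
  "results/structure_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

truth <- jsonlite::read_json("results/simdata/truth.json",
                             simplifyVector = TRUE)
want <- paste(truth$pk_pairs$i, truth$pk_pairs$j)
got <- paste(fold$pairs[, 1], fold$pairs[, 2])
cat(sprintf("Fold: %.2f kcal/mol, %d pairs, pseudoknotted: %s\n",
            attr(fold, "energy"), n_pairs(fold), has_crossing(fold)))
print(core)
cat(sprintf("Planted pseudoknot pairs recovered: %d / %d\n",
            sum(want %in% got), length(want)))
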