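#!/usr/bin/env Rscript
# Stage 6: per-culture retrotransposition frequencies, per-strain medians
# with exact order-statistic 95% confidence intervals, and
# percent-of-wild-type summaries.

suppressPackageStartupMessages(library(tipirt))
counts <- read_culture_tsv("results/simdata/colony_counts.tsv")
summ <- summarize_strains(counts, reference_strain = "WT", level = 0.95)
write.table(summ, "results/retro_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summ, digits = 3)
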