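#!/usr/bin/env Rscript

# Stage 3: compositional summaries.
#
# Intensity-weighted molecular weight, DBE and AImod per sample, compound
# category percentages on formula counts, heteroatom-group abundances on
# intensities, and exclusivity statistics.

library(domchar)

raw <- read.delim("results/assigned_table.tsv", check.names = FALSE)
mat <- as.matrix(raw[, -1])
rownames(mat) <- raw$formula
tab <- structure(list(intensity = mat, formulas = parse_formula(raw$formula)),
                 class = "assigned_table")

st <- summarize_table(tab)
write.table(st, "results/sample_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

arom <- st$A_Or + st$A_Op
message(sprintf("aromatic formula share: %.1f-%.1f%% (terrestrial-like high)",
                min(arom), max(arom)))
message(sprintf("exclusive formulas: %.1f-%.1f%% of the dataset per sample",
                min(st$pct_exclusive), max(st$pct_exclusive)))
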