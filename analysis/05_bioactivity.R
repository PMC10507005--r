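#!/usr/bin/env Rscript

# Stage 5: bioactivity quantification and descriptor-activity regressions.
#
# Replicate-wise IC50 by log-linear interpolation (censored series reported
# as ">200" as screened plates are), then linear regressions of
# -log10(IC50) on aromaticity-related descriptors and the first ordination
# axis.

library(domchar)

plate <- read.delim("results/data/bioassay.tsv")
ic <- ic50_table(plate)
write.table(ic, "results/ic50_table.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

st <- read.delim("results/sample_summary.tsv")
sc <- read.delim("results/pcoa_scores.tsv")
y <- -log10(ic$ic50_mean[match(st$sample_id, ic$sample_id)])
descs <- list(aromatic_pct = st$A_Or + st$A_Op, dbe_w = st$dbe_w,
              aimod_w = st$aimod_w,
              pco1 = sc$PCo1[match(st$sample_id, sc$sample_id)])
regs <- do.call(rbind, lapply(names(descs), function(nm)
  cbind(descriptor = nm, regress_bioactivity(descs[[nm]], y))))
write.table(regs, "results/bioactivity_regressions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (i in seq_len(nrow(regs)))
  message(sprintf("-log10(IC50) ~ %s: R2 = %.2f%s", regs$descriptor[i],
                  regs$r2[i], regs$stars[i]))
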