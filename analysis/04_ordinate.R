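#!/usr/bin/env Rscript

# Stage 4: ordination.
#
# Bray-Curtis dissimilarities of the normalized formula intensities,
# principal coordinate analysis, and post-hoc fitting of the compound
# category percentages and weighted descriptors with 10,000 permutations
# (significance at p < 0.1).

library(domchar)

raw <- read.delim("results/assigned_table.tsv", check.names = FALSE)
mat <- as.matrix(raw[, -1])
rownames(mat) <- raw$formula

ord <- pcoa(bray_curtis_matrix(mat))
write.table(data.frame(sample_id = rownames(ord$scores), ord$scores,
                       check.names = FALSE),
            "results/pcoa_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues),
            "results/pcoa_eigenvalues.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

st <- read.delim("results/sample_summary.tsv")
descs <- st[match(rownames(ord$scores), st$sample_id),
            c(category_levels(), "dbe_w", "aimod_w", "mw_w")]
ef <- envfit_all(ord, descs, n_perm = 10000, alpha = 0.1, seed = 2024)
write.table(ef, "results/envfit.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message(sprintf("PCo1 + PCo2 explain %.1f%% of the molecular variability",
                100 * sum(ord$explained[1:2])))
sig <- ef$descriptor[which(ef$significant)]
message("descriptors significant at p < 0.1: ", paste(sig, collapse = ", "))
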