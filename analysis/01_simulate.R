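#!/usr/bin/env Rscript

# Stage 1: simulate a two-source DOM study.
#
# Twelve samples -- six from a terrestrial, aromatic-rich source and six
# from a marine, highly-unsaturated-rich source -- each measured in
# duplicate with 0.1 ppm mass error and ~10% unassignable noise peaks, plus
# a serial-dilution growth-inhibition plate whose true IC50 follows the
# configured log-linear link on the aromatic formula fraction.

library(domchar)

cfg <- synth_config(n_samples = 12, n_formulas_per_sample = 600, seed = 2024)
truth <- generate_formula_library(cfg)
peaks <- render_peak_lists(truth)
plate <- generate_bioassay_plate(truth)

dir.create("results", showWarnings = FALSE)
write_synthetic_dataset(truth, peaks, plate, "results/data")

message(sprintf("library: %d sample-formula records, %d distinct formulas",
                nrow(truth$library), length(unique(truth$library$formula))))
message(sprintf("peaks rendered: %d across %d replicate spectra",
                nrow(peaks), length(unique(paste(peaks$sample_id,
                                                 peaks$replicate_id)))))
message(sprintf("true IC50 range: %.1f-%.1f ug/mL",
                min(truth$samples$ic50_true), max(truth$samples$ic50_true)))
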