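# Shared fixtures: small synthetic configurations and hand-built tables.

cho_only_bounds <- function() {
  list(lo = c(c = 1L, h = 0L, n = 0L, o = 0L, s = 0L, p = 0L),
       hi = c(c = 100L, h = 200L, n = 0L, o = 80L, s = 0L, p = 0L))
}

cho_only_weights <- function() {
  w <- c(A_Or = 0.08, A_Op = 0.25, HUn_Or = 0.15, HUn_Op = 0.30,
         Un_Or = 0.04, Un_Op = 0.12, Un_withN = 0, Sat_Or = 0.03,
         Sat_Op = 0.03)
  list(g1 = w, g2 = w)
}

# zero-noise CHO-only configuration for exact round-trip checks
zero_noise_cho_config <- function(n_samples = 2, n_formulas = 300, seed = 7) {
  synth_config(n_samples = n_samples, n_formulas_per_sample = n_formulas,
               category_weights = cho_only_weights(),
               element_bounds = cho_only_bounds(),
               ppm_error_sd = 0, noise_peak_fraction = 0,
               replicate_sd_log = 0, seed = seed)
}

# assigned table built directly from formula strings and an intensity matrix
make_table <- function(formulas, mat) {
  rownames(mat) <- formulas
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  fdf <- parse_formula(formulas)
  structure(list(intensity = mat, formulas = fdf,
                 annotation = data.frame(formula = formulas,
                                         neutral_mass = formula_mass(fdf),
                                         ppm_error = 0,
                                         series_support = NA_integer_),
                 provenance = list(source = "test")),
            class = "assigned_table")
}

# random CHNOSP formulas with integer-DBE parity, for oracle sweeps
random_formulas <- function(n, seed = 1) {
  set.seed(seed)
  f <- data.frame(c = sample(1:60, n, replace = TRUE),
                  h = sample(0:120, n, replace = TRUE),
                  n = sample(0:4, n, replace = TRUE),
                  o = sample(0:40, n, replace = TRUE),
                  s = sample(0:2, n, replace = TRUE),
                  p = sample(0:1, n, replace = TRUE))
  parity <- (f$h + f$n + f$p) %% 2L
  f$h <- f$h + parity
  f
}
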