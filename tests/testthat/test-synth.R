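test_that("library generation is deterministic and respects its weights", {
  cfg <- synth_config(n_samples = 2, n_formulas_per_sample = 400, seed = 21)
  t1 <- generate_formula_library(cfg)
  t2 <- generate_formula_library(cfg)
  expect_identical(t1$library, t2$library)
  expect_identical(t1$samples, t2$samples)

  # per-sample category composition matches the group's weights
  for (sid in unique(t1$library$sample_id)) {
    lib <- t1$library[t1$library$sample_id == sid, ]
    grp <- lib$group[1]
    emp <- table(factor(lib$category, levels = category_levels())) / nrow(lib)
    expect_equal(as.numeric(emp),
                 as.numeric(cfg$category_weights[[grp]]),
                 tolerance = 0.02)
    # relative intensities sum to one
    expect_equal(sum(lib$rel_intensity), 1)
    # all formulas unique within a sample and inside bounds/mass window
    expect_false(anyDuplicated(lib$formula) > 0)
    m <- formula_mass(lib[, c("c", "h", "n", "o", "s", "p")])
    expect_true(all(m >= 100 & m <= 1000))
  }
})

test_that("category composition converges to the weights at large n", {
  w <- c(A_Or = 0, A_Op = 0.5, HUn_Or = 0, HUn_Op = 0.5, Un_Or = 0,
         Un_Op = 0, Un_withN = 0, Sat_Or = 0, Sat_Op = 0)
  cfg <- synth_config(n_samples = 1, n_formulas_per_sample = 5000,
                      groups = "g", category_weights = list(g = w),
                      seed = 22)
  truth <- generate_formula_library(cfg)
  emp <- table(factor(truth$library$category, levels = category_levels())) /
    nrow(truth$library)
  expect_equal(as.numeric(emp), as.numeric(w), tolerance = 0.01)
  # the classifier agrees with every stored label
  cls <- classify_formula(truth$library[, c("c", "h", "n", "o", "s", "p")])
  expect_identical(as.character(cls), truth$library$category)
})

test_that("all-saturated CHO weights force DBE zero everywhere", {
  w <- c(A_Or = 0, A_Op = 0, HUn_Or = 0, HUn_Op = 0, Un_Or = 0, Un_Op = 0,
         Un_withN = 0, Sat_Or = 0.5, Sat_Op = 0.5)
  cfg <- synth_config(n_samples = 1, n_formulas_per_sample = 150,
                      groups = "g", category_weights = list(g = w),
                      element_bounds = cho_only_bounds(), seed = 23)
  truth <- generate_formula_library(cfg)
  expect_true(all(dbe(truth$library[, c("c", "h", "n", "o", "s", "p")]) == 0))
})

test_that("infeasible weight/bounds combinations raise an explicit error", {
  w <- c(A_Or = 0, A_Op = 0, HUn_Or = 0, HUn_Op = 0, Un_Or = 0, Un_Op = 0,
         Un_withN = 1, Sat_Or = 0, Sat_Op = 0)
  cfg <- synth_config(n_samples = 1, n_formulas_per_sample = 10,
                      groups = "g", category_weights = list(g = w),
                      element_bounds = cho_only_bounds(), seed = 24)
  expect_error(generate_formula_library(cfg, max_attempts = 50L),
               "infeasible")
})

test_that("zero-noise rendering reproduces theoretical ion m/z exactly", {
  cfg <- zero_noise_cho_config(n_samples = 1, n_formulas = 100, seed = 25)
  truth <- generate_formula_library(cfg)
  pk <- render_peak_lists(truth)
  theo <- sort(ion_mz(truth$library[, c("c", "h", "n", "o", "s", "p")]))
  for (r in unique(pk$replicate_id))
    expect_equal(pk$mz[pk$replicate_id == r], theo)
})

test_that("rendered peak counts follow the noise bookkeeping", {
  cfg <- synth_config(n_samples = 1, n_formulas_per_sample = 1000,
                      noise_peak_fraction = 0.2, seed = 26)
  truth <- generate_formula_library(cfg)
  pk <- render_peak_lists(truth)
  counts <- table(pk$replicate_id)
  expect_true(all(counts == 1250))
  # noise peaks sit below the signal intensities by construction
  expect_identical(nrow(pk), 2L * 1250L)
})

test_that("rendering is deterministic and 13C satellites obey the model", {
  cfg <- synth_config(n_samples = 1, n_formulas_per_sample = 50,
                      noise_peak_fraction = 0, ppm_error_sd = 0,
                      replicate_sd_log = 0, replicate_count = 1,
                      isotope_satellites = TRUE, seed = 27)
  truth <- generate_formula_library(cfg)
  pk1 <- render_peak_lists(truth)
  pk2 <- render_peak_lists(truth)
  expect_identical(pk1, pk2)
  expect_identical(nrow(pk1), 100L)
  lib <- truth$library
  mz <- ion_mz(lib)
  i <- which.max(lib$c)
  sat <- pk1[abs(pk1$mz - (mz[i] + 1.0033548)) < 1e-9, ]
  parent <- pk1[abs(pk1$mz - mz[i]) < 1e-9, ]
  expect_identical(nrow(sat), 1L)
  expect_equal(sat$intensity, 0.0107 * lib$c[i] * parent$intensity)
})

test_that("bioassay plates hit the logistic midpoint without noise", {
  # flat link so the true IC50 (50 ug/mL) lies on the dilution grid
  cfg <- synth_config(n_samples = 2, n_formulas_per_sample = 60,
                      link_coefficient = 0, link_intercept = log10(50),
                      assay_noise_sd = 0, seed = 28)
  truth <- generate_formula_library(cfg)
  expect_equal(truth$samples$ic50_true, c(50, 50))
  plate <- generate_bioassay_plate(truth)
  at_mid <- plate[plate$concentration_ug_ml == 50, ]
  expect_equal(at_mid$percent_inhibition, rep(50, nrow(at_mid)))
  ctrl <- plate[plate$concentration_ug_ml == 0, ]
  expect_equal(ctrl$percent_inhibition, rep(0, nrow(ctrl)))
})

test_that("a positive link makes the descriptor predict -log10(IC50)", {
  cfg <- synth_config(n_samples = 12, n_formulas_per_sample = 150, seed = 29)
  truth <- generate_formula_library(cfg)
  plate <- generate_bioassay_plate(truth)
  ic <- ic50_table(plate)
  y <- -log10(ic$ic50_mean[match(truth$samples$sample_id, ic$sample_id)])
  fit <- regress_bioactivity(truth$samples$aromatic_fraction, y)
  expect_gt(fit$r2, 0.5)
  expect_gt(fit$slope, 0)
})

test_that("the synthetic dataset round-trips through its TSV layout", {
  cfg <- synth_config(n_samples = 2, n_formulas_per_sample = 40, seed = 30)
  truth <- generate_formula_library(cfg)
  pk <- render_peak_lists(truth)
  plate <- generate_bioassay_plate(truth)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(truth, pk, plate, dir)
  back <- read_peak_lists(dir)
  expect_equal(back$mz, pk$mz)
  expect_equal(back$intensity, pk$intensity)
  expect_error(read_peak_lists(file.path(dir, "nope")), "metadata")
})
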