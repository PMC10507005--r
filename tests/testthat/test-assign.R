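test_that("MDL filter separates a noise floor from signal", {
  set.seed(31)
  pk <- data.frame(mz = seq_len(1250) + 100,
                   intensity = c(rep(100, 1000), runif(250, 0.9, 1.1)))
  res <- mdl_filter(pk, mdl_level = 4, noise_band = 0.25)
  expect_identical(nrow(res$peaks), 1000L)
  expect_true(all(res$peaks$intensity == 100))
  expect_gt(res$threshold, 1.1)
  expect_lt(res$threshold, 100)
})

test_that("MDL filter degenerate cases behave as defined", {
  pk <- data.frame(mz = 1:10 + 100, intensity = rep(5, 10))
  res <- mdl_filter(pk)              # zero robust SD: all retained
  expect_identical(nrow(res$peaks), 10L)
  expect_equal(res$threshold, 5)

  pk2 <- data.frame(mz = 1:100 + 100, intensity = seq(1, 100))
  res2 <- mdl_filter(pk2, mdl_level = 0, noise_band = 0.25)
  # threshold equals the noise-band median; peaks below it removed
  expect_equal(res2$threshold, stats::median(seq(1, 25)))
  expect_true(all(res2$peaks$intensity >= res2$threshold))
  expect_error(mdl_filter(pk2[0, ]), "empty")
})

test_that("recalibration recovers an injected systematic mass shift", {
  refs <- parse_formula(c("C10H12O5", "C15H18O7", "C20H24O9", "C25H30O11",
                          "C30H36O13", "C12H16O6"))
  mz <- ion_mz(refs)
  shifted <- data.frame(mz = mz * (1 + 1.0e-6), intensity = 1)
  res <- recalibrate(shifted, refs)
  expect_true(res$recalibrated)
  expect_equal(res$offset_ppm, 1.0, tolerance = 0.05)
  expect_equal(res$peaks$mz, mz, tolerance = 1e-9)

  # zero shift: identity within numerical noise
  res0 <- recalibrate(data.frame(mz = mz, intensity = 1), refs)
  expect_equal(res0$offset_ppm, 0, tolerance = 1e-6)
  expect_equal(res0$peaks$mz, mz)

  # half +1 ppm, half -1 ppm: median offset zero, spectrum unchanged
  sgn <- rep(c(1, -1), 3)
  mixed <- data.frame(mz = mz * (1 + sgn * 1e-6), intensity = 1)
  resm <- recalibrate(mixed, refs)
  expect_equal(resm$offset_ppm, 0, tolerance = 1e-9)
  expect_equal(resm$peaks$mz, mixed$mz)

  # too few matches: skipped with warning
  expect_warning(res_skip <- recalibrate(data.frame(mz = mz + 1, intensity = 1),
                                         refs),
                 "skipped")
  expect_false(res_skip$recalibrated)
})

test_that("alignment groups masses by single linkage at ppm tolerance", {
  mk <- function(mz, s, r) data.frame(mz = mz, intensity = 1, sample_id = s,
                                      replicate_id = r)
  # identical replicate lists: one group of two per mass
  two <- rbind(mk(c(200.1, 300.2, 400.3), "A", 1),
               mk(c(200.1, 300.2, 400.3), "A", 2))
  al <- align_peaks(two, 0.5)
  expect_identical(nrow(al$groups), 3L)
  expect_true(all(al$groups$n_peaks == 2))

  # 1.0 ppm apart at 400: two groups; 0.375 ppm apart: one group
  al2 <- align_peaks(rbind(mk(400.00000, "A", 1), mk(400.00040, "A", 2)), 0.5)
  expect_identical(nrow(al2$groups), 2L)
  al3 <- align_peaks(rbind(mk(400.00000, "A", 1), mk(400.00015, "A", 2)), 0.5)
  expect_identical(nrow(al3$groups), 1L)
  expect_equal(al3$groups$mz, mean(c(400.00000, 400.00015)), tolerance = 1e-9)

  # two peaks of one replicate in tolerance: nearest kept, other split off
  clash <- rbind(mk(c(400.00000, 400.00010), "A", 1), mk(400.00001, "A", 2))
  al4 <- align_peaks(clash, 0.5)
  expect_identical(nrow(al4$groups), 2L)
  big <- al4$groups[al4$groups$n_peaks == 2, ]
  expect_equal(big$mz, mean(c(400.00000, 400.00001)), tolerance = 1e-9)
})

test_that("candidate enumeration finds printed formulas", {
  cand <- enumerate_candidates(260.03209, 0.5)
  expect_true("C13H8O6" %in% format_formula(cand))
  # CH4 has H/C = 4, outside the default screen window; widen it
  cand2 <- enumerate_candidates(16.0313, 0.5, hc_max = 4.1)
  expect_identical(format_formula(cand2), "CH4")
  expect_equal(dbe(cand2), 0)
  cand3 <- enumerate_candidates(918.42491, 0.5, bounds = cho_only_bounds())
  expect_true("C47H66O18" %in% format_formula(cand3))
})

test_that("enumeration agrees with a naive full-grid brute force", {
  bounds <- list(lo = c(c = 1L, h = 0L, n = 0L, o = 0L, s = 0L, p = 0L),
                 hi = c(c = 25L, h = 50L, n = 3L, o = 20L, s = 2L, p = 1L))
  masses_el <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069, P = 30.97376151)
  grid <- expand.grid(c = 1:25, h = 0:50, n = 0:3, o = 0:20, s = 0:2, p = 0:1)
  gm <- as.matrix(grid) %*% masses_el[c("C", "H", "N", "O", "S", "P")]
  brute <- function(m, tol) {
    ppm <- (m - gm) / gm * 1e6
    hit <- grid[abs(ppm) <= tol, , drop = FALSE]
    hc <- hit$h / hit$c; oc <- hit$o / hit$c
    ok <- hc >= 0.3 & hc <= 2.5 & oc <= 1.2 &
      (hit$h + hit$n + hit$p) %% 2 == 0 &
      1 + hit$c - hit$h / 2 + (hit$n + hit$p) / 2 >= 0
    sort(format_formula(hit[ok, , drop = FALSE]))
  }
  set.seed(33)
  for (m in runif(50, 150, 420)) {
    got <- enumerate_candidates(m, 0.5, bounds = bounds)
    expect_identical(sort(format_formula(got)), brute(m, 0.5))
  }
})

test_that("shrinking the tolerance never adds candidates", {
  set.seed(34)
  for (m in runif(10, 200, 800)) {
    wide <- format_formula(enumerate_candidates(m, 0.5))
    narrow <- format_formula(enumerate_candidates(m, 0.2))
    expect_true(all(narrow %in% wide))
  }
})

test_that("the N,S,P rule removes implausible heteroatom combinations", {
  cand <- data.frame(idx = 1:4,
                     c = 20, h = 20, n = c(6L, 0L, 3L, 3L),
                     o = 5, s = c(0L, 0L, 2L, 2L), p = c(0L, 0L, 1L, 1L),
                     ppm = 0)
  cand$isotope_verified <- c(FALSE, FALSE, FALSE, TRUE)
  out <- apply_nsp_rule(cand)
  # n = 6 removed; CHO retained; n+s+p = 6 removed unless isotope-verified
  expect_identical(out$idx, c(2L, 4L))
})

test_that("isotope verification checks position and intensity band", {
  pk <- data.frame(mz = c(400, 401.0033548), intensity = c(1000, 0.0107 * 20 * 1000))
  expect_true(verify_isotope(20, 400, 1000, pk))
  expect_false(verify_isotope(20, 400, 1000, pk[1, , drop = FALSE]))
  pk5 <- pk; pk5$intensity[2] <- 5 * pk5$intensity[2]
  expect_false(verify_isotope(20, 400, 1000, pk5))
})

test_that("homologous ladders resolve to the true series", {
  ladder <- data.frame(c = 10:20, h = seq(12, 32, 2), n = 0L, o = 5L,
                       s = 0L, p = 0L)
  masses <- formula_mass(ladder)
  cand <- enumerate_candidates(masses, 0.5)
  res <- resolve_candidates(cand)
  expect_identical(nrow(res), nrow(ladder))
  expect_identical(format_formula(res[order(res$idx), ]),
                   format_formula(ladder))
  interior <- res$idx > 1 & res$idx < nrow(ladder)
  expect_true(all(res$series_support[interior] >= 1))
})

test_that("candidate ties break on ppm error, then heteroatoms", {
  cand <- data.frame(idx = c(1L, 1L), c = c(12L, 11L), h = c(10L, 10L),
                     n = c(0L, 0L), o = c(4L, 5L), s = c(0L, 0L),
                     p = c(0L, 0L), ppm = c(0.3, 0.1))
  res <- resolve_candidates(cand)
  expect_identical(res$c, 11L)  # smaller |ppm| wins at equal support
})

test_that("duplicate consensus drops single-replicate formulas", {
  f <- parse_formula(c("C10H12O5", "C15H18O7", "C20H24O9"))
  mz <- ion_mz(f)
  rep1 <- data.frame(mz = mz, intensity = c(10, 20, 30),
                     sample_id = "A", replicate_id = 1)
  rep2 <- data.frame(mz = mz[1:2], intensity = c(11, 19),
                     sample_id = "A", replicate_id = 2)
  tab <- assign_formulas(rbind(rep1, rep2), mdl_level = NULL)
  expect_setequal(rownames(tab$intensity), c("C10H12O5", "C15H18O7"))
  expect_equal(colSums(tab$intensity), c(A = 1))
})

test_that("zero-noise CHO-only data are recovered perfectly", {
  cfg <- zero_noise_cho_config(n_samples = 2, n_formulas = 200, seed = 36)
  truth <- generate_formula_library(cfg)
  pk <- render_peak_lists(truth)
  tab <- assign_formulas(pk, mdl_level = NULL, bounds = cho_only_bounds())
  ev <- evaluate_assignment(tab, truth)
  expect_identical(ev$recall, 1)
  expect_identical(ev$precision, 1)
  expect_equal(unname(colSums(tab$intensity)), rep(1, 2))
  # assigned table invariants: bounds and validity screens hold
  f <- tab$formulas
  expect_true(all(f$c >= 1 & f$c <= 100 & f$h <= 200))
  expect_true(all(f$h / f$c >= 0.3 & f$h / f$c <= 2.5))
  expect_true(all(f$o / f$c <= 1.2))
  expect_true(all(dbe(f) >= 0))
})
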