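test_that("percent inhibition is relative to the negative control", {
  expect_equal(percent_inhibition(120, 120), 0)
  expect_equal(percent_inhibition(0, 120), 100)
  expect_equal(percent_inhibition(30, 120), 75)
  expect_error(percent_inhibition(10, 0), "positive")
})

test_that("log-linear interpolation hits the textbook two-point case", {
  r <- ic50(c(10, 100), c(20, 80))
  expect_equal(r$ic50, 10^1.5, tolerance = 1e-9)
  expect_false(r$censored)
})

test_that("sub-50% series are censored at the top concentration", {
  conc <- 200 / 2^(0:9)
  r <- ic50(conc, rep(30, 10))
  expect_true(r$censored)
  expect_identical(r$label, ">200")
  expect_true(is.na(r$ic50))
})

test_that("IC50 is equivariant to concentration rescaling", {
  conc <- 200 / 2^(0:9)
  inh <- 100 / (1 + 40 / conc)
  base <- ic50(conc, inh)$ic50
  base_log <- ic50(conc, inh, method = "logistic")$ic50
  for (k in c(0.1, 3, 10)) {
    expect_equal(ic50(k * conc, inh)$ic50, k * base, tolerance = 1e-9)
    expect_equal(ic50(k * conc, inh, method = "logistic")$ic50, k * base_log,
                 tolerance = 1e-3)
  }
})

test_that("the logistic fit recovers noise-free midpoints within 0.5%", {
  conc <- 200 / 2^(0:9)
  for (mid in c(5, 25, 80)) {
    inh <- 100 / (1 + mid / conc)
    r <- ic50(conc, inh, method = "logistic")
    expect_equal(r$ic50, mid, tolerance = 0.005)
    # interpolation and logistic agree within 10% for Hill slope 1
    ri <- ic50(conc, inh)
    expect_equal(ri$ic50 / r$ic50, 1, tolerance = 0.1)
  }
})

test_that("replicate IC50s are averaged and censoring propagates", {
  conc <- 200 / 2^(0:5)
  mk <- function(s, r, inh) data.frame(sample_id = s, assay = "a",
                                       concentration_ug_ml = conc,
                                       replicate = r,
                                       percent_inhibition = inh)
  plate <- rbind(mk("A", 1, 100 / (1 + 20 / conc)),
                 mk("A", 2, 100 / (1 + 25 / conc)),
                 mk("B", 1, rep(10, 6)), mk("B", 2, rep(12, 6)))
  tab <- ic50_table(plate)
  a <- tab[tab$sample_id == "A", ]
  expect_false(is.na(a$ic50_mean))
  expect_identical(a$n_censored, 0L)
  expect_gt(a$ic50_sd, 0)
  b <- tab[tab$sample_id == "B", ]
  expect_identical(b$label, ">200")
  expect_identical(b$n_censored, 2L)
})

test_that("TEAC conversion follows the Trolox calibration line", {
  calib <- data.frame(trolox_umol = c(0, 30, 60, 90),
                      response = 0.5 * c(0, 30, 60, 90))
  r <- teac(30, calib, dw_mass = 0.5)
  expect_equal(r$teac, 120)
  expect_equal(r$r2, 1)
  expect_equal(teac(0, calib, 1)$teac, 0)   # activity at the intercept
  # linear in activity, inverse in mass
  expect_equal(teac(60, calib, 0.5)$teac, 2 * r$teac)
  expect_equal(teac(30, calib, 1)$teac, r$teac / 2)
  flat <- data.frame(trolox_umol = c(0, 30, 60), response = c(5, 5, 5))
  expect_error(teac(10, flat, 1), "slope")
  expect_error(teac(10, calib[1:2, ], 1), "3 points")
})

test_that("the descriptor regression matches closed-form least squares", {
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(12); y <- 2 * x + rnorm(12)
    fit <- regress_bioactivity(x, y)
    # normal equations by hand
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
    res <- y - intercept - slope * x
    expect_equal(fit$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
  exact <- regress_bioactivity(1:5, 2 * (1:5))
  expect_equal(exact$r2, 1)
  expect_identical(exact$stars, "**")
  expect_error(regress_bioactivity(rep(1, 5), rnorm(5)), "constant")
  expect_error(regress_bioactivity(1:2, 1:2), "3 paired")
})

test_that("significance stars follow the p-value bands", {
  set.seed(62)
  x <- rnorm(30)
  f_strong <- regress_bioactivity(x, x + rnorm(30, 0, 0.1))
  expect_identical(f_strong$stars, "**")
  f_null <- regress_bioactivity(x, rnorm(30))
  expect_identical(f_null$stars,
                   if (f_null$p < 0.01) "**" else if (f_null$p < 0.05) "*" else "")
})
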