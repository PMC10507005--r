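# Bioassay quantification: percent inhibition, IC50 by log-linear
# interpolation or four-parameter logistic fit, Trolox-equivalent
# antioxidant capacity, and descriptor-activity regressions.

#' Percent inhibition relative to a negative control
#'
#' @param signal Raw signal of the treated well(s).
#' @param negative_control Raw signal of the untreated control (> 0).
#' @return `100 * (1 - signal / negative_control)`.
#' @export
percent_inhibition <- function(signal, negative_control) {
  if (any(negative_control <= 0)) stop("negative control must be positive")
  100 * (1 - signal / negative_control)
}

#' IC50 of a dose-response series
#'
#' Interpolation method (default): when the maximal inhibition stays below
#' 50%, the result is censored at the top tested concentration (reported as
#' `">Cmax"`); otherwise the IC50 is the linear interpolation of inhibition
#' against log10(concentration) between the two points bracketing 50%. With
#' a non-monotone series the lowest crossing is used, with a warning.
#' The logistic method fits a four-parameter logistic curve (floor 0,
#' ceiling 100 as starting values, all parameters free) and reports its
#' midpoint.
#'
#' @param concentration Concentrations (> 0; zero-concentration control
#'   wells are dropped).
#' @param inhibition Percent inhibition, same length.
#' @param method `"interpolation"` or `"logistic"`.
#' @return List with `ic50` (numeric or NA when censored), `censored`
#'   (logical) and `label` (formatted value, or `">Cmax"`).
#' @export
ic50 <- function(concentration, inhibition,
                 method = c("interpolation", "logistic")) {
  method <- match.arg(method)
  keep <- concentration > 0
  conc <- concentration[keep]
  inh <- inhibition[keep]
  if (length(conc) < 2) stop("need at least two positive concentrations")
  ord <- order(conc)
  conc <- conc[ord]; inh <- inh[ord]
  # average duplicate wells at the same concentration
  if (anyDuplicated(conc)) {
    inh <- as.numeric(tapply(inh, conc, mean))
    conc <- sort(unique(conc))
  }
  cmax <- max(conc)
  if (max(inh) < 50)
    return(list(ic50 = NA_real_, censored = TRUE,
                label = paste0(">", format(cmax, trim = TRUE))))
  if (method == "interpolation") {
    cross <- which(inh >= 50)
    j <- cross[1]
    if (j == 1)
      return(list(ic50 = conc[1], censored = FALSE,
                  label = format(conc[1], trim = TRUE)))
    if (any(diff(inh) < 0) && length(cross) > 1 &&
        any(inh[seq_len(max(cross))] < 50 &
            seq_len(max(cross)) > min(cross)))
      warning("non-monotone dose-response; using lowest crossing")
    lx <- log10(conc)
    val <- 10^(lx[j - 1] + (50 - inh[j - 1]) / (inh[j] - inh[j - 1]) *
                 (lx[j] - lx[j - 1]))
    return(list(ic50 = val, censored = FALSE,
                label = format(val, trim = TRUE)))
  }
  # four-parameter logistic: y = d + (a - d) / (1 + (e / x)^b)
  start <- list(a = max(100, max(inh)), b = 1,
                d = min(0, min(inh)),
                e = conc[which.min(abs(inh - 50))])
  fit <- minpack.lm::nlsLM(inh ~ d + (a - d) / (1 + (e / conc)^b),
                           start = start,
                           lower = c(a = 50, b = 0.1, d = -20, e = min(conc) / 100),
                           upper = c(a = 150, b = 10, d = 45, e = max(conc) * 100),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  val <- stats::coef(fit)[["e"]]
  list(ic50 = val, censored = FALSE, label = format(val, trim = TRUE))
}

#' Replicate-wise IC50 summary of a bioassay table
#'
#' Fits each replicate's dilution series independently and reports mean and
#' standard deviation across replicates, formatted as `"m (+-s)"`. Samples
#' whose replicates are all censored are reported as `">Cmax"`.
#'
#' @param plate Data frame with columns `sample_id`, `assay`,
#'   `concentration_ug_ml`, `replicate`, `percent_inhibition`.
#' @param method Passed to [ic50()].
#' @return Data frame: sample_id, assay, ic50_mean, ic50_sd, n_replicates,
#'   n_censored, label.
#' @export
ic50_table <- function(plate, method = "interpolation") {
  key <- unique(plate[, c("sample_id", "assay")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- plate[plate$sample_id == key$sample_id[i] &
                 plate$assay == key$assay[i], ]
    fits <- lapply(split(sub, sub$replicate), function(rr)
      ic50(rr$concentration_ug_ml, rr$percent_inhibition, method = method))
    vals <- vapply(fits, function(f) f$ic50, numeric(1))
    cens <- vapply(fits, function(f) f$censored, logical(1))
    ok <- !cens
    if (!any(ok)) {
      lab <- fits[[1]]$label
      m <- NA_real_; s <- NA_real_
    } else {
      m <- mean(vals[ok])
      s <- if (sum(ok) > 1) stats::sd(vals[ok]) else NA_real_
      lab <- sprintf("%.1f (± %.1f)", m, if (is.na(s)) 0 else s)
    }
    data.frame(sample_id = key$sample_id[i], assay = key$assay[i],
               ic50_mean = m, ic50_sd = s,
               n_replicates = length(fits), n_censored = sum(cens),
               label = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trolox-equivalent antioxidant capacity
#'
#' Fits the Trolox calibration line (percent radical scavenging against
#' micromoles of Trolox), converts a sample's percent scavenging into Trolox
#' equivalents and normalizes by dry weight.
#'
#' @param activity Percent radical scavenging of the sample(s).
#' @param calibration Data frame with columns `trolox_umol` and `response`
#'   (percent scavenging); at least 3 points.
#' @param dw_mass Dry weight of the extract, g.
#' @return List with `teac` (micromol Trolox equivalents per g dry weight),
#'   `slope`, `intercept`, `r2` of the calibration.
#' @export
teac <- function(activity, calibration, dw_mass) {
  if (nrow(calibration) < 3)
    stop("calibration needs at least 3 points")
  fit <- stats::lm(response ~ trolox_umol, data = calibration)
  slope <- stats::coef(fit)[[2]]
  if (abs(slope) < 1e-12) stop("calibration slope is zero")
  ss_tot <- sum((calibration$response - mean(calibration$response))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  val <- (activity - stats::coef(fit)[[1]]) / slope / dw_mass
  list(teac = val, slope = slope, intercept = stats::coef(fit)[[1]], r2 = r2)
}

#' Linear regression of bioactivity on a molecular descriptor
#'
#' Ordinary least squares with the two-sided slope test; significance is
#' annotated as `**` (p < 0.01), `*` (p < 0.05) or empty. Censored
#' responses should be excluded (passed as NA) and are counted.
#'
#' @param descriptor Per-sample descriptor values.
#' @param response Per-sample bioactivity (NA for censored/missing).
#' @return Data frame row: slope, intercept, r2, p, stars, n, n_excluded.
#' @export
regress_bioactivity <- function(descriptor, response) {
  ok <- is.finite(descriptor) & is.finite(response)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  x <- descriptor[ok]; y <- response[ok]
  if (stats::var(x) < 1e-15 * max(1, mean(x)^2))
    stop("descriptor is constant; slope inference undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- sm$coefficients[2, 4]
  data.frame(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
             r2 = sm$r.squared, p = p,
             stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
             n = sum(ok), n_excluded = sum(!ok))
}
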