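# Formula attribution from replicate peak lists: detection-limit noise
# filtering, recalibration, ppm alignment, exhaustive CHNOSP enumeration with
# validity screens, heteroatom and isotope plausibility rules, homologous
# series resolution, duplicate consensus and per-sample normalization.

#' Default element bounds for formula enumeration
#'
#' C 1-100, H 0-200, N 0-4, O 0-80, S 0-2, P 0-1; wide enough for all
#' SPE-DOM formulas commonly reported below 1000 Da.
#'
#' @return List with integer vectors `lo` and `hi` named c, h, n, o, s, p.
#' @export
default_bounds <- function() {
  list(lo = c(c = 1L, h = 0L, n = 0L, o = 0L, s = 0L, p = 0L),
       hi = c(c = 100L, h = 200L, n = 4L, o = 80L, s = 2L, p = 1L))
}

#' Method-detection-limit noise filter
#'
#' Estimates the instrumental noise floor from the lowest-intensity quantile
#' band of the peak list and removes peaks below
#' `T = median(band) + mdl_level * madsd(band)`, where madsd is the
#' MAD-based robust standard deviation. The band fraction must undershoot
#' the spectrum's true noise proportion for the estimate to be uncontaminated
#' by faint analyte signal; the default of 5% is conservative in that sense.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param mdl_level Multiplier on the robust SD of the noise band.
#' @param noise_band Fraction of lowest-intensity peaks treated as the noise
#'   population.
#' @return List with `peaks` (filtered, original order kept) and `threshold`.
#' @export
mdl_filter <- function(peaks, mdl_level = 4, noise_band = 0.05) {
  if (nrow(peaks) == 0) stop("empty peak list")
  n_band <- max(2L, ceiling(noise_band * nrow(peaks)))
  band <- sort(peaks$intensity)[seq_len(n_band)]
  threshold <- stats::median(band) + mdl_level * stats::mad(band)
  keep <- peaks$intensity >= threshold
  if (!any(keep)) stop("MDL filter removed all peaks (threshold ", threshold, ")")
  list(peaks = peaks[keep, , drop = FALSE], threshold = threshold)
}

#' Recalibrate a spectrum against reference formulas
#'
#' Matches the theoretical deprotonated m/z of the reference formulas to the
#' nearest observed peak within `match_tol_ppm`, takes the median ppm offset
#' of the matches and divides all m/z by `1 + offset * 1e-6`. With fewer
#' than `min_matches` matches the spectrum is returned unchanged with a
#' warning and `recalibrated = FALSE`.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param reference_formulas Formula data frame of calibrants.
#' @param match_tol_ppm Pre-calibration match tolerance, ppm.
#' @param min_matches Minimum number of matched calibrants.
#' @return List with `peaks`, `offset_ppm`, `n_matched`, `recalibrated`.
#' @export
recalibrate <- function(peaks, reference_formulas, match_tol_ppm = 2,
                        min_matches = 5L) {
  theo <- sort(ion_mz(reference_formulas))
  obs <- peaks$mz
  # nearest observed peak per calibrant
  idx <- findInterval(theo, sort(obs))
  sorted_obs <- sort(obs)
  cand_lo <- pmax(idx, 1L)
  cand_hi <- pmin(idx + 1L, length(obs))
  d_lo <- abs(sorted_obs[cand_lo] - theo)
  d_hi <- abs(sorted_obs[cand_hi] - theo)
  nearest <- ifelse(d_lo <= d_hi, sorted_obs[cand_lo], sorted_obs[cand_hi])
  ppm <- (nearest - theo) / theo * 1e6
  ok <- abs(ppm) <= match_tol_ppm
  if (sum(ok) < min_matches) {
    warning("recalibration skipped: only ", sum(ok),
            " reference matches within ", match_tol_ppm, " ppm")
    return(list(peaks = peaks, offset_ppm = NA_real_, n_matched = sum(ok),
                recalibrated = FALSE))
  }
  offset <- stats::median(ppm[ok])
  peaks$mz <- peaks$mz / (1 + offset * 1e-6)
  list(peaks = peaks, offset_ppm = offset, n_matched = sum(ok),
       recalibrated = TRUE)
}

#' Align masses across replicates and samples
#'
#' Single-linkage grouping on the sorted pooled m/z values: consecutive
#' masses whose gap is within `tol_ppm` join the same group. Each group may
#' hold at most one peak per replicate; when a replicate contributes several,
#' the peak nearest the group's intensity-weighted mean m/z is kept and the
#' others are split off into singleton groups. The group m/z is the
#' intensity-weighted mean of its members.
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `sample_id`,
#'   `replicate_id`.
#' @param tol_ppm Alignment tolerance in ppm.
#' @return List with `peaks` (input plus a `group` column) and `groups`
#'   (data frame: group, mz, intensity, n_peaks).
#' @export
align_peaks <- function(peaks, tol_ppm = 0.5) {
  stopifnot(tol_ppm > 0)
  p <- peaks[order(peaks$mz), , drop = FALSE]
  n <- nrow(p)
  if (n == 0) stop("empty peak list")
  gap_ppm <- diff(p$mz) / p$mz[-n] * 1e6
  p$group <- cumsum(c(1L, as.integer(gap_ppm > tol_ppm)))

  # enforce one peak per replicate per group
  rep_key <- paste(p$sample_id, p$replicate_id, sep = "\r")
  repeat {
    wm <- tapply(p$mz * p$intensity, p$group, sum) /
      tapply(p$intensity, p$group, sum)
    p$grp_mz <- as.numeric(wm[as.character(p$group)])
    dup <- duplicated(cbind(p$group, rep_key)) |
      duplicated(cbind(p$group, rep_key), fromLast = TRUE)
    if (!any(dup)) break
    # within each (group, replicate) clash keep the nearest peak
    dist <- abs(p$mz - p$grp_mz)
    ord <- order(p$group, rep_key, dist)
    keepers <- !duplicated(paste(p$group, rep_key, sep = "\r")[ord])
    lose <- ord[!keepers]
    p$group[lose] <- max(p$group) + seq_along(lose)
  }
  wm <- tapply(p$mz * p$intensity, p$group, sum) /
    tapply(p$intensity, p$group, sum)
  groups <- data.frame(group = as.integer(names(wm)),
                       mz = as.numeric(wm),
                       intensity = as.numeric(tapply(p$intensity, p$group, mean)),
                       n_peaks = as.integer(table(p$group)))
  p$grp_mz <- NULL
  list(peaks = p, groups = groups[order(groups$mz), ])
}

#' Enumerate candidate formulas for neutral masses
#'
#' Exhaustive enumeration over N, S, P, O and C counts with the hydrogen
#' count solved from the mass remainder. Candidates must fall within
#' `tol_ppm` of the query mass and pass the validity screens: H within
#' bounds, `hc_min <= H/C <= hc_max`, `O/C <= oc_max`, and nonnegative
#' integer DBE (equivalent to the nitrogen rule for these elements). An
#' empty result is a valid outcome, not an error.
#'
#' @param masses Neutral monoisotopic masses, Da.
#' @param tol_ppm Mass tolerance, ppm.
#' @param bounds Element bounds, see [default_bounds()].
#' @param hc_min,hc_max Allowed H/C window.
#' @param oc_max Allowed O/C maximum.
#' @return Data frame with columns `idx` (index into `masses`), element
#'   counts `c`..`p`, and `ppm` (signed observed-minus-theoretical error).
#' @export
enumerate_candidates <- function(masses, tol_ppm = 0.5,
                                 bounds = default_bounds(),
                                 hc_min = 0.3, hc_max = 2.5, oc_max = 1.2) {
  stopifnot(tol_ppm > 0)
  el <- toupper(.ELEMENTS)
  enumerate_candidates_cpp(as.numeric(masses), tol_ppm,
                           .ELEMENT_MASS[el],
                           as.integer(bounds$lo[.ELEMENTS]),
                           as.integer(bounds$hi[.ELEMENTS]),
                           hc_min, hc_max, oc_max)
}

#' Heteroatom plausibility (N, S, P) rule
#'
#' Removes candidates exceeding the per-element heteroatom caps, or carrying
#' two or more heteroatom species with a combined count above `sum_max` --
#' unless the candidate is isotope-verified.
#'
#' @param candidates Data frame with element count columns; may carry a
#'   logical `isotope_verified` column (absent means not verified).
#' @param n_max,s_max,p_max Per-element caps.
#' @param sum_max Combined N+S+P cap applied when at least two heteroatom
#'   species are present.
#' @return The retained subset of `candidates`.
#' @export
apply_nsp_rule <- function(candidates, n_max = 4L, s_max = 2L, p_max = 1L,
                           sum_max = 5L) {
  iv <- if (!is.null(candidates$isotope_verified))
    candidates$isotope_verified else rep(FALSE, nrow(candidates))
  species <- (candidates$n > 0) + (candidates$s > 0) + (candidates$p > 0)
  bad <- candidates$n > n_max | candidates$s > s_max | candidates$p > p_max |
    (species >= 2 & candidates$n + candidates$s + candidates$p > sum_max)
  candidates[!bad | iv, , drop = FALSE]
}

#' Verify a candidate by its 13C isotope satellite
#'
#' True when a peak exists at the parent m/z + 1.0033548 Da (within
#' `tol_ppm`) whose intensity lies within `band` times the predicted
#' satellite intensity `0.0107 * C * parent_intensity`.
#'
#' @param c_count Carbon count of the candidate.
#' @param parent_mz Parent ion m/z.
#' @param parent_intensity Parent peak intensity.
#' @param peaks Peak data frame searched for the satellite.
#' @param tol_ppm Satellite mass tolerance, ppm.
#' @param band Acceptable intensity range as multiples of the prediction.
#' @return Logical.
#' @export
verify_isotope <- function(c_count, parent_mz, parent_intensity, peaks,
                           tol_ppm = 1, band = c(0.5, 2)) {
  target <- parent_mz + .C13_DELTA
  tol_da <- target * tol_ppm * 1e-6
  hit <- abs(peaks$mz - target) <= tol_da
  if (!any(hit)) return(FALSE)
  pred <- .C13_ABUNDANCE * c_count * parent_intensity
  any(peaks$intensity[hit] >= band[1] * pred &
      peaks$intensity[hit] <= band[2] * pred)
}

# Integer key encoding one formula; bounds-safe for c<=150, h<=300, n<=6,
# o<=120, s<=4, p<=2. Negative counts give NA (invalid neighbor).
.formula_key <- function(m) {
  bad <- m[, 1] < 0 | m[, 2] < 0 | m[, 3] < 0 | m[, 4] < 0 | m[, 5] < 0 |
    m[, 6] < 0 | m[, 1] > 150 | m[, 2] > 300 | m[, 3] > 6 | m[, 4] > 120 |
    m[, 5] > 4 | m[, 6] > 2
  key <- ((((m[, 1] * 301 + m[, 2]) * 7 + m[, 3]) * 121 + m[, 4]) * 5 +
            m[, 5]) * 3 + m[, 6]
  key[bad] <- NA_real_
  key
}

# Homologous-series unit element increments (c, h, n, o, s, p): CH2, CO2,
# H2, H2O, O.
.SERIES_UNITS <- rbind(
  CH2 = c(1, 2, 0, 0, 0, 0),
  CO2 = c(1, 0, 0, 2, 0, 0),
  H2  = c(0, 2, 0, 0, 0, 0),
  H2O = c(0, 2, 0, 1, 0, 0),
  O   = c(0, 0, 0, 1, 0, 0)
)

# Count, for every candidate row, how many distinct reference groups hold a
# formula reachable by +-k units (k = 1..max_k) of any homologous series.
.series_support <- function(cand_mat, cand_group, ref_keys, ref_group,
                            max_k = 10L) {
  m <- nrow(cand_mat)
  hits <- vector("list", 2L * max_k * nrow(.SERIES_UNITS))
  hi <- 0L
  for (u in seq_len(nrow(.SERIES_UNITS))) {
    unit <- .SERIES_UNITS[u, ]
    for (k in seq_len(max_k)) {
      for (sgn in c(1, -1)) {
        nb <- sweep(cand_mat, 2, sgn * k * unit, "+")
        j <- match(.formula_key(nb), ref_keys)
        ok <- which(!is.na(j) & ref_group[j] != cand_group)
        if (length(ok)) {
          hi <- hi + 1L
          hits[[hi]] <- cbind(ok, ref_group[j[ok]])
        }
      }
    }
  }
  if (hi == 0L) return(integer(m))
  all_hits <- unique(do.call(rbind, hits[seq_len(hi)]))
  tab <- tabulate(all_hits[, 1], nbins = m)
  tab
}

# Pick the winning candidate index per group: max series support, then
# smallest |ppm|, then fewest heteroatoms, then lexicographic formula.
.pick_winners <- function(cand, support) {
  het <- cand$n + cand$s + cand$p
  ord <- order(cand$idx, -support, abs(cand$ppm), het,
               format_formula(cand))
  first <- !duplicated(cand$idx[ord])
  sort(ord[first])
}

#' Resolve candidate formulas by homologous-series support
#'
#' For each aligned mass group, counts how many other groups hold a
#' candidate reachable by 1-10 units of the CH2, CO2, H2, H2O or O
#' homologous series, and selects the candidate with maximal support (ties:
#' smallest |ppm error|, then fewest heteroatoms, then lexicographic formula
#' string). Support counting is then iterated against the winner set until
#' the winners stop changing, up to `max_pass` passes.
#'
#' @param candidates Data frame from [enumerate_candidates()] (columns
#'   `idx`, element counts, `ppm`), `idx` identifying the mass group.
#' @param max_k Maximum series multiple considered.
#' @param max_pass Iteration bound; non-convergence keeps the last pass with
#'   a warning.
#' @return Data frame with one row per resolved group: `idx`, element
#'   counts, `ppm`, `series_support`.
#' @export
resolve_candidates <- function(candidates, max_k = 10L, max_pass = 8L) {
  if (nrow(candidates) == 0)
    return(cbind(candidates, series_support = integer(0)))
  cand_mat <- as.matrix(candidates[, .ELEMENTS])
  keys <- .formula_key(cand_mat)

  # initial reference set: each group's smallest-|ppm| candidate; using all
  # candidates here would let mutually consistent near-degenerate "shadow"
  # ladders (e.g. P-for-S substitutions a few tenths of a mDa off) support
  # each other as strongly as the true series
  init <- .pick_winners(candidates, integer(nrow(candidates)))
  support <- .series_support(cand_mat, candidates$idx, keys[init],
                             candidates$idx[init], max_k)
  win <- .pick_winners(candidates, support)
  for (pass in seq_len(max_pass)) {
    support <- .series_support(cand_mat, candidates$idx,
                               keys[win], candidates$idx[win], max_k)
    new_win <- .pick_winners(candidates, support)
    if (identical(new_win, win)) break
    win <- new_win
    if (pass == max_pass)
      warning("series support did not converge within ", max_pass, " passes")
  }
  out <- candidates[win, , drop = FALSE]
  out$series_support <- support[win]
  rownames(out) <- NULL
  out
}

#' Assign molecular formulas to replicate peak lists
#'
#' Runs the full attribution chain: per-replicate MDL noise filtering and
#' optional recalibration, cross-replicate mass alignment, exhaustive
#' candidate enumeration on the neutral-mass scale, heteroatom rule with
#' isotope-verification escape, homologous-series resolution, duplicate
#' consensus (a formula counts for a sample only when every replicate of
#' that sample contributes a peak to it) and per-sample normalization of
#' intensities to sum 1.
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `sample_id`,
#'   `replicate_id`.
#' @param tol_ppm Alignment and enumeration tolerance, ppm.
#' @param mdl_level MDL multiplier; `NULL` skips noise filtering (use for
#'   noiseless data, where no noise population exists to estimate).
#' @param noise_band Noise band fraction for [mdl_filter()].
#' @param bounds Element bounds.
#' @param reference_formulas Optional calibrant formulas for [recalibrate()].
#' @param exclude_masses Optional numeric vector of contaminant neutral
#'   masses removed (within `tol_ppm`) after alignment.
#' @param isotope_check Attempt 13C satellite verification for candidates
#'   failing the heteroatom rule.
#' @param ... Passed to [enumerate_candidates()] (H/C and O/C screens).
#' @return An `assigned_table`: list with `intensity` (formula-by-sample
#'   matrix of relative intensities, columns summing to 1), `formulas`
#'   (element counts per row), `annotation` (formula, neutral mass, ppm
#'   error, series support) and `provenance`.
#' @export
assign_formulas <- function(peaks, tol_ppm = 0.5, mdl_level = 4,
                            noise_band = 0.05, bounds = default_bounds(),
                            reference_formulas = NULL,
                            exclude_masses = NULL,
                            isotope_check = TRUE, ...) {
  prov <- list(tol_ppm = tol_ppm, mdl_level = mdl_level,
               recalibration = list())
  pieces <- split(peaks, paste(peaks$sample_id, peaks$replicate_id, sep = "\r"))
  pieces <- lapply(pieces, function(pp) {
    if (!is.null(mdl_level)) pp <- mdl_filter(pp, mdl_level, noise_band)$peaks
    if (!is.null(reference_formulas)) {
      rc <- recalibrate(pp, reference_formulas)
      pp <- rc$peaks
    }
    pp
  })
  peaks <- do.call(rbind, pieces)

  al <- align_peaks(peaks, tol_ppm)
  groups <- al$groups
  if (!is.null(exclude_masses)) {
    neutral <- neutral_mass(groups$mz)
    bad <- vapply(neutral, function(m)
      any(abs(exclude_masses - m) / m * 1e6 <= tol_ppm), logical(1))
    groups <- groups[!bad, , drop = FALSE]
  }

  cand <- enumerate_candidates(neutral_mass(groups$mz), tol_ppm, bounds, ...)
  cand$idx <- groups$group[cand$idx]

  # heteroatom rule, with isotope-verification escape for violating candidates
  kept <- apply_nsp_rule(cand)
  if (isotope_check && nrow(kept) < nrow(cand)) {
    rej_rows <- setdiff(rownames(cand), rownames(kept))
    rej <- cand[rej_rows, , drop = FALSE]
    if (nrow(rej)) {
      gm <- groups$mz[match(rej$idx, groups$group)]
      gi <- groups$intensity[match(rej$idx, groups$group)]
      rej$isotope_verified <- vapply(seq_len(nrow(rej)), function(i)
        verify_isotope(rej$c[i], gm[i], gi[i], al$peaks,
                       tol_ppm = max(tol_ppm, 1)), logical(1))
      kept <- rbind(kept, rej[rej$isotope_verified,
                              setdiff(names(rej), "isotope_verified"),
                              drop = FALSE])
    }
  }
  resolved <- resolve_candidates(kept)

  # per-sample presence and intensity from the aligned peaks
  pk <- al$peaks
  pk <- pk[pk$group %in% resolved$idx, , drop = FALSE]
  fml <- format_formula(resolved)[match(pk$group, resolved$idx)]
  pk$formula <- fml

  reps_per_sample <- tapply(peaks$replicate_id, peaks$sample_id,
                            function(x) length(unique(x)))
  # replicate-level intensity per (sample, formula): sum over groups
  agg <- stats::aggregate(intensity ~ formula + sample_id + replicate_id,
                          data = pk, FUN = sum)
  nrep <- stats::aggregate(replicate_id ~ formula + sample_id,
                           data = agg, FUN = function(x) length(unique(x)))
  names(nrep)[3] <- "n_reps"
  mean_int <- stats::aggregate(intensity ~ formula + sample_id, data = agg,
                               FUN = mean)
  tab <- merge(mean_int, nrep, by = c("formula", "sample_id"))
  tab <- tab[tab$n_reps >= reps_per_sample[tab$sample_id], , drop = FALSE]
  if (nrow(tab) == 0) stop("no formula survived the duplicate-consensus rule")

  samples <- sort(unique(peaks$sample_id))
  formulas <- sort(unique(tab$formula))
  mat <- matrix(0, nrow = length(formulas), ncol = length(samples),
                dimnames = list(formulas, samples))
  mat[cbind(match(tab$formula, formulas), match(tab$sample_id, samples))] <-
    tab$intensity
  mat <- sweep(mat, 2, colSums(mat), "/")

  fdf <- parse_formula(formulas)
  res_f <- format_formula(resolved)
  j <- match(formulas, res_f)
  annotation <- data.frame(formula = formulas,
                           neutral_mass = formula_mass(fdf),
                           ppm_error = resolved$ppm[j],
                           series_support = resolved$series_support[j])
  structure(list(intensity = mat, formulas = fdf, annotation = annotation,
                 provenance = prov),
            class = "assigned_table")
}

#' Build an assigned table directly from a ground-truth library
#'
#' Bypasses the spectral stages, mapping the true library straight into the
#' formula-by-sample relative intensity matrix (columns normalized to 1).
#' Useful for validating the composition and ordination stages in isolation.
#'
#' @param truth A `ground_truth` from [generate_formula_library()].
#' @return An `assigned_table`.
#' @export
truth_as_assigned_table <- function(truth) {
  lib <- truth$library
  samples <- sort(unique(lib$sample_id))
  formulas <- sort(unique(lib$formula))
  mat <- matrix(0, length(formulas), length(samples),
                dimnames = list(formulas, samples))
  mat[cbind(match(lib$formula, formulas), match(lib$sample_id, samples))] <-
    lib$rel_intensity
  mat <- sweep(mat, 2, colSums(mat), "/")
  fdf <- parse_formula(formulas)
  structure(list(intensity = mat, formulas = fdf,
                 annotation = data.frame(formula = formulas,
                                         neutral_mass = formula_mass(fdf),
                                         ppm_error = 0,
                                         series_support = NA_integer_),
                 provenance = list(source = "ground_truth")),
            class = "assigned_table")
}

#' Compare an assigned table against a ground-truth library
#'
#' Recall is the fraction of true sample-formula occurrences recovered;
#' precision is the fraction of assigned occurrences that are true.
#'
#' @param table An `assigned_table`.
#' @param truth A `ground_truth`.
#' @return List with `recall`, `precision`, and per-sample data frame.
#' @export
evaluate_assignment <- function(table, truth) {
  lib <- truth$library
  per <- lapply(sort(unique(lib$sample_id)), function(sid) {
    true_set <- lib$formula[lib$sample_id == sid]
    got <- rownames(table$intensity)[table$intensity[, sid] > 0]
    tp <- length(intersect(true_set, got))
    data.frame(sample_id = sid, n_true = length(true_set),
               n_assigned = length(got), tp = tp)
  })
  per <- do.call(rbind, per)
  list(recall = sum(per$tp) / sum(per$n_true),
       precision = sum(per$tp) / sum(per$n_assigned),
       per_sample = per)
}
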