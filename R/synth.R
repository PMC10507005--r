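# Synthetic DOM dataset generator: formula libraries with source-dependent
# compound-class composition, rendered noisy replicate peak lists, and
# bioassay plates whose IC50 is linked to a molecular descriptor.

#' Default compound-category weights for synthetic source groups
#'
#' Two contrasting DOM sources: a terrestrial, aromatic-rich pool (peat-like,
#' high aromatic and highly unsaturated O-poor content) and a marine,
#' highly-unsaturated-rich pool (deep-water-like, dominated by highly
#' unsaturated O-poor formulas with almost no aromatics).
#'
#' @return Named list of numeric weight vectors over [category_levels()],
#'   each summing to 1.
#' @export
default_category_weights <- function() {
  lv <- category_levels()
  terrestrial <- c(A_Or = 0.10, A_Op = 0.30, HUn_Or = 0.15, HUn_Op = 0.30,
                   Un_Or = 0.02, Un_Op = 0.08, Un_withN = 0.03,
                   Sat_Or = 0.01, Sat_Op = 0.01)
  marine <- c(A_Or = 0.01, A_Op = 0.02, HUn_Or = 0.25, HUn_Op = 0.55,
              Un_Or = 0.05, Un_Op = 0.06, Un_withN = 0.04,
              Sat_Or = 0.01, Sat_Op = 0.01)
  list(terrestrial = terrestrial[lv], marine = marine[lv])
}

#' Configuration for the synthetic DOM generator
#'
#' @param n_samples Number of samples; split between the source groups in
#'   `category_weights` (first half first group, second half second group by
#'   default `groups = NULL`).
#' @param n_formulas_per_sample Formulas per sample library.
#' @param groups Optional character vector (length `n_samples`) of group
#'   names, matched against `names(category_weights)`.
#' @param category_weights Named list of per-group weights over the 9
#'   compound categories; each must sum to 1.
#' @param element_bounds Element bounds as returned by [default_bounds()].
#' @param mass_range_da Neutral mass window of the simulated acquisition, Da.
#' @param intensity_lognormal Meanlog and sdlog of true relative intensities.
#' @param replicate_sd_log Sdlog of multiplicative intensity noise between
#'   replicate measurements.
#' @param ppm_error_sd Gaussian mass error per rendered peak, ppm.
#' @param noise_peak_fraction Fraction of each rendered replicate peak list
#'   consisting of unassignable noise peaks.
#' @param noise_intensity_rel Center of the noise intensity floor, as a
#'   fraction of the 10th percentile of signal intensities.
#' @param noise_sd_log Sdlog of the noise intensity floor.
#' @param isotope_satellites Render 13C satellite peaks at +1.0033548 Da with
#'   intensity 0.0107 x C x parent intensity.
#' @param intensity_scale Arbitrary instrument-counts scale factor.
#' @param replicate_count Replicate measurements per sample.
#' @param shared_fraction Fraction of each sample's formulas drawn from its
#'   group-level pool (the rest are private to the sample).
#' @param link_coefficient Slope linking the aromatic formula fraction to
#'   -log10(IC50): `log10(IC50) = link_intercept - link_coefficient * arom`.
#' @param link_intercept Intercept of the link on the log10 microgram/mL
#'   scale.
#' @param assay_c_max Top concentration of the dilution series, microgram/mL.
#' @param assay_dilution Serial dilution factor.
#' @param assay_n_dilutions Number of concentrations in the series.
#' @param assay_replicates Duplicate wells per concentration.
#' @param assay_hill Hill slope of the simulated dose-response.
#' @param assay_noise_sd Gaussian noise on percent inhibition.
#' @param seed Integer seed; all generation is deterministic given the seed.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_samples = 12,
                         n_formulas_per_sample = 500,
                         groups = NULL,
                         category_weights = default_category_weights(),
                         element_bounds = default_bounds(),
                         mass_range_da = c(100, 1000),
                         intensity_lognormal = c(meanlog = 0, sdlog = 1),
                         replicate_sd_log = 0.1,
                         ppm_error_sd = 0.1,
                         noise_peak_fraction = 0.1,
                         noise_intensity_rel = 0.2,
                         noise_sd_log = 0.15,
                         isotope_satellites = FALSE,
                         intensity_scale = 1e8,
                         replicate_count = 2,
                         shared_fraction = 0.7,
                         link_coefficient = 4,
                         link_intercept = log10(150),
                         assay_c_max = 200,
                         assay_dilution = 2,
                         assay_n_dilutions = 10,
                         assay_replicates = 2,
                         assay_hill = 1,
                         assay_noise_sd = 3,
                         seed = 1L) {
  if (is.null(groups)) {
    gnames <- names(category_weights)
    groups <- gnames[ceiling(seq_len(n_samples) / (n_samples / length(gnames)))]
  }
  stopifnot(length(groups) == n_samples,
            all(groups %in% names(category_weights)),
            replicate_count >= 1,
            mass_range_da[1] > 0, mass_range_da[2] > mass_range_da[1],
            noise_peak_fraction >= 0, noise_peak_fraction < 1,
            shared_fraction >= 0, shared_fraction <= 1)
  for (g in names(category_weights)) {
    w <- category_weights[[g]]
    if (!setequal(names(w), category_levels()))
      stop("category weights for group '", g, "' must be named by category")
    if (abs(sum(w) - 1) > 1e-9)
      stop("category weights for group '", g, "' must sum to 1")
    category_weights[[g]] <- w[category_levels()]
  }
  cfg <- list(n_samples = n_samples,
              n_formulas_per_sample = n_formulas_per_sample,
              groups = groups,
              category_weights = category_weights,
              element_bounds = element_bounds,
              mass_range_da = mass_range_da,
              intensity_lognormal = intensity_lognormal,
              replicate_sd_log = replicate_sd_log,
              ppm_error_sd = ppm_error_sd,
              noise_peak_fraction = noise_peak_fraction,
              noise_intensity_rel = noise_intensity_rel,
              noise_sd_log = noise_sd_log,
              isotope_satellites = isotope_satellites,
              intensity_scale = intensity_scale,
              replicate_count = replicate_count,
              shared_fraction = shared_fraction,
              link_coefficient = link_coefficient,
              link_intercept = link_intercept,
              assay_c_max = assay_c_max,
              assay_dilution = assay_dilution,
              assay_n_dilutions = assay_n_dilutions,
              assay_replicates = assay_replicates,
              assay_hill = assay_hill,
              assay_noise_sd = assay_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# Largest-remainder apportionment of n formulas over category weights.
.apportion <- function(weights, n) {
  raw <- weights * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  base
}

# Uniform integer draw on [a, b] that is safe when a == b (unlike
# sample(seq(a, b), 1), which falls into sample's 1:n interpretation).
.rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# Heteroatom count proposal, CHO-biased as in natural DOM spectra.
.draw_hetero <- function(hi) {
  n <- sample.int(min(hi[["n"]], 3) + 1L, 1L,
                  prob = c(0.72, 0.18, 0.07, 0.03)[seq_len(min(hi[["n"]], 3) + 1L)]) - 1L
  s <- sample.int(min(hi[["s"]], 2) + 1L, 1L,
                  prob = c(0.85, 0.12, 0.03)[seq_len(min(hi[["s"]], 2) + 1L)]) - 1L
  p <- sample.int(min(hi[["p"]], 1) + 1L, 1L,
                  prob = c(0.92, 0.08)[seq_len(min(hi[["p"]], 1) + 1L)]) - 1L
  c(n = n, s = s, p = p)
}

# Propose one formula aimed at `target` category; may still misclassify
# (caller rejects until the classifier agrees).
.propose_formula <- function(target, bounds, mass_range) {
  lo <- bounds$lo; hi <- bounds$hi
  het <- .draw_hetero(hi)
  n <- het[["n"]]; s <- het[["s"]]; p <- het[["p"]]
  o_rich <- grepl("_Or$", target)
  c_hi <- min(hi[["c"]], floor(mass_range[2] / 13))
  if (startsWith(target, "Sat")) {
    # keep H/C <= 2.5 so the library stays inside the assignable space
    c_lo <- max(5L, 4L + 2L * (n + p))
    if (c_lo > min(c_hi, 45L)) return(NULL)
    cc <- .rint(c_lo, min(c_hi, 45L))
    h <- 2L + 2L * cc + n + p
    if (h > hi[["h"]]) return(NULL)
  } else {
    hc_win <- switch(substr(target, 1, 2),
                     "A_" = c(0.30, 1.20),
                     "HU" = c(0.60, 1.49),
                     "Un" = c(1.50, 2.00))
    if (startsWith(target, "Un")) {
      if (target == "Un_withN") {
        if (hi[["n"]] < 1) return(NULL)
        n <- sample(seq_len(min(hi[["n"]], 3)), 1L,
                    prob = c(0.7, 0.2, 0.1)[seq_len(min(hi[["n"]], 3))])
      } else n <- 0L
    }
    cc <- .rint(max(lo[["c"]], 5L), min(c_hi, 60L))
    h <- round(cc * stats::runif(1, hc_win[1], hc_win[2]))
    if ((h + n + p) %% 2 != 0) h <- h + sample(c(-1L, 1L), 1L)
    if (h < lo[["h"]] || h > hi[["h"]] || h < 0) return(NULL)
  }
  if (o_rich) {
    o_lo <- floor(0.5 * cc) + 1L
    o_hi <- min(hi[["o"]], floor(1.2 * cc))
  } else {
    o_lo <- max(lo[["o"]], 1L)
    o_hi <- max(o_lo, floor(0.5 * cc))
  }
  if (o_lo > o_hi) return(NULL)
  o <- .rint(as.integer(o_lo), as.integer(o_hi))
  # final screens mirroring the assignment validity windows, so that every
  # ground-truth formula is recoverable in principle
  if (h / cc < 0.3 || h / cc > 2.5 || o / cc > 1.2) return(NULL)
  f <- data.frame(c = cc, h = h, n = n, o = o, s = s, p = p)
  m <- formula_mass(f)
  if (m < mass_range[1] || m > mass_range[2]) return(NULL)
  f
}

# Generate `n` unique formulas of one category as CH2-homologous ladders:
# each accepted seed is extended by +CH2 steps while the extension stays in
# category, in bounds and in the mass window. DOM spectra are dense in such
# series, and the attribution stage exploits exactly that structure.
.gen_category_formulas <- function(target, n, bounds, mass_range, seen,
                                   max_attempts = 5000L) {
  rows <- vector("list", n)
  k <- 0L
  while (k < n) {
    f <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- .propose_formula(target, bounds, mass_range)
      if (is.null(cand)) next
      if (as.character(classify_formula(cand)) != target) next
      if (!is.null(seen[[format_formula(cand)]])) next
      f <- cand
      break
    }
    if (is.null(f))
      stop("infeasible category weights: could not generate a '", target,
           "' formula within bounds after ", max_attempts, " attempts")
    len <- min(1L + stats::rgeom(1, 0.3), 8L)
    for (j in seq_len(len) - 1L) {
      fj <- f
      fj$c <- fj$c + j
      fj$h <- fj$h + 2L * j
      if (fj$c > bounds$hi[["c"]] || fj$h > bounds$hi[["h"]]) break
      if (fj$h / fj$c > 2.5) break
      m <- formula_mass(fj)
      if (m > mass_range[2]) break
      if (as.character(classify_formula(fj)) != target) break
      key <- format_formula(fj)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      rows[[k]] <- cbind(fj, formula = key, category = target)
      if (k == n) break
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Generate a ground-truth DOM formula library
#'
#' Per source group, a category-stratified formula pool is generated with
#' CH2-homologous ladder structure (category target counts follow the
#' group's weights by largest-remainder apportionment, so the empirical
#' composition matches the weights to within 1/n). Each sample draws
#' `shared_fraction` of its formulas per category from its group pool and
#' generates the rest privately, giving within-group compositional overlap
#' as in real multi-sample datasets. True relative intensities are
#' lognormal, normalized to sum 1 per sample. True IC50 values follow the
#' configured log-linear link on the aromatic formula fraction.
#'
#' @param config A [synth_config()].
#' @param max_attempts Rejection attempts per formula before declaring the
#'   weight/bounds combination infeasible.
#' @return A `ground_truth` list with elements `config`, `library` (one row
#'   per sample-formula: sample_id, group, element counts, formula string,
#'   rel_intensity, category) and `samples` (per-sample descriptor and true
#'   IC50 table).
#' @export
generate_formula_library <- function(config, max_attempts = 5000L) {
  set.seed(config$seed)
  lv <- category_levels()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pools <- list()
  for (grp in unique(config$groups)) {
    counts <- .apportion(config$category_weights[[grp]],
                         config$n_formulas_per_sample)
    pools[[grp]] <- lapply(seq_along(lv), function(cat_i) {
      if (counts[cat_i] == 0L) return(NULL)
      .gen_category_formulas(lv[cat_i], counts[cat_i], config$element_bounds,
                             config$mass_range_da, seen, max_attempts)
    })
  }
  libs <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    grp <- config$groups[i]
    counts <- .apportion(config$category_weights[[grp]],
                         config$n_formulas_per_sample)
    sample_seen <- new.env(hash = TRUE, parent = emptyenv())
    parts <- vector("list", length(lv))
    for (cat_i in seq_along(lv)) {
      if (counts[cat_i] == 0L) next
      pool <- pools[[grp]][[cat_i]]
      n_shared <- round(config$shared_fraction * counts[cat_i])
      take <- if (n_shared > 0)
        pool[sort(sample.int(nrow(pool), n_shared)), , drop = FALSE]
      else pool[0, , drop = FALSE]
      for (key in take$formula) sample_seen[[key]] <- TRUE
      n_fresh <- counts[cat_i] - n_shared
      if (n_fresh > 0) {
        # private formulas must not duplicate the pool either
        for (key in pool$formula) sample_seen[[key]] <- TRUE
        fresh <- .gen_category_formulas(lv[cat_i], n_fresh,
                                        config$element_bounds,
                                        config$mass_range_da, sample_seen,
                                        max_attempts)
        take <- rbind(take, fresh)
      }
      parts[[cat_i]] <- take
    }
    lib <- do.call(rbind, parts)
    ri <- stats::rlnorm(nrow(lib),
                        config$intensity_lognormal[[1]],
                        config$intensity_lognormal[[2]])
    lib$rel_intensity <- ri / sum(ri)
    lib$sample_id <- sprintf("S%02d", i)
    lib$group <- grp
    libs[[i]] <- lib
  }
  library_df <- do.call(rbind, libs)
  arom <- vapply(libs, function(l) mean(l$category %in% c("A_Or", "A_Op")),
                 numeric(1))
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(config$n_samples)),
    group = config$groups,
    aromatic_fraction = arom,
    ic50_true = 10^(config$link_intercept - config$link_coefficient * arom)
  )
  structure(list(config = config, library = library_df, samples = samples),
            class = "ground_truth")
}

#' Render replicate peak lists from a ground-truth library
#'
#' Each replicate observes the singly deprotonated ion m/z of every library
#' formula perturbed by Gaussian ppm error, with multiplicative lognormal
#' intensity noise, plus unassignable noise peaks at uniform m/z drawn from a
#' tight low-intensity floor beneath the faintest signals. Optional 13C
#' satellites are appended last.
#'
#' @param truth A `ground_truth` from [generate_formula_library()].
#' @param config The same [synth_config()].
#' @return Data frame with columns `mz`, `intensity`, `sample_id`,
#'   `replicate_id`, sorted by replicate and m/z.
#' @export
render_peak_lists <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  out <- list()
  for (sid in unique(truth$library$sample_id)) {
    lib <- truth$library[truth$library$sample_id == sid, ]
    mz_theo <- ion_mz(lib)
    for (r in seq_len(config$replicate_count)) {
      err <- stats::rnorm(nrow(lib), 0, config$ppm_error_sd)
      mz <- mz_theo * (1 + err * 1e-6)
      intensity <- lib$rel_intensity * config$intensity_scale *
        exp(stats::rnorm(nrow(lib), 0, config$replicate_sd_log))
      sig <- data.frame(mz = mz, intensity = intensity)
      n_noise <- round(config$noise_peak_fraction /
                         (1 - config$noise_peak_fraction) * nrow(lib))
      if (n_noise > 0) {
        floor_level <- config$noise_intensity_rel *
          stats::quantile(intensity, 0.10, names = FALSE)
        noise <- data.frame(
          mz = stats::runif(n_noise,
                            config$mass_range_da[1] - .PROTON_MASS,
                            config$mass_range_da[2] - .PROTON_MASS),
          intensity = stats::rlnorm(n_noise, log(floor_level),
                                    config$noise_sd_log))
        sig <- rbind(sig, noise)
      }
      if (config$isotope_satellites) {
        sat <- data.frame(mz = mz + .C13_DELTA,
                          intensity = .C13_ABUNDANCE * lib$c * intensity)
        sig <- rbind(sig, sat)
      }
      sig <- sig[order(sig$mz), ]
      sig$sample_id <- sid
      sig$replicate_id <- r
      out[[length(out) + 1L]] <- sig
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate bioassay plates linked to the ground-truth IC50
#'
#' Per sample, a serial dilution series from the top test concentration with
#' percent inhibition drawn from a four-parameter logistic (floor 0, ceiling
#' 100, midpoint at the sample's true IC50) plus Gaussian well noise;
#' duplicate wells and negative-control wells (concentration 0, expected 0%
#' inhibition) are included.
#'
#' @param truth A `ground_truth`.
#' @param config The same [synth_config()].
#' @param assay Assay name recorded in the output.
#' @return Data frame with columns `sample_id`, `assay`,
#'   `concentration_ug_ml`, `replicate`, `percent_inhibition`.
#' @export
generate_bioassay_plate <- function(truth, config = truth$config,
                                    assay = "growth_inhibition") {
  set.seed(config$seed + 2L)
  conc <- config$assay_c_max / config$assay_dilution^(0:(config$assay_n_dilutions - 1))
  rows <- list()
  for (i in seq_len(nrow(truth$samples))) {
    ic50 <- truth$samples$ic50_true[i]
    for (r in seq_len(config$assay_replicates)) {
      inh <- 100 / (1 + (ic50 / conc)^config$assay_hill) +
        stats::rnorm(length(conc), 0, config$assay_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = truth$samples$sample_id[i], assay = assay,
        concentration_ug_ml = c(conc, 0),
        replicate = r,
        percent_inhibition = c(inh, stats::rnorm(1, 0, config$assay_noise_sd)))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a synthetic dataset to TSV files
#'
#' Writes one peak-list TSV per sample-replicate (`peaks_<sample>_<rep>.tsv`,
#' columns mz and intensity), a metadata TSV (sample_id, group, replicate,
#' file), a ground-truth TSV (sample_id, formula, rel_intensity, category)
#' and a bioassay TSV.
#'
#' @param truth A `ground_truth`.
#' @param peaks Rendered peak lists from [render_peak_lists()].
#' @param plate Bioassay table from [generate_bioassay_plate()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata data frame.
#' @export
write_synthetic_dataset <- function(truth, peaks, plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- unique(peaks[, c("sample_id", "replicate_id")])
  meta$group <- truth$samples$group[match(meta$sample_id,
                                          truth$samples$sample_id)]
  meta$file <- sprintf("peaks_%s_%d.tsv", meta$sample_id, meta$replicate_id)
  for (i in seq_len(nrow(meta))) {
    sub <- peaks[peaks$sample_id == meta$sample_id[i] &
                 peaks$replicate_id == meta$replicate_id[i],
                 c("mz", "intensity")]
    utils::write.table(sub, file.path(dir, meta$file[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(meta[, c("sample_id", "group", "replicate_id", "file")],
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(truth$library[, c("sample_id", "formula",
                                       "rel_intensity", "category")],
                     file.path(dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(plate, file.path(dir, "bioassay.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(meta)
}

#' Read peak lists written by [write_synthetic_dataset()]
#'
#' @param dir Directory holding `metadata.tsv` and the per-replicate TSVs.
#' @return Combined peak data frame (mz, intensity, sample_id, replicate_id).
#' @export
read_peak_lists <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- utils::read.delim(meta_path)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    p <- utils::read.delim(file.path(dir, meta$file[i]))
    p$sample_id <- meta$sample_id[i]
    p$replicate_id <- meta$replicate_id[i]
    p
  })
  do.call(rbind, out)
}
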