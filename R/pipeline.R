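# End-to-end orchestration: synthetic generation (optional), formula
# assignment, composition summaries, ordination with descriptor fitting,
# bioactivity quantification, TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' Bundles every stage parameter with explicit seeds so a run is exactly
#' reproducible and the manifest can echo all settings.
#'
#' @param mode `"synthetic"` (generate inputs) or `"user-data"` (read peak
#'   lists and bioassay TSVs from `input_dir`).
#' @param input_dir Directory with `metadata.tsv`, per-replicate peak TSVs
#'   and `bioassay.tsv` (user-data mode).
#' @param output_dir Directory for all output tables and the manifest.
#' @param synth A [synth_config()] used in synthetic mode.
#' @param tol_ppm Alignment/enumeration tolerance, ppm.
#' @param mdl_level MDL noise filter multiplier (`NULL` to skip filtering).
#' @param noise_band MDL noise band fraction.
#' @param bounds Element bounds for enumeration.
#' @param n_perm Permutations for descriptor fitting.
#' @param alpha Significance level for descriptor fitting.
#' @param ic50_method `"interpolation"` or `"logistic"`.
#' @param seed Master seed for the stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "user-data"),
                            input_dir = NULL,
                            output_dir = tempfile("domchar_run_"),
                            synth = synth_config(),
                            tol_ppm = 0.5,
                            mdl_level = 4,
                            noise_band = 0.05,
                            bounds = default_bounds(),
                            n_perm = 10000,
                            alpha = 0.1,
                            ic50_method = "interpolation",
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "user-data" && is.null(input_dir))
    stop("user-data mode needs input_dir")
  structure(list(mode = mode, input_dir = input_dir, output_dir = output_dir,
                 synth = synth, tol_ppm = tol_ppm, mdl_level = mdl_level,
                 noise_band = noise_band, bounds = bounds, n_perm = n_perm,
                 alpha = alpha, ic50_method = ic50_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full characterization pipeline
#'
#' Synthetic mode generates a ground-truth library, renders replicate peak
#' lists and bioassay plates and writes them as TSVs; both modes then run
#' assignment, composition summaries, Bray-Curtis PCoA with descriptor
#' fitting, and IC50 quantification with descriptor-activity regressions.
#' All tables are written to `config$output_dir` together with a JSON
#' manifest echoing parameters, seeds and per-stage row counts. Identical
#' configurations yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`truth`, `table`,
#'   `summary`, `heteroatoms`, `ordination`, `envfit`, `ic50`,
#'   `regressions`, `manifest`).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "domchar",
                   version = as.character(utils::packageVersion("domchar")),
                   mode = config$mode,
                   seed = config$seed,
                   parameters = list(tol_ppm = config$tol_ppm,
                                     mdl_level = config$mdl_level,
                                     noise_band = config$noise_band,
                                     n_perm = config$n_perm,
                                     alpha = config$alpha,
                                     ic50_method = config$ic50_method),
                   counts = list())

  truth <- NULL
  if (config$mode == "synthetic") {
    message("[synth] generating library: ", config$synth$n_samples,
            " samples x ", config$synth$n_formulas_per_sample, " formulas")
    truth <- generate_formula_library(config$synth)
    peaks <- render_peak_lists(truth)
    plate <- generate_bioassay_plate(truth)
    data_dir <- file.path(out_dir, "input")
    write_synthetic_dataset(truth, peaks, plate, data_dir)
    manifest$counts$library_formulas <- nrow(truth$library)
    manifest$parameters$synth_seed <- config$synth$seed
  } else {
    data_dir <- config$input_dir
    peaks <- read_peak_lists(data_dir)
    plate_path <- file.path(data_dir, "bioassay.tsv")
    if (!file.exists(plate_path)) stop("bioassay file not found: ", plate_path)
    plate <- utils::read.delim(plate_path)
  }
  manifest$counts$peaks <- nrow(peaks)

  message("[assign] attributing formulas to ", nrow(peaks), " peaks")
  table <- assign_formulas(peaks, tol_ppm = config$tol_ppm,
                           mdl_level = config$mdl_level,
                           noise_band = config$noise_band,
                           bounds = config$bounds)
  manifest$counts$assigned_formulas <- nrow(table$intensity)
  int_out <- data.frame(formula = rownames(table$intensity),
                        table$intensity, check.names = FALSE)
  .write_tsv(int_out, out_dir, "assigned_table.tsv")
  .write_tsv(table$annotation, out_dir, "assigned_annotation.tsv")

  message("[compose] summarizing ", ncol(table$intensity), " samples")
  summary_tab <- summarize_table(table)
  .write_tsv(summary_tab, out_dir, "sample_summary.tsv")
  het <- summary_tab[, c("sample_id", grep("^ab_", names(summary_tab),
                                           value = TRUE))]
  .write_tsv(het, out_dir, "heteroatom_abundance.tsv")
  manifest$counts$samples <- nrow(summary_tab)

  message("[ordinate] Bray-Curtis PCoA with ", config$n_perm,
          " permutations per descriptor")
  d <- bray_curtis_matrix(table)
  ord <- pcoa(d)
  scores_out <- data.frame(sample_id = rownames(ord$scores), ord$scores,
                           check.names = FALSE)
  .write_tsv(scores_out, out_dir, "pcoa_scores.tsv")
  .write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                        eigenvalue = ord$eigenvalues), out_dir,
             "pcoa_eigenvalues.tsv")
  desc_cols <- c(category_levels(), "dbe_w", "aimod_w", "mw_w")
  descs <- summary_tab[match(rownames(ord$scores), summary_tab$sample_id),
                       desc_cols]
  ef <- envfit_all(ord, descs, n_perm = config$n_perm, alpha = config$alpha,
                   seed = config$seed)
  .write_tsv(ef, out_dir, "envfit.tsv")

  message("[bioactivity] IC50 (", config$ic50_method, ") and regressions")
  ic <- ic50_table(plate, method = config$ic50_method)
  .write_tsv(ic, out_dir, "ic50_table.tsv")
  manifest$counts$assays <- nrow(ic)

  # regress -log10(IC50) on selected descriptors and the first axis
  samp <- summary_tab$sample_id
  neg_log_ic50 <- -log10(ic$ic50_mean[match(samp, ic$sample_id)])
  aromatic_pct <- summary_tab$A_Or + summary_tab$A_Op
  reg_desc <- list(aromatic_pct = aromatic_pct,
                   dbe_w = summary_tab$dbe_w,
                   aimod_w = summary_tab$aimod_w,
                   pco1 = ord$scores[match(samp, rownames(ord$scores)), 1])
  regs <- do.call(rbind, lapply(names(reg_desc), function(nm) {
    r <- tryCatch(regress_bioactivity(reg_desc[[nm]], neg_log_ic50),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(descriptor = nm, r)
  }))
  if (!is.null(regs)) .write_tsv(regs, out_dir, "bioactivity_regressions.tsv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth, table = table, summary = summary_tab,
                 heteroatoms = het, ordination = ord, envfit = ef,
                 ic50 = ic, regressions = regs, manifest = manifest))
}
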