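# Per-sample compositional summaries: intensity-weighted descriptors,
# compound-category percentages on formula counts, heteroatom-group
# abundances on intensities, and exclusivity statistics.

#' Summarize one sample of an assigned table
#'
#' Weighted descriptors are intensity-weighted means
#' \eqn{X_w = \sum I_i X_i / \sum I_i}, invariant to intensity rescaling.
#' Category percentages are computed on formula counts; heteroatom-group
#' abundances on summed intensities. The two weighting bases differ on
#' purpose: class composition is conventionally reported per formula, while
#' heteroatom composition is reported as relative abundance.
#'
#' @param table An `assigned_table`.
#' @param sample_id Column to summarize.
#' @return One-row data frame: sample_id, n_formulas, mw_w, dbe_w, aimod_w,
#'   hc_w, oc_w, the 9 category percentages, and the 5 heteroatom-group
#'   abundances (prefixed `ab_`).
#' @export
summarize_sample <- function(table, sample_id) {
  if (!sample_id %in% colnames(table$intensity))
    stop("unknown sample: ", sample_id)
  w <- table$intensity[, sample_id]
  keep <- w > 0
  if (!any(keep)) stop("sample ", sample_id, " has no formulas")
  w <- w[keep] / sum(w[keep])
  f <- table$formulas[keep, , drop = FALSE]
  d <- formula_descriptors(f)
  cat_pct <- 100 * as.numeric(table(d$category)) / nrow(f)
  names(cat_pct) <- category_levels()
  ab <- 100 * vapply(split(w, d$group), sum, numeric(1))[
    levels(heteroatom_group(f))]
  ab[is.na(ab)] <- 0
  out <- data.frame(sample_id = sample_id,
                    n_formulas = nrow(f),
                    mw_w = sum(w * d$mass),
                    dbe_w = sum(w * d$dbe),
                    aimod_w = sum(w * d$aimod),
                    hc_w = sum(w * d$hc),
                    oc_w = sum(w * d$oc))
  out <- cbind(out, as.data.frame(as.list(cat_pct)),
               stats::setNames(as.data.frame(as.list(as.numeric(ab))),
                               paste0("ab_", names(ab))))
  rownames(out) <- NULL
  out
}

#' Exclusive formulas per sample
#'
#' A formula is exclusive to a sample when its intensity is nonzero there
#' and zero in every other sample. Percentages are relative to the total
#' number of distinct formulas in the dataset.
#'
#' @param table An `assigned_table` with at least two samples.
#' @return Data frame: sample_id, n_exclusive, pct_exclusive.
#' @export
exclusivity <- function(table) {
  mat <- table$intensity
  if (ncol(mat) < 2) stop("exclusivity needs at least two samples")
  pres <- mat > 0
  n_samples_per_formula <- rowSums(pres)
  excl <- pres & n_samples_per_formula == 1
  n_excl <- colSums(excl)
  data.frame(sample_id = colnames(mat),
             n_exclusive = as.integer(n_excl),
             pct_exclusive = 100 * n_excl / nrow(mat),
             row.names = NULL)
}

#' Sample-by-sample composition summary table
#'
#' One row per sample with formula counts, exclusivity, weighted
#' descriptors, category percentages and heteroatom-group abundances.
#'
#' @param table An `assigned_table`.
#' @return Data frame with one row per sample.
#' @export
summarize_table <- function(table) {
  rows <- do.call(rbind, lapply(colnames(table$intensity),
                                function(s) summarize_sample(table, s)))
  if (ncol(table$intensity) >= 2) {
    ex <- exclusivity(table)
    rows <- merge(ex, rows, by = "sample_id", sort = TRUE)
  }
  rows
}
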