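# Ordination of samples: Bray-Curtis dissimilarity, principal coordinate
# analysis, and permutation-based post-hoc fitting of molecular descriptors.

#' Bray-Curtis dissimilarity between two intensity vectors
#'
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix of an assigned table
#'
#' @param x An `assigned_table` or a formula-by-sample intensity matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  mat <- if (inherits(x, "assigned_table")) x$intensity else x
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(mat[, i], mat[, j])
  d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of \eqn{-d^2/2} followed by a symmetric
#' eigendecomposition; scores are eigenvectors scaled by the square root of
#' their (positive) eigenvalues. Negative eigenvalues are reported, not
#' corrected. For determinism each axis is oriented so its largest-magnitude
#' score is positive.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param eig_tol Relative tolerance below which eigenvalues count as zero.
#' @return A `pcoa_result` list: `scores` (samples x axes), `eigenvalues`
#'   (all, descending), `explained` (proportion of the positive-eigenvalue
#'   total per retained axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d, eig_tol = 1e-9) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lam <- e$values
  tol <- eig_tol * max(abs(lam))
  pos <- lam > tol
  scores <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), nrow = sum(pos))
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 eigenvalues = lam,
                 explained = lam[pos] / sum(lam[pos]),
                 negative_eigenvalues = lam[lam < -tol]),
            class = "pcoa_result")
}

#' Post-hoc descriptor fitting with a permutation test
#'
#' Least-squares regression of a per-sample descriptor on the first `axes`
#' ordination axes. The squared correlation r2 is tested by permuting the
#' descriptor across samples: \eqn{p = (1 + \#\{r^2_{perm} \ge r^2\}) /
#' (1 + n_{perm})}. The fitted direction is the normalized coefficient
#' vector. A constant descriptor returns a flagged null result.
#'
#' @param result A `pcoa_result`.
#' @param descriptor Numeric vector, one value per sample (score row).
#' @param n_perm Number of permutations.
#' @param alpha Significance level for the `significant` flag.
#' @param axes Number of leading axes fitted.
#' @param seed Optional integer seed for the permutations.
#' @return Data frame row: direction cosines (`d1`, `d2`, ...), `r2`, `p`,
#'   `significant`.
#' @export
envfit_pcoa <- function(result, descriptor, n_perm = 10000, alpha = 0.1,
                        axes = 2, seed = NULL) {
  stopifnot(n_perm >= 1)
  x <- result$scores[, seq_len(min(axes, ncol(result$scores))), drop = FALSE]
  n <- nrow(x)
  stopifnot(length(descriptor) == n, all(is.finite(descriptor)))
  dn <- paste0("d", seq_len(ncol(x)))
  yc <- descriptor - mean(descriptor)
  ss_tot <- sum(yc^2)
  if (ss_tot < 1e-12 * max(1, mean(descriptor)^2)) {
    out <- stats::setNames(as.data.frame(as.list(rep(NA_real_, ncol(x)))), dn)
    return(cbind(out, r2 = NA_real_, p = NA_real_, significant = FALSE))
  }
  xc <- sweep(x, 2, colMeans(x))
  qr_x <- qr(xc)
  q <- qr.Q(qr_x)
  r2 <- sum(crossprod(q, yc)^2) / ss_tot
  beta <- qr.coef(qr_x, yc)
  beta[is.na(beta)] <- 0
  dir <- beta / sqrt(sum(beta^2))

  if (!is.null(seed)) set.seed(seed)
  perm_idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  yp <- matrix(yc[perm_idx], nrow = n)
  r2_perm <- colSums(crossprod(q, yp)^2) / ss_tot
  p <- (1 + sum(r2_perm >= r2)) / (1 + n_perm)
  out <- stats::setNames(as.data.frame(as.list(dir)), dn)
  cbind(out, r2 = r2, p = p, significant = p < alpha)
}

#' Fit several descriptors to an ordination
#'
#' @param result A `pcoa_result`.
#' @param descriptors Data frame of per-sample descriptor columns, rows
#'   matching the score rows.
#' @param ... Passed to [envfit_pcoa()]. A `seed` here applies to the first
#'   descriptor; subsequent fits continue the RNG stream, so the full table
#'   is reproducible for a fixed seed.
#' @return Data frame with one row per descriptor.
#' @export
envfit_all <- function(result, descriptors, ...) {
  args <- list(...)
  rows <- lapply(seq_along(descriptors), function(i) {
    a <- c(list(result = result, descriptor = descriptors[[i]]), args)
    if (i > 1) a$seed <- NULL
    r <- do.call(envfit_pcoa, a)
    cbind(descriptor = names(descriptors)[i], r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
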