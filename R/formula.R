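#' @useDynLib domchar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Monoisotopic masses (CODATA/AME-derived values, Da). The electron mass
# matters because spectra are acquired on deprotonated anions.
.ELEMENT_MASS <- c(
  C = 12.000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)
.ELECTRON_MASS <- 0.00054857990
.PROTON_MASS <- .ELEMENT_MASS[["H"]] - .ELECTRON_MASS # 1.00727645
.C13_DELTA <- 1.0033548   # 13C - 12C mass difference, Da
.C13_ABUNDANCE <- 0.0107  # natural 13C isotopic abundance

.ELEMENTS <- c("c", "h", "n", "o", "s", "p")

#' Construct a table of molecular formulas
#'
#' A molecular formula over C, H, N, O, S, P is represented as one row of a
#' data frame with integer count columns `c`, `h`, `n`, `o`, `s`, `p`. Most
#' functions in the package accept and return such data frames, so that whole
#' formula libraries are handled vectorized.
#'
#' @param c,h,n,o,s,p Integer element counts (vectors recycle as in
#'   `data.frame()`).
#' @return A data frame with columns `c`, `h`, `n`, `o`, `s`, `p`.
#' @examples
#' molecular_formula(c = 13, h = 8, o = 6)   # C13H8O6
#' @export
molecular_formula <- function(c, h, n = 0L, o = 0L, s = 0L, p = 0L) {
  f <- data.frame(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                  o = as.integer(o), s = as.integer(s), p = as.integer(p))
  if (any(f < 0L)) stop("element counts must be nonnegative")
  if (any(f$c < 1L)) stop("formulas must contain at least one carbon")
  f
}

#' Canonical text form of molecular formulas
#'
#' Renders counts in the fixed element order C, H, N, O, S, P with zero-count
#' elements omitted and the count `1` written explicitly omitted (e.g.
#' `"C13H8O6"`, `"C21H43O9P"`).
#'
#' @param f Formula data frame (see [molecular_formula()]).
#' @return Character vector of formula strings.
#' @export
format_formula <- function(f) {
  sym <- c(c = "C", h = "H", n = "N", o = "O", s = "S", p = "P")
  out <- character(nrow(f))
  for (el in .ELEMENTS) {
    cnt <- f[[el]]
    piece <- ifelse(cnt == 0L, "",
                    ifelse(cnt == 1L, sym[[el]], paste0(sym[[el]], cnt)))
    out <- paste0(out, piece)
  }
  out
}

#' Parse canonical formula strings
#'
#' Inverse of [format_formula()] for formulas over C, H, N, O, S, P.
#'
#' @param x Character vector such as `"C47H66O18"`.
#' @return Formula data frame.
#' @export
parse_formula <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = 6,
                dimnames = list(NULL, .ELEMENTS))
  m <- gregexpr("([CHNOSP])([0-9]*)", x, perl = TRUE)
  for (i in seq_along(x)) {
    toks <- regmatches(x[i], m[i])[[1]]
    if (length(toks) == 0L || paste(toks, collapse = "") != x[i])
      stop("cannot parse formula: ", x[i])
    for (tk in toks) {
      el <- tolower(substr(tk, 1, 1))
      cnt <- substr(tk, 2, nchar(tk))
      out[i, el] <- out[i, el] + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  as.data.frame(out)
}

#' Neutral monoisotopic mass of molecular formulas
#'
#' @param f Formula data frame.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formula_mass(parse_formula("C13H8O6"))  # 260.03209
#' @export
formula_mass <- function(f) {
  as.numeric(as.matrix(f[, .ELEMENTS]) %*% .ELEMENT_MASS[toupper(.ELEMENTS)])
}

#' Singly deprotonated ion m/z of a neutral formula
#'
#' Negative-mode electrospray of DOM yields essentially singly charged
#' \eqn{[M-H]^-} ions: the ion m/z is the neutral mass minus a proton
#' (H minus an electron).
#'
#' @param f Formula data frame.
#' @return Numeric m/z vector.
#' @export
ion_mz <- function(f) formula_mass(f) - .PROTON_MASS

#' Convert observed negative-mode m/z to the neutral mass scale
#'
#' @param mz Observed m/z of singly deprotonated ions.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz) mz + .PROTON_MASS

#' Double bond equivalents
#'
#' DBE counts rings plus double bonds of a neutral formula, treating N and P
#' as trivalent: \eqn{DBE = 1 + C - H/2 + (N + P)/2}.
#'
#' @param f Formula data frame.
#' @return Numeric DBE vector.
#' @examples
#' dbe(parse_formula(c("CH4", "C6H6", "C13H8O6")))  # 0, 4, 10
#' @export
dbe <- function(f) 1 + f$c - f$h / 2 + (f$n + f$p) / 2

#' Modified aromaticity index
#'
#' AImod assumes half of the oxygen is bound in non-aromatic carbonyl-like
#' positions:
#' \deqn{AImod = \frac{1 + C - 0.5 O - S - 0.5 (N + P + H)}{C - 0.5 O - N - S - P}}
#' A non-positive denominator, or a negative ratio, yields 0.
#'
#' @param f Formula data frame.
#' @return Numeric vector of AImod values, clamped to `>= 0`.
#' @examples
#' aimod(parse_formula("C13H8O6"))  # 0.7
#' @export
aimod <- function(f) {
  num <- 1 + f$c - 0.5 * f$o - f$s - 0.5 * (f$n + f$p + f$h)
  den <- f$c - 0.5 * f$o - f$n - f$s - f$p
  ai <- ifelse(den > 0, num / den, 0)
  pmax(ai, 0)
}

#' Category labels used by the compound classifier
#'
#' The nine van Krevelen style compound categories: aromatic, highly
#' unsaturated and unsaturated each split into O-rich (O/C > 0.5) and O-poor
#' (O/C <= 0.5), unsaturated-with-N as its own class, and saturated split by
#' oxygen as well.
#'
#' @return Character vector of the 9 category labels in reporting order.
#' @export
category_levels <- function() {
  c("A_Or", "A_Op", "HUn_Or", "HUn_Op",
    "Un_Or", "Un_Op", "Un_withN", "Sat_Or", "Sat_Op")
}

#' Classify formulas into compound categories
#'
#' Thresholds: aromatic when AImod >= 0.5; highly unsaturated when
#' AImod < 0.5 and H/C < 1.5; unsaturated when 1.5 <= H/C <= 2 (reported
#' separately when the formula carries nitrogen); saturated when DBE = 0.
#' Each non-nitrogen class is split at O/C > 0.5 into O-rich vs O-poor.
#'
#' Precedence resolves the overlaps the raw thresholds permit: saturated is
#' decided first (DBE = 0), then aromatic, then unsaturated-with-N, then
#' unsaturated, then highly unsaturated. Heteroatom-rich formulas with
#' H/C > 2 but DBE > 0 fall outside all threshold windows and are routed to
#' the saturated split as the closest class.
#'
#' @param f Formula data frame.
#' @return Factor with levels [category_levels()].
#' @examples
#' classify_formula(parse_formula("C13H8O6"))   # A_Op
#' classify_formula(parse_formula("C16H32O2"))  # Un_Op
#' @export
classify_formula <- function(f) {
  hc <- f$h / f$c
  oc <- f$o / f$c
  ai <- aimod(f)
  de <- dbe(f)
  rich <- oc > 0.5

  out <- character(nrow(f))
  sat <- de == 0
  out[sat] <- ifelse(rich[sat], "Sat_Or", "Sat_Op")
  aro <- !sat & ai >= 0.5
  out[aro] <- ifelse(rich[aro], "A_Or", "A_Op")
  unwin <- !sat & !aro & hc >= 1.5 & hc <= 2
  unn <- unwin & f$n > 0
  out[unn] <- "Un_withN"
  un <- unwin & f$n == 0
  out[un] <- ifelse(rich[un], "Un_Or", "Un_Op")
  hun <- !sat & !aro & hc < 1.5
  out[hun] <- ifelse(rich[hun], "HUn_Or", "HUn_Op")
  # residual: DBE > 0 but H/C > 2 (possible with N or P); closest to saturated
  res <- out == ""
  out[res] <- ifelse(rich[res], "Sat_Or", "Sat_Op")
  factor(out, levels = category_levels())
}

#' Heteroatom group of formulas
#'
#' CHO (no heteroatoms), CHON (N only), CHOS (S only), CHOP (P only), and
#' Others (two or more heteroatom species, i.e. CHONS/CHOSP/CHONP/CHONSP).
#'
#' @param f Formula data frame.
#' @return Factor with levels CHO, CHON, CHOS, CHOP, Others.
#' @export
heteroatom_group <- function(f) {
  k <- (f$n > 0) + (f$s > 0) + (f$p > 0)
  out <- ifelse(k == 0, "CHO",
         ifelse(k >= 2, "Others",
         ifelse(f$n > 0, "CHON", ifelse(f$s > 0, "CHOS", "CHOP"))))
  factor(out, levels = c("CHO", "CHON", "CHOS", "CHOP", "Others"))
}

#' Per-formula composition descriptors
#'
#' Convenience wrapper returning H/C, O/C, DBE, AImod, neutral mass, compound
#' category and heteroatom group for every formula.
#'
#' @param f Formula data frame.
#' @return Data frame with columns `formula`, `mass`, `hc`, `oc`, `dbe`,
#'   `aimod`, `category`, `group`.
#' @export
formula_descriptors <- function(f) {
  data.frame(
    formula = format_formula(f),
    mass = formula_mass(f),
    hc = f$h / f$c,
    oc = f$o / f$c,
    dbe = dbe(f),
    aimod = aimod(f),
    category = classify_formula(f),
    group = heteroatom_group(f)
  )
}
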