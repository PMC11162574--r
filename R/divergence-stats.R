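#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / x_max) / (n - 1)` over the `n` tissues, with
#' `x_max` the profile maximum (Yanai-style index). Ranges from 0 for a
#' uniformly expressed gene to 1 for strict single-tissue expression, and
#' is invariant under positive rescaling of the profile. Computed here on
#' whatever scale the caller supplies; the pipeline uses log2(x+1) values,
#' matching the profiles the distances are computed on.
#'
#' @param x Non-negative numeric profile (length >= 2), or a gene x tissue
#'   matrix (tau per row).
#' @return Scalar in \[0, 1\], or a named vector for matrix input.
#' @export
tau <- function(x) {
  if (is.matrix(x)) {
    return(apply(unclass(x), 1, tau))
  }
  if (!is.numeric(x) || anyNA(x)) stop("profile must be numeric and complete")
  if (length(x) < 2) stop("tau needs at least two tissues")
  if (any(x < 0)) stop("tau requires non-negative expression values")
  m <- max(x)
  if (m == 0) stop("tau is undefined for an all-zero profile")
  sum(1 - x / m) / (length(x) - 1)
}

#' Pearson correlation with a t-distributed two-sided p-value
#'
#' Sample Pearson product-moment correlation; the p-value comes from the t
#' distribution with n - 2 degrees of freedom (via `stats::cor.test`).
#' Degenerate inputs (fewer than 3 complete observations, or zero variance
#' on either side) are an error rather than an NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate expression divergence with sequence divergence and tau
#'
#' One correlation row per covariate (Ka, Ks, Ka/Ks, tau) against the
#' expression divergence (Euclidean distance) of each duplicate. Records
#' missing a covariate are dropped from that covariate's row only
#' (pairwise-complete deletion, mirroring per-panel sample sizes), never
#' listwise.
#'
#' @param records Data frame with a `divergence` column and any of `ka`,
#'   `ks`, `kaks`, `tau`.
#' @param covariates Covariate columns to report (default all four).
#' @return Data frame with columns `covariate`, `n`, `r`, `p`, `note`;
#'   covariates that cannot be tested (n < 3 or zero variance) get NA with
#'   the reason in `note`.
#' @export
correlate_divergence <- function(records,
                                 covariates = c("ka", "ks", "kaks", "tau")) {
  if (!("divergence" %in% names(records))) {
    stop("records must contain a 'divergence' column")
  }
  rows <- lapply(covariates, function(cv) {
    if (!(cv %in% names(records))) {
      return(data.frame(covariate = cv, n = 0L, r = NA_real_, p = NA_real_,
                        note = "covariate absent", stringsAsFactors = FALSE))
    }
    ok <- is.finite(records$divergence) & is.finite(records[[cv]])
    x <- records$divergence[ok]
    y <- records[[cv]][ok]
    if (length(x) < 3) {
      return(data.frame(covariate = cv, n = length(x), r = NA_real_,
                        p = NA_real_, note = "fewer than 3 complete records",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(covariate = cv, n = length(x), r = NA_real_,
                        p = NA_real_, note = "zero variance",
                        stringsAsFactors = FALSE))
    }
    pc <- pearson_cor(x, y)
    data.frame(covariate = cv, n = pc$n, r = pc$r, p = pc$p, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
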