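#' The seven cis/trans regulatory-divergence categories
#'
#' Category identities follow the classical allele-specific-expression
#' scheme: I cis-only, II trans-only, III cis+trans enhancing (same
#' direction), IV cis x trans opposing, V compensatory, VI conserved,
#' VII ambiguous.
#'
#' @export
cis_trans_categories <- data.frame(
  category = c("I", "II", "III", "IV", "V", "VI", "VII"),
  label = c("cis only", "trans only", "cis + trans (enhancing)",
            "cis x trans (opposing)", "compensatory", "conserved",
            "ambiguous"),
  stringsAsFactors = FALSE)

#' Parent-mix and allopolyploid homoeolog log ratios
#'
#' The total regulatory divergence between the progenitor alleles is
#' `A = log2(sum A counts / sum C counts)` in the progenitor mix
#' (cis + trans combined); the divergence inside the allopolyploid's common
#' trans environment is `B = log2(An / Cn)` (cis effects); the trans
#' component is `A - B`. Ratios are computed on replicate-summed counts
#' with a pseudocount added to each side; per-replicate log ratios are
#' retained for the trans t-test.
#'
#' @param ct A [count_table()].
#' @param pseudocount Added to each side of every ratio (default 0.5) so
#'   zero counts cannot produce infinities.
#' @param lib_norm If `TRUE` (default), counts are first rescaled so every
#'   compartment x replicate library has the same total depth (the mean
#'   observed depth), mirroring the depth-matching of the in-silico
#'   progenitor mix to the allopolyploid libraries.
#' @return List with `ratios` (data frame: `pair_id`, `A`, `B`, `trans`,
#'   `untestable_A`, `untestable_B`), and per-replicate log2-ratio matrices
#'   `rep_ratios_parent`, `rep_ratios_allo`.
#' @export
compute_ratios <- function(ct, pseudocount = 0.5, lib_norm = TRUE) {
  if (!inherits(ct, "count_table")) stop("ct must be a count_table")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  mats <- lapply(count_compartments, function(cp) {
    m <- ct[[cp]]
    storage.mode(m) <- "double"
    m
  })
  names(mats) <- count_compartments
  if (lib_norm) {
    depths <- unlist(lapply(mats, colSums))
    target <- mean(depths)
    mats <- lapply(mats, function(m) {
      d <- colSums(m)
      d[d == 0] <- target  # empty library: nothing to rescale
      sweep(m, 2, target / d, "*")
    })
  }
  sa <- rowSums(mats$parentmix_A)
  sc <- rowSums(mats$parentmix_C)
  san <- rowSums(mats$allo_An)
  scn <- rowSums(mats$allo_Cn)
  A <- log2((sa + pseudocount) / (sc + pseudocount))
  B <- log2((san + pseudocount) / (scn + pseudocount))
  ratios <- data.frame(pair_id = pair_ids(ct), A = A, B = B, trans = A - B,
                       untestable_A = sa + sc == 0,
                       untestable_B = san + scn == 0,
                       stringsAsFactors = FALSE)
  rownames(ratios) <- NULL
  list(ratios = ratios,
       rep_ratios_parent = log2((mats$parentmix_A + pseudocount) /
                                  (mats$parentmix_C + pseudocount)),
       rep_ratios_allo = log2((mats$allo_An + pseudocount) /
                                (mats$allo_Cn + pseudocount)))
}

#' Common negative-binomial dispersion across pairs
#'
#' Method-of-moments estimate of a dispersion shared by all pairs: for each
#' pair x compartment with mean count >= `min_mean`, the moment estimate is
#' `(variance - mean) / mean^2`; the common value is the mean of these
#' (the per-pair estimates are unbiased but individually very noisy at few
#' replicates, so averaging, not the median of their skewed distribution,
#' recovers the common value), floored at zero. Used by [test_divergence()] to deflate pooled counts so
#' the exact binomial test is calibrated under biological replication.
#'
#' @param ct A [count_table()].
#' @param min_mean Minimum replicate-mean count for a pair to contribute
#'   (default 5; moment estimates below that are dominated by shot noise).
#' @return Non-negative scalar dispersion (0 when fewer than 2 replicates).
#' @export
estimate_dispersion <- function(ct, min_mean = 5) {
  if (n_reps(ct) < 2) return(0)
  ests <- unlist(lapply(count_compartments, function(cp) {
    m <- ct[[cp]]
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    est <- (v - mu) / mu^2
    est[mu >= min_mean]
  }))
  if (length(ests) == 0) return(0)
  max(0, mean(ests, na.rm = TRUE))
}

#' Test a homoeolog read-count ratio against 1:1
#'
#' Two-sided exact binomial test of the pooled counts of one side out of
#' the pooled total against 0.5. With `dispersion > 0` both pooled counts
#' are first deflated by the common quasi-likelihood factor
#' `1 + dispersion * h`, where `h` is the harmonic mean of the two
#' replicate-mean counts: this preserves the observed count proportion
#' while shrinking the total to the information actually carried by
#' negative-binomially overdispersed replicates (the deflated totals
#' reproduce the NB log-ratio variance `(1/R) * (1/m_x + 1/m_y + 2*phi)`),
#' keeping the test calibrated under biological replication.
#' `dispersion = 0` is the plain exact binomial test.
#'
#' @param x,y Non-negative replicate count vectors for the two sides.
#' @param dispersion Common NB dispersion (default 0), e.g. from
#'   [estimate_dispersion()].
#' @return Two-sided p-value, or `NA` when both sides are all zero
#'   (untestable).
#' @export
test_divergence <- function(x, y, dispersion = 0) {
  if (length(x) < 1 || length(y) < 1) stop("need at least one replicate per side")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  sx <- sum(x)
  sy <- sum(y)
  if (sx + sy == 0) return(NA_real_)
  mx <- mean(x)
  my <- mean(y)
  h <- if (mx == 0 || my == 0) 0 else 2 / (1 / mx + 1 / my)
  f <- 1 + dispersion * h
  xe <- round(sx / f)
  ye <- round(sy / f)
  if (xe + ye == 0) return(NA_real_)
  stats::binom.test(xe, xe + ye, p = 0.5, alternative = "two.sided")$p.value
}

#' Student's t-test for a trans effect (A != B)
#'
#' Two-sided two-sample Student's t-test (pooled variance) comparing the
#' per-replicate log2 homoeolog ratios in the progenitor mix against those
#' in the allopolyploid; with the usual 3-vs-3 replication the pooled
#' 4-df test is noticeably better powered than Welch and the two ratio
#' variances are equal by construction under the count model. Degenerate
#' zero-variance inputs (noiseless data) are resolved deterministically:
#' identical constant ratios give p = 1, different constants give p = 0.
#'
#' @param parent_ratios,allo_ratios Per-replicate log2 ratios (length >= 2
#'   each; shorter input returns `NA`, the untestable flag).
#' @return Two-sided p-value or `NA`.
#' @export
test_trans <- function(parent_ratios, allo_ratios) {
  if (length(parent_ratios) < 2 || length(allo_ratios) < 2) return(NA_real_)
  if (anyNA(parent_ratios) || anyNA(allo_ratios)) return(NA_real_)
  sp <- stats::sd(parent_ratios)
  sa <- stats::sd(allo_ratios)
  if (sp == 0 && sa == 0) {
    return(if (isTRUE(all.equal(mean(parent_ratios), mean(allo_ratios)))) 1 else 0)
  }
  out <- tryCatch(
    stats::t.test(parent_ratios, allo_ratios, var.equal = TRUE)$p.value,
    error = function(e) {
      ## "data are essentially constant": fall back to the deterministic rule
      if (isTRUE(all.equal(mean(parent_ratios), mean(allo_ratios)))) 1 else 0
    })
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), clipped at 1 and monotone in rank.
#' `NA` p-values (untestable pairs) are passed through as `NA` and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Assign the seven cis/trans regulatory categories
#'
#' Pure function of the three significance flags and the signs of B and of
#' the trans component:
#' \itemize{
#'   \item VI conserved: none of A, B, A-B significant
#'   \item I cis only: A and B significant, A-B not
#'   \item II trans only: A and A-B significant, B not
#'   \item V compensatory: B and A-B significant, A not
#'   \item III enhancing: all three significant, sign(B) == sign(trans)
#'   \item IV opposing: all three significant, sign(B) != sign(trans)
#'   \item VII ambiguous: every remaining combination, and any pair with an
#'     untestable (NA) flag
#' }
#'
#' @param sig_a,sig_b,sig_ab Logical vectors: is A != 0 / B != 0 / A != B
#'   significant at the FDR threshold. NAs route to VII.
#' @param sign_b,sign_trans Signs (or signed values) of B and trans.
#' @return Factor with levels I..VII.
#' @export
assign_category <- function(sig_a, sig_b, sig_ab, sign_b, sign_trans) {
  n <- length(sig_a)
  stopifnot(length(sig_b) == n, length(sig_ab) == n,
            length(sign_b) == n, length(sign_trans) == n)
  cat <- rep("VII", n)
  testable <- !is.na(sig_a) & !is.na(sig_b) & !is.na(sig_ab)
  a <- sig_a & testable
  b <- sig_b & testable
  ab <- sig_ab & testable
  cat[testable & !a & !b & !ab] <- "VI"
  cat[testable & a & b & !ab] <- "I"
  cat[testable & a & !b & ab] <- "II"
  cat[testable & !a & b & ab] <- "V"
  all3 <- testable & a & b & ab
  cat[all3 & sign(sign_b) == sign(sign_trans)] <- "III"
  cat[all3 & sign(sign_b) != sign(sign_trans)] <- "IV"
  factor(cat, levels = cis_trans_categories$category)
}

#' Full cis/trans category calling for a count table
#'
#' Runs the whole module: log ratios ([compute_ratios()]), the three
#' hypothesis tests per pair (A != 0 and B != 0 via [test_divergence()],
#' A != B via [test_trans()]), BH FDR adjustment across pairs per
#' hypothesis, and category assignment.
#'
#' @param ct A [count_table()].
#' @param pseudocount,lib_norm Passed to [compute_ratios()].
#' @param fdr_alpha FDR threshold for all three hypotheses (default 0.05).
#' @param dispersion Common NB dispersion for [test_divergence()]; default
#'   `NULL` estimates it from the table via [estimate_dispersion()]. Pass 0
#'   to force the plain binomial test.
#' @return Data frame with pair id, A, B, trans, the three p- and q-values,
#'   and `category`; attributes `dispersion` and `fdr_alpha` record the
#'   values used.
#' @export
call_cis_trans <- function(ct, pseudocount = 0.5, lib_norm = TRUE,
                           fdr_alpha = 0.05, dispersion = NULL) {
  cr <- compute_ratios(ct, pseudocount = pseudocount, lib_norm = lib_norm)
  phi <- dispersion %||% estimate_dispersion(ct)
  n <- n_pairs(ct)
  p_a <- p_b <- p_ab <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!cr$ratios$untestable_A[i]) {
      p_a[i] <- test_divergence(ct$parentmix_A[i, ], ct$parentmix_C[i, ], phi)
    }
    if (!cr$ratios$untestable_B[i]) {
      p_b[i] <- test_divergence(ct$allo_An[i, ], ct$allo_Cn[i, ], phi)
    }
    p_ab[i] <- test_trans(cr$rep_ratios_parent[i, ], cr$rep_ratios_allo[i, ])
  }
  q_a <- bh_fdr(p_a)
  q_b <- bh_fdr(p_b)
  q_ab <- bh_fdr(p_ab)
  out <- cr$ratios[, c("pair_id", "A", "B", "trans")]
  out$p_A <- p_a; out$p_B <- p_b; out$p_AB <- p_ab
  out$q_A <- q_a; out$q_B <- q_b; out$q_AB <- q_ab
  out$category <- assign_category(q_a < fdr_alpha, q_b < fdr_alpha,
                                  q_ab < fdr_alpha, out$B, out$trans)
  attr(out, "dispersion") <- phi
  attr(out, "fdr_alpha") <- fdr_alpha
  out
}

#' Category counts and proportions
#'
#' @param calls Output of [call_cis_trans()], or any data frame with a
#'   `category` column; optionally a `tissue` column for per-tissue output.
#' @param by Optional grouping column name (e.g. `"tissue"`); default
#'   pooled.
#' @return Data frame with columns (`by` group,) `category`, `n`,
#'   `proportion`; proportions sum to 1 within each group.
#' @export
category_summary <- function(calls, by = NULL) {
  if (nrow(calls) == 0) stop("no category calls to summarize")
  cat <- factor(calls$category, levels = cis_trans_categories$category)
  if (is.null(by)) {
    tab <- table(category = cat)
    return(data.frame(category = names(tab), n = as.integer(tab),
                      proportion = as.numeric(tab) / sum(tab),
                      stringsAsFactors = FALSE))
  }
  if (!(by %in% names(calls))) stop("grouping column not found: ", by)
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), calls[[by]]), function(i) {
    tab <- table(factor(calls$category[i], levels = cis_trans_categories$category))
    data.frame(group = calls[[by]][i[1]], category = names(tab),
               n = as.integer(tab), proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}

#' Chi-squared comparison of two category distributions
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 7
#' contingency table of category counts from two call sets, e.g. the
#' progenitor mix versus the allopolyploid.
#'
#' @param calls1,calls2 Data frames with a `category` column.
#' @return List with `statistic`, `df`, `p`, and the `table` tested
#'   (zero-count categories are dropped so expected counts are positive).
#' @export
compare_category_sets <- function(calls1, calls2) {
  t1 <- table(factor(calls1$category, levels = cis_trans_categories$category))
  t2 <- table(factor(calls2$category, levels = cis_trans_categories$category))
  tab <- rbind(set1 = as.integer(t1), set2 = as.integer(t2))
  colnames(tab) <- cis_trans_categories$category
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (identical(tab[1, ], tab[2, ])) {
    ## identical distributions: statistic 0, p 1 without the expected-count
    ## warning machinery
    return(list(statistic = 0, df = ncol(tab) - 1L, p = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
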