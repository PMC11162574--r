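#' The five duplicate-gene fate labels
#'
#' Neofunctionalization records which copy diverged, so the four biological
#' fates expand to five labels.
#'
#' @export
fate_levels <- c("conserved",
                 "neofunctionalized(parent)",
                 "neofunctionalized(child)",
                 "subfunctionalized",
                 "specialized")

#' Euclidean distance between two expression profiles
#'
#' The divergence measure underlying fate classification:
#' `sqrt(sum((p_i - q_i)^2))` over tissues. Profiles must be on the same
#' scale and in the same tissue order (Euclidean distance is
#' order-sensitive); length mismatch is an error.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q)) stop("profiles must be numeric")
  if (length(p) != length(q)) {
    stop(sprintf("profile length mismatch: %d vs %d", length(p), length(q)))
  }
  if (anyNA(p) || anyNA(q)) stop("profiles must not contain missing values")
  sqrt(sum((p - q)^2))
}

## row-wise distances between two matched gene x tissue matrices
profile_distances <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  sqrt(rowSums((unclass(P) - unclass(Q))^2))
}

#' Combined expression profile of a duplicate pair
#'
#' The parent+child unit is compared against the ancestral gene to separate
#' subfunctionalization from specialization. Transcript abundance is
#' additive on the raw scale, not in log space, so log2(x+1) profiles are
#' de-logged, summed, and re-logged: `log2(2^p + 2^c - 1)`
#' (equivalently `log2((2^p - 1) + (2^c - 1) + 1)`).
#'
#' @param parent,child Numeric profiles on the same scale and tissue order.
#' @param scale Scale both profiles are on: `"log2p1"` (default) or
#'   `"raw"`.
#' @return The combined profile on the same scale.
#' @export
combined_profile <- function(parent, child, scale = c("log2p1", "raw")) {
  scale <- match.arg(scale)
  if (length(parent) != length(child)) {
    stop("parent and child profiles differ in length")
  }
  if (scale == "raw") parent + child else log2(2^parent + 2^child - 1)
}

#' Select the E_div cutoff from single-copy ortholog distances
#'
#' E_div operationalizes the expression divergence expected between two
#' species in the absence of duplication: the empirical `q`-th quantile
#' (linear interpolation, `stats::quantile` type 7) of the Euclidean
#' distances between single-copy ortholog expression profiles.
#'
#' @param distances Numeric vector of single-copy ortholog distances.
#' @param q Quantile in (0, 1); default 0.90.
#' @param min_pairs Minimum number of distances required (default 30);
#'   below this the empirical quantile is too unstable and the caller must
#'   supply `e_div` explicitly.
#' @return The cutoff, with attribute `q`.
#' @export
select_ediv <- function(distances, q = 0.9, min_pairs = 30) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (anyNA(distances) || any(distances < 0)) {
    stop("distances must be non-negative and complete")
  }
  if (length(distances) < min_pairs) {
    stop(sprintf(paste0("only %d single-copy ortholog distances (need >= %d); ",
                        "supply e_div explicitly"),
                 length(distances), min_pairs))
  }
  ed <- stats::quantile(distances, probs = q, type = 7, names = FALSE)
  structure(ed, q = q)
}

#' Classify duplicate fates from expression distances
#'
#' Applies the distance rules, with ties at the cutoff classed as "<=",
#' i.e. toward conservation:
#' \itemize{
#'   \item conserved: `e_parent <= e_div` and `e_child <= e_div`
#'   \item neofunctionalized(child): `e_parent <= e_div < e_child`
#'   \item neofunctionalized(parent): `e_child <= e_div < e_parent`
#'   \item subfunctionalized: both `> e_div`, `e_combined <= e_div`
#'   \item specialized: both `> e_div`, `e_combined > e_div`
#' }
#' The rules are exhaustive and mutually exclusive: every finite input gets
#' exactly one fate. The neofunctionalized label names the copy that
#' diverged.
#'
#' @param e_parent,e_child,e_combined Distances of parent, child, and the
#'   combined parent+child profile from the ancestral profile (vectors,
#'   recycled to common length).
#' @param e_div Scalar cutoff (>= 0), usually from [select_ediv()].
#' @return Factor with levels [fate_levels].
#' @export
classify_fate <- function(e_parent, e_child, e_combined, e_div) {
  if (length(e_div) != 1 || !is.finite(e_div) || e_div < 0) {
    stop("e_div must be a single non-negative finite value")
  }
  n <- max(length(e_parent), length(e_child), length(e_combined))
  e_parent <- rep_len(e_parent, n)
  e_child <- rep_len(e_child, n)
  e_combined <- rep_len(e_combined, n)
  if (!all(is.finite(c(e_parent, e_child, e_combined)))) {
    stop("all distances must be finite")
  }
  ## absolute tolerance so float round-off in re-logged combined profiles
  ## cannot flip a boundary case (ties go toward "<=" by the rules anyway)
  tol <- 1e-9
  p_ok <- e_parent <= e_div + tol
  c_ok <- e_child <= e_div + tol
  fate <- ifelse(p_ok & c_ok, "conserved",
          ifelse(p_ok & !c_ok, "neofunctionalized(child)",
          ifelse(!p_ok & c_ok, "neofunctionalized(parent)",
          ifelse(e_combined <= e_div + tol, "subfunctionalized", "specialized"))))
  factor(fate, levels = fate_levels)
}

#' Fate classification for a full set of duplicate triples
#'
#' Orchestrates the distance method end to end: computes single-copy
#' ortholog distances between the two genomes, selects (or accepts) E_div,
#' computes each triple's parent, child and combined distances against its
#' ancestral gene, and classifies the fates.
#'
#' @param expr_ref Log2p1-scale [expression_matrix()] of the reference
#'   genome carrying the ancestral genes and the `gene_s1` side of the
#'   ortholog pairs.
#' @param expr_dup Log2p1-scale [expression_matrix()] of the
#'   duplicate-bearing genome (parent/child copies, `gene_s2` orthologs).
#'   Tissue order must match `expr_ref`.
#' @param pairs A [pair_tables()] with ortholog pairs and duplicate triples.
#' @param q Quantile passed to [select_ediv()] (default 0.90).
#' @param e_div Optional user-supplied cutoff; overrides quantile selection.
#' @param min_pairs Passed to [select_ediv()].
#' @return A `fate_result` list: `calls` (per-triple data frame with the
#'   three distances and the fate), `e_div`, `q`, `single_distances`, and
#'   the counts of pairs/triples skipped for missing genes.
#' @export
fate_analysis <- function(expr_ref, expr_dup, pairs, q = 0.9, e_div = NULL,
                          min_pairs = 30) {
  if (expr_scale(expr_ref) != "log2p1" || expr_scale(expr_dup) != "log2p1") {
    stop("fate_analysis expects log2(x+1)-transformed matrices")
  }
  if (!identical(colnames(expr_ref), colnames(expr_dup))) {
    stop("tissue labels/order differ between the two expression matrices")
  }
  op <- pairs$ortholog_pairs
  tr <- pairs$duplicate_triples
  if (is.null(tr) || nrow(tr) == 0) stop("no duplicate triples to classify")

  single_distances <- numeric(0)
  n_op_skipped <- 0L
  if (!is.null(op) && nrow(op) > 0) {
    ok <- op$gene_s1 %in% rownames(expr_ref) & op$gene_s2 %in% rownames(expr_dup)
    n_op_skipped <- sum(!ok)
    op <- op[ok, , drop = FALSE]
    single_distances <- profile_distances(expr_ref[op$gene_s1, , drop = FALSE],
                                          expr_dup[op$gene_s2, , drop = FALSE])
  }
  if (is.null(e_div)) {
    e_div <- select_ediv(single_distances, q = q, min_pairs = min_pairs)
  } else {
    if (length(e_div) != 1 || e_div < 0) stop("e_div must be a single value >= 0")
    q <- NA_real_
  }

  ok <- tr$ancestral_id %in% rownames(expr_ref) &
    tr$parent_id %in% rownames(expr_dup) & tr$child_id %in% rownames(expr_dup)
  n_tr_skipped <- sum(!ok)
  tr <- tr[ok, , drop = FALSE]
  if (nrow(tr) == 0) stop("no classifiable triples (all have missing profiles)")

  anc <- unclass(expr_ref[tr$ancestral_id, , drop = FALSE])
  par <- unclass(expr_dup[tr$parent_id, , drop = FALSE])
  chd <- unclass(expr_dup[tr$child_id, , drop = FALSE])
  comb <- log2(2^par + 2^chd - 1)
  e_parent <- sqrt(rowSums((par - anc)^2))
  e_child <- sqrt(rowSums((chd - anc)^2))
  e_combined <- sqrt(rowSums((comb - anc)^2))
  calls <- data.frame(ancestral_id = tr$ancestral_id,
                      parent_id = tr$parent_id,
                      child_id = tr$child_id,
                      dup_type = tr$dup_type,
                      e_parent = e_parent, e_child = e_child,
                      e_combined = e_combined,
                      e_div = as.numeric(e_div),
                      fate = classify_fate(e_parent, e_child, e_combined,
                                           as.numeric(e_div)),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, e_div = as.numeric(e_div), q = q,
                 single_distances = single_distances,
                 n_orthologs_skipped = n_op_skipped,
                 n_triples_skipped = n_tr_skipped),
            class = "fate_result")
}

#' @export
print.fate_result <- function(x, ...) {
  cat(sprintf("fate_result: %d triples, E_div = %.4g (q = %s)\n",
              nrow(x$calls), x$e_div,
              if (is.na(x$q)) "user-supplied" else format(x$q)))
  print(table(x$calls$fate))
  invisible(x)
}

#' Cross-tabulate fate calls by duplication type
#'
#' @param calls Either a `fate_result` or its `calls` data frame (columns
#'   `fate`, `dup_type`).
#' @return A list with `counts` (fate x dup_type contingency table whose
#'   grand total equals the number of calls) and `proportions` (each
#'   dup_type column normalized to sum to 1; all-zero columns are NaN).
#' @export
fate_by_dup_type <- function(calls) {
  if (inherits(calls, "fate_result")) calls <- calls$calls
  if (nrow(calls) == 0) {
    tab <- table(factor(character(), levels = fate_levels),
                 factor(character(), levels = dup_types))
    return(list(counts = tab, proportions = tab))
  }
  bad <- !(calls$dup_type %in% dup_types)
  if (any(bad)) {
    stop("unknown duplication type: ",
         paste(unique(calls$dup_type[bad]), collapse = ", "))
  }
  tab <- table(fate = factor(calls$fate, levels = fate_levels),
               dup_type = factor(calls$dup_type, levels = dup_types))
  prop <- sweep(tab, 2, colSums(tab), "/")
  list(counts = tab, proportions = prop)
}
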