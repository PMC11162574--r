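filter_report <- function(criterion, n_input, removed_ids,
                          removed_missing_ids = character(0)) {
  structure(list(criterion = criterion,
                 n_input = n_input,
                 n_removed = length(removed_ids) + length(removed_missing_ids),
                 n_retained = n_input - length(removed_ids) - length(removed_missing_ids),
                 removed_ids = removed_ids,
                 removed_missing_ids = removed_missing_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter [%s]: %d in, %d removed (%d missing-value), %d retained\n",
              x$criterion, x$n_input, x$n_removed,
              length(x$removed_missing_ids), x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(criterion = x$criterion, n_input = x$n_input,
             n_removed = x$n_removed, n_retained = x$n_retained,
             stringsAsFactors = FALSE)
}

#' Log-transform an expression matrix
#'
#' Replaces every value `v` by `log2(v + 1)` and flips the scale flag to
#' `"log2p1"`. Applying the transform to an already transformed matrix is
#' refused (it would silently compound).
#'
#' @param x A raw-scale [expression_matrix()].
#' @return The transformed `expression_matrix` (scale `"log2p1"`).
#' @export
log_transform <- function(x) {
  if (expr_scale(x) != "raw") {
    stop("matrix is already log2(x+1)-transformed; refusing to transform twice")
  }
  expression_matrix(log2(unclass(x) + 1), scale = "log2p1")
}

#' Remove genes expressed at noise level in every tissue
#'
#' A gene is removed if and only if its `log2(FPKM + 1)` value is strictly
#' below `threshold` in all tissues: such genes are expressed at levels
#' attributable to transcriptional noise. The comparison is strict, so a
#' gene with one value exactly at the threshold is retained.
#'
#' @param x A log2p1-scale [expression_matrix()].
#' @param threshold Removal cutoff on the log2(x+1) scale (default 1).
#' @return A list with elements `matrix` (the filtered matrix) and
#'   `report` (a `filter_report` with the removed gene ids).
#' @export
filter_low_expression <- function(x, threshold = 1) {
  if (expr_scale(x) != "log2p1") {
    stop("filter_low_expression expects a log2(x+1)-transformed matrix; ",
         "call log_transform() first")
  }
  low_all <- rowSums(unclass(x) >= threshold) == 0
  removed <- rownames(x)[low_all]
  kept <- x[!low_all, , drop = FALSE]
  list(matrix = kept,
       report = filter_report(sprintf("log2(FPKM+1) < %g in all tissues", threshold),
                              nrow(x), removed))
}

#' Remove duplicate triples with saturated or missing Ks
#'
#' Drops triples whose synonymous divergence `Ks` is at or above `max_ks`
#' (substitution saturation makes such estimates unreliable) and, counted
#' separately, triples whose Ks is absent from the Ka/Ks table. The
#' comparison is strict: `Ks = 2.99` is retained, `Ks = 3` removed. Ka/Ks
#' values are looked up by the triple's child gene id.
#'
#' @param pairs A [pair_tables()] with `duplicate_triples` and `kaks`.
#' @param max_ks Exclusive upper bound on Ks (default 3).
#' @return A list with elements `pairs` (filtered [pair_tables()]) and
#'   `report` (a `filter_report`; triples with missing Ks appear in
#'   `removed_missing_ids`).
#' @export
filter_ks <- function(pairs, max_ks = 3) {
  if (!inherits(pairs, "pair_tables")) stop("pairs must be a pair_tables object")
  tr <- pairs$duplicate_triples
  if (is.null(tr)) stop("pair_tables has no duplicate triples to filter")
  if (is.null(pairs$kaks)) stop("pair_tables has no Ka/Ks table")
  ks <- pairs$kaks$ks[match(tr$child_id, pairs$kaks$id)]
  missing <- is.na(ks)
  saturated <- !missing & ks >= max_ks
  keep <- !missing & !saturated
  out <- pairs
  out$duplicate_triples <- tr[keep, , drop = FALSE]
  rownames(out$duplicate_triples) <- NULL
  list(pairs = out,
       report = filter_report(sprintf("Ks < %g", max_ks), nrow(tr),
                              removed_ids = tr$child_id[saturated],
                              removed_missing_ids = tr$child_id[missing]))
}

#' Drop triples and ortholog pairs with filtered-out members
#'
#' After the low-expression filter, a triple whose ancestral, parent or
#' child gene was removed can no longer be classified; likewise an ortholog
#' pair with a removed member cannot contribute a calibration distance.
#' Both are dropped here, with counts reported.
#'
#' @param pairs A [pair_tables()].
#' @param ref_ids Gene ids retained in the reference (ancestral-genome)
#'   matrix.
#' @param dup_ids Gene ids retained in the duplicate-genome matrix.
#' @return A list with elements `pairs`, `n_triples_dropped`,
#'   `n_orthologs_dropped`.
#' @export
drop_incomplete_triples <- function(pairs, ref_ids, dup_ids) {
  out <- pairs
  n_tr <- 0L
  n_op <- 0L
  if (!is.null(pairs$duplicate_triples)) {
    tr <- pairs$duplicate_triples
    keep <- tr$ancestral_id %in% ref_ids &
      tr$parent_id %in% dup_ids & tr$child_id %in% dup_ids
    n_tr <- sum(!keep)
    out$duplicate_triples <- tr[keep, , drop = FALSE]
    rownames(out$duplicate_triples) <- NULL
  }
  if (!is.null(pairs$ortholog_pairs)) {
    op <- pairs$ortholog_pairs
    keep <- op$gene_s1 %in% ref_ids & op$gene_s2 %in% dup_ids
    n_op <- sum(!keep)
    out$ortholog_pairs <- op[keep, , drop = FALSE]
    rownames(out$ortholog_pairs) <- NULL
  }
  list(pairs = out, n_triples_dropped = n_tr, n_orthologs_dropped = n_op)
}
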