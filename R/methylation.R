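#' The four expression classes
#' @export
expression_classes <- c("non", "low", "medium", "high")

#' Classify genes into expression classes
#'
#' FPKM cutpoints: `non` below 0.001; `low` from 0.001 to 5 (both ends
#' inclusive: "between x and y" read as a closed interval); `medium` above
#' 5 up to 50 inclusive; `high` strictly above 50.
#'
#' @param fpkm Non-negative numeric vector of raw-scale expression values.
#' @return Factor with levels [expression_classes].
#' @export
classify_expression <- function(fpkm) {
  if (anyNA(fpkm)) stop("fpkm must be complete")
  if (any(fpkm < 0)) stop("fpkm must be non-negative")
  cls <- ifelse(fpkm < 0.001, "non",
         ifelse(fpkm <= 5, "low",
         ifelse(fpkm <= 50, "medium", "high")))
  out <- factor(cls, levels = expression_classes)
  names(out) <- names(fpkm)
  out
}

genes_to_granges <- function(genes) {
  genes <- validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(seqnames = genes$chrom,
                               ranges = IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}

## strand-aware region GRanges; regions running past chromosome start are
## truncated at position 1 (count reported via attribute)
region_granges <- function(genes, region, flank = 2000) {
  gr <- genes_to_granges(genes)
  rg <- switch(region,
    promoter = GenomicRanges::promoters(gr, upstream = flank, downstream = 0),
    gene_body = gr,
    downstream = GenomicRanges::flank(gr, width = flank, start = FALSE),
    stop("unknown region: ", region))
  n_trunc <- sum(GenomicRanges::start(rg) < 1)
  if (n_trunc > 0) {
    message(n_trunc, " ", region, " region(s) truncated at chromosome start")
    st <- pmax(GenomicRanges::start(rg), 1L)
    en <- pmax(GenomicRanges::end(rg), 0L)
    rg <- GenomicRanges::GRanges(GenomicRanges::seqnames(rg),
                                 IRanges::IRanges(st, pmax(en, st - 1L)),
                                 strand = GenomicRanges::strand(rg))
    names(rg) <- names(gr)
  }
  attr(rg, "n_truncated") <- n_trunc
  rg
}

calls_to_granges <- function(calls, context = "all") {
  if (!identical(context, "all")) {
    if (!all(context %in% meth_contexts)) stop("unknown context: ", context)
    calls <- calls[calls$context %in% context, , drop = FALSE]
  }
  list(calls = calls,
       gr = GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$position, width = 1)))
}

#' Coverage-weighted region methylation level per gene
#'
#' Pools all cytosine calls of the requested context inside a gene's
#' region and reports the coverage-weighted level
#' `sum(n_methylated) / sum(n_total)`. Regions are strand-aware: the
#' promoter is the 2 kb upstream of the TSS, the downstream region the
#' 2 kb past the TES. A gene with fewer covered cytosines than `min_sites`
#' gets `NA` (level undefined at that coverage).
#'
#' @param calls Methylation-call data frame ([read_methylation_calls()]).
#' @param genes Gene-model data frame ([read_gff3_genes()]).
#' @param region One of `"gene_body"`, `"promoter"`, `"downstream"`.
#' @param context `"CG"`, `"CHG"`, `"CHH"`, a vector of these, or `"all"`.
#' @param min_sites Minimum covered cytosines for a defined level
#'   (default 3).
#' @param flank Flank width in bp for promoter/downstream (default 2000).
#' @return Data frame: `gene_id`, `region`, `context`, `level`, `n_sites`.
#' @export
region_methylation <- function(calls, genes,
                               region = c("gene_body", "promoter", "downstream"),
                               context = "all", min_sites = 3, flank = 2000) {
  region <- match.arg(region)
  cc <- calls_to_granges(calls, context)
  rg <- region_granges(genes, region, flank)
  hits <- GenomicRanges::findOverlaps(cc$gr, rg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  m <- rowsum(cc$calls$n_methylated[qi], si)
  t <- rowsum(cc$calls$n_total[qi], si)
  ns <- rowsum(rep(1L, length(si)), si)
  gene_idx <- as.integer(rownames(m))
  level <- rep(NA_real_, length(rg))
  n_sites <- rep(0L, length(rg))
  level[gene_idx] <- m[, 1] / t[, 1]
  n_sites[gene_idx] <- ns[, 1]
  level[n_sites < min_sites] <- NA_real_
  data.frame(gene_id = names(rg), region = region,
             context = paste(context, collapse = "+"),
             level = level, n_sites = n_sites, stringsAsFactors = FALSE)
}

#' Expression-class-stratified meta-gene methylation profile
#'
#' Averages methylation over genes in aligned bins: `flank/flank_bin_width`
#' fixed-width bins across the 2 kb upstream of the TSS, `n_body_bins`
#' proportional bins across the gene body, and fixed-width bins across the
#' 2 kb downstream of the TES, all strand-aware (upstream is 5' of the TSS
#' in transcription direction). Within each bin and expression class the
#' level is the coverage-weighted pool `sum(m) / sum(t)` across all
#' contributing cytosines of all genes. Genes shorter than `n_body_bins`
#' bp cannot fill one site per body bin and are excluded (count reported
#' via the `"n_excluded_short"` attribute).
#'
#' @param calls Methylation-call data frame.
#' @param genes Gene-model data frame.
#' @param classes Factor/character of expression classes named by gene id
#'   (e.g. from [classify_expression()]); genes without a class are dropped.
#' @param context Context filter as in [region_methylation()].
#' @param n_body_bins Number of relative gene-body bins (default 40).
#' @param flank_bin_width Width of each flank bin in bp (default 100; must
#'   divide `flank`).
#' @param flank Flank span in bp (default 2000).
#' @return Data frame with one row per bin x class: `bin` (1-based across
#'   upstream, body, downstream), `zone`, `class`, `level`, `n_sites`,
#'   `n_genes`. Bins with no covered cytosines in a class have `NA` level.
#' @export
metagene_profile <- function(calls, genes, classes, context = "all",
                             n_body_bins = 40, flank_bin_width = 100,
                             flank = 2000) {
  if (flank %% flank_bin_width != 0) {
    stop("flank must be a multiple of flank_bin_width")
  }
  n_flank <- flank %/% flank_bin_width
  genes <- validate_gene_models(genes)
  cls <- as.character(classes)[match(genes$gene_id, names(classes))]
  n_unclassed <- sum(is.na(cls))
  genes <- genes[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  if (nrow(genes) == 0) stop("no genes with an expression class")
  len <- genes$end - genes$start + 1
  short <- len < n_body_bins
  n_short <- sum(short)
  genes <- genes[!short, , drop = FALSE]
  cls <- cls[!short]
  len <- len[!short]
  if (nrow(genes) == 0) stop("all genes shorter than n_body_bins bp")

  cc <- calls_to_granges(calls, context)
  loci <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(genes$start - flank, 1L),
                                                  genes$end + flank))
  hits <- GenomicRanges::findOverlaps(cc$gr, loci)
  qi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- cc$calls$position[qi]
  plus <- genes$strand[gi] == "+"
  ## position along transcription direction; t < 0 upstream of the TSS,
  ## t in [0, L) inside the body, t >= L downstream of the TES
  t_dir <- ifelse(plus, pos - genes$start[gi], genes$end[gi] - pos)
  L <- len[gi]
  n_bins <- 2L * n_flank + n_body_bins
  bin <- integer(length(t_dir))
  up <- t_dir < 0
  body <- t_dir >= 0 & t_dir < L
  down <- t_dir >= L
  bin[up] <- (t_dir[up] + flank) %/% flank_bin_width
  bin[body] <- n_flank + (t_dir[body] * n_body_bins) %/% L[body]
  bin[down] <- n_flank + n_body_bins + (t_dir[down] - L[down]) %/% flank_bin_width
  bin <- bin + 1L

  class_f <- factor(cls, levels = expression_classes)
  key <- (bin - 1L) * length(expression_classes) + as.integer(class_f[gi])
  m <- rowsum(cc$calls$n_methylated[qi], key)
  t_ <- rowsum(cc$calls$n_total[qi], key)
  ns <- rowsum(rep(1L, length(qi)), key)
  ug <- tapply(gi, key, function(v) length(unique(v)))

  grid_bin <- rep(seq_len(n_bins), each = length(expression_classes))
  grid_cls <- rep(expression_classes, times = n_bins)
  grid_key <- (grid_bin - 1L) * length(expression_classes) +
    match(grid_cls, expression_classes)
  idx <- match(grid_key, as.integer(rownames(m)))
  level <- ifelse(is.na(idx), NA_real_, m[idx, 1] / t_[idx, 1])
  nsites <- ifelse(is.na(idx), 0L, ns[idx, 1])
  ngen <- ifelse(is.na(idx), 0L, as.integer(ug[match(grid_key, as.integer(names(ug)))]))
  zone <- ifelse(grid_bin <= n_flank, "upstream",
          ifelse(grid_bin <= n_flank + n_body_bins, "body", "downstream"))
  empty_classes <- setdiff(expression_classes, unique(cls))
  if (length(empty_classes) > 0) {
    message("no genes in expression class(es): ",
            paste(empty_classes, collapse = ", "))
  }
  out <- data.frame(bin = grid_bin, zone = zone,
                    class = factor(grid_cls, levels = expression_classes),
                    level = level, n_sites = nsites, n_genes = ngen,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded_short") <- n_short
  attr(out, "n_unclassed") <- n_unclassed
  attr(out, "n_flank_bins") <- n_flank
  attr(out, "n_body_bins") <- n_body_bins
  out
}

#' Correlation between region methylation and expression
#'
#' Pearson correlation (and t-distribution p-value) between per-gene
#' region methylation levels and `log2(FPKM + 1)`, per region x context
#' group. Degenerate groups (fewer than 3 defined levels, or constant
#' values) are reported as NA with the reason.
#'
#' @param region_levels Output of [region_methylation()] (possibly several
#'   rbind-ed regions/contexts).
#' @param fpkm Named numeric vector of raw-scale expression, names = gene
#'   ids.
#' @return Data frame: `region`, `context`, `n`, `r`, `p`, `note`.
#' @export
methylation_expression_association <- function(region_levels, fpkm) {
  groups <- unique(region_levels[, c("region", "context")])
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    sub <- region_levels[region_levels$region == groups$region[k] &
                           region_levels$context == groups$context[k], ]
    expr <- fpkm[sub$gene_id]
    ok <- !is.na(sub$level) & !is.na(expr)
    x <- sub$level[ok]
    y <- log2(expr[ok] + 1)
    base <- data.frame(region = groups$region[k], context = groups$context[k],
                       n = sum(ok), r = NA_real_, p = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (sum(ok) < 3) {
      base$note <- "fewer than 3 genes with defined level"
    } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      base$note <- "zero variance"
    } else {
      pc <- pearson_cor(x, y)
      base$r <- pc$r
      base$p <- pc$p
    }
    base
  })
  do.call(rbind, rows)
}
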