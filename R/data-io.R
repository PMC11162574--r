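#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 file via `rtracklayer::readGFF` and keeps records of type
#' `"gene"` only. Coordinates are kept 1-based inclusive (GFF3 native);
#' this is the single internal coordinate convention for the whole package.
#'
#' @param path GFF3 file path.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`. Files with no gene records yield a zero-row frame.
#' @details A gene record with `start > end` or with a strand other than
#'   `+`/`-` (e.g. `.`) is rejected: gene models without an orientation
#'   cannot anchor strand-aware promoter/flank regions.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) load_error("GFF3 file does not exist: %s", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (nrow(g) == 0) return(empty)
  g <- g[as.character(g$type) == "gene", , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  strand <- as.character(g$strand)
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    load_error("gene record(s) with unsupported strand '%s' (need + or -)",
               paste(unique(strand[bad]), collapse = "','"))
  }
  if (any(g$start > g$end)) {
    load_error("gene record(s) with start > end at %s:%d",
               as.character(g$seqid)[g$start > g$end][1],
               g$start[g$start > g$end][1])
  }
  id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  if ("Name" %in% names(g)) {
    id[is.na(id)] <- as.character(g$Name)[is.na(id)]
  }
  if (anyNA(id)) load_error("gene record(s) without an ID attribute")
  data.frame(gene_id = id, chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = strand, stringsAsFactors = FALSE)
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    load_error("gene model table missing column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (any(genes$start > genes$end)) load_error("gene model with start > end")
  if (!all(genes$strand %in% c("+", "-"))) {
    load_error("gene model strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) load_error("duplicated gene_id in gene models")
  genes
}

meth_contexts <- c("CG", "CHG", "CHH")

#' Read per-cytosine methylation calls
#'
#' Canonical input is a 5-column TSV (CGmap-like dialect): `chrom`,
#' `position` (1-based), `context` (CG/CHG/CHH), `n_methylated`, `n_total`.
#' Rows with zero coverage (`n_total == 0`) carry no information and are
#' dropped; the number dropped is reported via a message and the
#' `"n_dropped"` attribute. A row with more methylated than total reads is
#' an inconsistent call and rejects the whole load.
#'
#' @param path TSV file path.
#' @return A data frame of calls (columns as above) with attribute
#'   `n_dropped`.
#' @seealso [methylation_from_bedgraph()] for fraction+coverage input.
#' @export
read_methylation_calls <- function(path) {
  df <- read_tsv_file(path, required_cols = c("chrom", "position", "context",
                                              "n_methylated", "n_total"))
  validate_methylation_calls(df)
}

validate_methylation_calls <- function(df) {
  df$chrom <- as.character(df$chrom)
  df$position <- as.integer(df$position)
  df$context <- as.character(df$context)
  df$n_methylated <- as.integer(df$n_methylated)
  df$n_total <- as.integer(df$n_total)
  if (anyNA(df$position) || any(df$position < 1)) {
    load_error("methylation call with missing or non-positive position")
  }
  bad_ctx <- !(df$context %in% meth_contexts)
  if (any(bad_ctx)) {
    load_error("unknown methylation context '%s'",
               paste(unique(df$context[bad_ctx]), collapse = "','"))
  }
  if (anyNA(df$n_methylated) || anyNA(df$n_total) || any(df$n_methylated < 0)) {
    load_error("methylation call with missing or negative read counts")
  }
  over <- df$n_methylated > df$n_total
  if (any(over)) {
    i <- which(over)[1]
    load_error("methylation call at %s:%d has n_methylated (%d) > n_total (%d)",
               df$chrom[i], df$position[i], df$n_methylated[i], df$n_total[i])
  }
  drop <- df$n_total == 0
  if (any(drop)) {
    message(sum(drop), " zero-coverage methylation call(s) dropped")
    df <- df[!drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_dropped") <- sum(drop)
  df
}

#' Convert bedGraph-style methylation fractions to call counts
#'
#' Some methylation extractors emit a per-cytosine methylation fraction plus
#' read coverage instead of methylated/total read counts. This converter
#' reconstructs integer counts (`n_methylated = round(level * coverage)`)
#' so the rest of the pipeline sees one dialect only.
#'
#' @param df Data frame with columns `chrom`, `position`, `context`,
#'   `level` (in \[0,1\]) and `coverage` (non-negative integer).
#' @return A validated methylation-call data frame as returned by
#'   [read_methylation_calls()].
#' @export
methylation_from_bedgraph <- function(df) {
  need <- c("chrom", "position", "context", "level", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    load_error("bedGraph-style input missing column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (any(df$level < 0 | df$level > 1, na.rm = TRUE) || anyNA(df$level)) {
    load_error("methylation level must lie in [0, 1]")
  }
  out <- data.frame(chrom = as.character(df$chrom),
                    position = as.integer(df$position),
                    context = as.character(df$context),
                    n_methylated = as.integer(round(df$level * df$coverage)),
                    n_total = as.integer(df$coverage),
                    stringsAsFactors = FALSE)
  validate_methylation_calls(out)
}

dup_types <- c("WGD", "TD", "PD", "DSD", "TRD")

#' Ortholog pairs, duplicate triples and Ka/Ks values
#'
#' Bundles the three relationship tables the fate and divergence modules
#' consume: single-copy ortholog pairs between the reference (ancestral)
#' genome and the duplicate-bearing genome; duplicate triples (ancestral,
#' parent, child plus duplication type); and a per-duplicate Ka/Ks table.
#' Ka/Ks values are consumed as precomputed input, keyed by the triple's
#' child gene id (the duplicate whose divergence from the ancestral copy
#' the alignment measured).
#'
#' @param ortholog_pairs Data frame with columns `gene_s1`, `gene_s2`
#'   (reference-genome and duplicate-genome gene ids), or `NULL`.
#' @param duplicate_triples Data frame with columns `ancestral_id`,
#'   `parent_id`, `child_id`, `dup_type` (one of WGD, TD, PD, DSD, TRD),
#'   or `NULL`.
#' @param kaks Data frame with columns `id`, `ka`, `ks`, `kaks`, or `NULL`.
#' @return A `pair_tables` object (a validated list of the three tables).
#' @export
pair_tables <- function(ortholog_pairs = NULL, duplicate_triples = NULL,
                        kaks = NULL) {
  if (!is.null(ortholog_pairs)) {
    miss <- setdiff(c("gene_s1", "gene_s2"), names(ortholog_pairs))
    if (length(miss) > 0) {
      load_error("ortholog pair table missing column(s): %s",
                 paste(miss, collapse = ", "))
    }
  }
  if (!is.null(duplicate_triples)) {
    need <- c("ancestral_id", "parent_id", "child_id", "dup_type")
    miss <- setdiff(need, names(duplicate_triples))
    if (length(miss) > 0) {
      load_error("duplicate triple table missing column(s): %s",
                 paste(miss, collapse = ", "))
    }
    bad <- !(duplicate_triples$dup_type %in% dup_types)
    if (any(bad)) {
      load_error("unknown duplication type '%s' (allowed: %s)",
                 paste(unique(duplicate_triples$dup_type[bad]), collapse = "','"),
                 paste(dup_types, collapse = ", "))
    }
    same <- duplicate_triples$parent_id == duplicate_triples$child_id
    if (any(same)) {
      load_error("triple(s) with identical parent and child id: %s",
                 paste(utils::head(duplicate_triples$parent_id[same], 5),
                       collapse = ", "))
    }
  }
  if (!is.null(kaks)) {
    miss <- setdiff(c("id", "ka", "ks", "kaks"), names(kaks))
    if (length(miss) > 0) {
      load_error("Ka/Ks table missing column(s): %s", paste(miss, collapse = ", "))
    }
  }
  structure(list(ortholog_pairs = ortholog_pairs,
                 duplicate_triples = duplicate_triples,
                 kaks = kaks),
            class = "pair_tables")
}

#' @export
print.pair_tables <- function(x, ...) {
  cat("pair_tables:\n")
  cat("  ortholog pairs:   ", if (is.null(x$ortholog_pairs)) 0 else nrow(x$ortholog_pairs), "\n")
  cat("  duplicate triples:", if (is.null(x$duplicate_triples)) 0 else nrow(x$duplicate_triples), "\n")
  cat("  Ka/Ks entries:    ", if (is.null(x$kaks)) 0 else nrow(x$kaks), "\n")
  invisible(x)
}

#' Read the pair/triple/Ka-Ks tables from TSV files
#'
#' @param orthologs_path TSV with columns `gene_s1`, `gene_s2`; or `NULL`.
#' @param triples_path TSV with columns `ancestral_id`, `parent_id`,
#'   `child_id`, `dup_type`; or `NULL`.
#' @param kaks_path TSV with columns `id`, `ka`, `ks`, `kaks`; or `NULL`.
#' @return A [pair_tables()] object.
#' @export
read_pair_tables <- function(orthologs_path = NULL, triples_path = NULL,
                             kaks_path = NULL) {
  op <- if (!is.null(orthologs_path)) {
    read_tsv_file(orthologs_path, c("gene_s1", "gene_s2"))
  }
  tr <- if (!is.null(triples_path)) {
    read_tsv_file(triples_path, c("ancestral_id", "parent_id", "child_id", "dup_type"))
  }
  kk <- if (!is.null(kaks_path)) {
    read_tsv_file(kaks_path, c("id", "ka", "ks", "kaks"))
  }
  pair_tables(op, tr, kk)
}

count_compartments <- c("parentmix_A", "parentmix_C", "allo_An", "allo_Cn")

#' Replicate read counts for homoeolog pairs
#'
#' Holds, for each homoeolog pair, replicate-level read counts in the four
#' compartments the cis/trans analysis compares: the A and C homoeologs in
#' the in-silico progenitor mix, and the An and Cn homoeologs in the
#' allopolyploid. Each argument is a pairs-by-replicates integer matrix;
#' all four must share dimensions and pair ids (row names).
#'
#' @param parentmix_A,parentmix_C,allo_An,allo_Cn Non-negative integer
#'   matrices, pairs in rows (row names = pair ids), replicates in columns.
#' @return A `count_table` object.
#' @export
count_table <- function(parentmix_A, parentmix_C, allo_An, allo_Cn) {
  mats <- list(parentmix_A = parentmix_A, parentmix_C = parentmix_C,
               allo_An = allo_An, allo_Cn = allo_Cn)
  dims <- lapply(mats, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    load_error("count matrices must share dimensions (same pairs, same replicates)")
  }
  ids <- rownames(parentmix_A)
  if (is.null(ids)) load_error("count matrices need pair ids as row names")
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!identical(rownames(m), ids)) {
      load_error("count matrix %s has mismatched pair ids", nm)
    }
    if (anyNA(m) || any(m < 0) || any(!is_wholenumber(m))) {
      load_error("count matrix %s must contain non-negative integers", nm)
    }
    storage.mode(mats[[nm]]) <- "integer"
  }
  structure(mats, class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d homoeolog pairs x %d replicates x 4 compartments\n",
              nrow(x$parentmix_A), ncol(x$parentmix_A)))
  invisible(x)
}

pair_ids <- function(ct) rownames(ct$parentmix_A)
n_pairs <- function(ct) nrow(ct$parentmix_A)
n_reps <- function(ct) ncol(ct$parentmix_A)

#' Read a homoeolog count table from long-format TSV
#'
#' Expects columns `pair_id`, `compartment` (one of `parentmix_A`,
#' `parentmix_C`, `allo_An`, `allo_Cn`), `replicate` (1..R) and `count`.
#' Every pair must have the same number of replicates in all four
#' compartments.
#'
#' @param path TSV file path.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- read_tsv_file(path, c("pair_id", "compartment", "replicate", "count"))
  bad <- !(df$compartment %in% count_compartments)
  if (any(bad)) {
    load_error("unknown compartment '%s'",
               paste(unique(df$compartment[bad]), collapse = "','"))
  }
  ids <- unique(df$pair_id)
  reps <- sort(unique(df$replicate))
  mats <- lapply(count_compartments, function(cp) {
    sub <- df[df$compartment == cp, , drop = FALSE]
    m <- matrix(NA_integer_, nrow = length(ids), ncol = length(reps),
                dimnames = list(ids, NULL))
    m[cbind(match(sub$pair_id, ids), match(sub$replicate, reps))] <- sub$count
    if (anyNA(m)) {
      load_error("compartment %s has missing replicate counts (unequal replication)", cp)
    }
    m
  })
  names(mats) <- count_compartments
  do.call(count_table, mats)
}

#' Write a homoeolog count table as long-format TSV
#'
#' @param ct A [count_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  long <- do.call(rbind, lapply(count_compartments, function(cp) {
    m <- ct[[cp]]
    data.frame(pair_id = rep(rownames(m), ncol(m)),
               compartment = cp,
               replicate = rep(seq_len(ncol(m)), each = nrow(m)),
               count = as.vector(m), stringsAsFactors = FALSE)
  }))
  write_tsv(long, path)
}

#' Write gene models as a minimal GFF3 file
#'
#' Emits one `gene` record per row (source `allodup`, `ID=` attribute),
#' suitable for re-loading with [read_gff3_genes()].
#'
#' @param genes Gene-model data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  genes <- validate_gene_models(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\tallodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write methylation calls as TSV
#'
#' Inverse of [read_methylation_calls()].
#'
#' @param calls Methylation-call data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path) {
  write_tsv(calls[, c("chrom", "position", "context", "n_methylated", "n_total")],
            path)
}
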