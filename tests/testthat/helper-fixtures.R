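# Small fixtures built in code; nothing is stored on disk.

tiny_expr_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_matrix <- function(values, genes = NULL, tissues = NULL,
                        scale = "raw") {
  m <- matrix(values, nrow = length(values) / 4, ncol = 4, byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- tissues %||% c("stem", "leaf", "flower", "silique")
  expression_matrix(m, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

tiny_counts <- function(pa, pc, an, cn, ids = NULL) {
  as_mat <- function(v) {
    m <- if (is.matrix(v)) v else matrix(v, nrow = 1)
    rownames(m) <- ids %||% sprintf("p%02d", seq_len(nrow(m)))
    m
  }
  count_table(as_mat(pa), as_mat(pc), as_mat(an), as_mat(cn))
}

# mirror a methylome through the end of its genome: positions reverse,
# strands flip; meta-gene profiles must be unchanged
mirror_methylome <- function(genes, calls) {
  g_len <- max(genes$end, calls$position) + 1000L
  list(genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          start = g_len + 1L - genes$end,
                          end = g_len + 1L - genes$start,
                          strand = ifelse(genes$strand == "+", "-", "+"),
                          stringsAsFactors = FALSE),
       calls = data.frame(chrom = calls$chrom,
                          position = g_len + 1L - calls$position,
                          context = calls$context,
                          n_methylated = calls$n_methylated,
                          n_total = calls$n_total, stringsAsFactors = FALSE))
}
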