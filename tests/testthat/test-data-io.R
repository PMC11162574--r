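test_that("expression matrices round-trip through TSV at full precision", {
  m <- tiny_matrix(c(0.123456789012345, 5, 0, 17.25,
                     3.999999999999999, 0.001, 200, 1e-12))
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_identical(dim(back), dim(m))
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(unclass(back), unclass(m), tolerance = 0)
  expect_identical(expr_scale(back), "raw")
})

test_that("expression loader rejects malformed input naming the offender", {
  ok <- tiny_expr_tsv(c("gene_id\tstem\tleaf\tflower\tsilique",
                        "gA\t1\t2\t3\t4", "gB\t0\t0\t5\t1"))
  m <- read_expression_matrix(ok)
  expect_identical(dim(m), c(2L, 4L))

  neg <- tiny_expr_tsv(c("gene_id\tstem\tleaf\tflower\tsilique",
                         "gA\t1\t2\t3\t4", "gB\t0\t-2\t5\t1"))
  expect_error(read_expression_matrix(neg), "negative.*gB")

  dup <- tiny_expr_tsv(c("gene_id\tstem\tleaf\tflower\tsilique",
                         "gA\t1\t2\t3\t4", "gA\t0\t0\t5\t1"))
  expect_error(read_expression_matrix(dup), "duplicated.*gA")

  holes <- tiny_expr_tsv(c("gene_id\tstem\tleaf\tflower\tsilique",
                           "gA\t1\t\t3\t4", "gB\t0\t0\t5\t1"))
  expect_error(read_expression_matrix(holes), "missing.*gA")
})

test_that("tissue label selection enforces presence and order", {
  path <- tiny_expr_tsv(c("gene_id\tleaf\tstem", "gA\t1\t2"))
  m <- read_expression_matrix(path, tissue_labels = c("stem", "leaf"))
  expect_identical(colnames(m), c("stem", "leaf"))
  expect_identical(unname(unclass(m)[1, ]), c(2, 1))
  expect_error(read_expression_matrix(path, tissue_labels = c("stem", "flower")),
               "missing tissue")
})

test_that("GFF3 reader keeps gene records with GFF3 coordinates", {
  path <- tiny_gff3(c(
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=mrnaA;Parent=geneA",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=mrnaA",
    "chr2\tsrc\tgene\t50\t80\t.\t-\t.\tID=geneB"))
  g <- read_gff3_genes(path)
  expect_identical(nrow(g), 2L)
  expect_identical(g$gene_id, c("geneA", "geneB"))
  expect_identical(g$start, c(100L, 50L))
  expect_identical(g$end, c(400L, 80L))
  expect_identical(g$strand, c("+", "-"))
})

test_that("GFF3 reader returns empty for files without gene records", {
  path <- tiny_gff3("chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=m1")
  g <- read_gff3_genes(path)
  expect_identical(nrow(g), 0L)
})

test_that("GFF3 reader rejects strandless gene records", {
  path <- tiny_gff3("chr1\tsrc\tgene\t100\t400\t.\t.\t.\tID=geneA")
  expect_error(read_gff3_genes(path), "strand")
})

test_that("gene models round-trip through the GFF3 writer", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
                      start = c(10L, 5000L), end = c(900L, 6200L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_gff3_genes(genes, path)
  expect_identical(read_gff3_genes(path), genes)
})

test_that("methylation call reader validates and drops zero coverage", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tcontext\tn_methylated\tn_total",
               "chr1\t150\tCG\t3\t10",
               "chr1\t170\tCHH\t0\t0",
               "chr1\t190\tCHG\t5\t5"), path)
  expect_message(calls <- read_methylation_calls(path), "1 zero-coverage")
  expect_identical(nrow(calls), 2L)
  expect_identical(attr(calls, "n_dropped"), 1L)
  expect_equal(calls$n_methylated[1] / calls$n_total[1], 0.3)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tcontext\tn_methylated\tn_total",
               "chr1\t1\tCG\t5\t4"), bad)
  expect_error(read_methylation_calls(bad), "n_methylated \\(5\\) > n_total \\(4\\)")

  ctx <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tcontext\tn_methylated\tn_total",
               "chr1\t1\tXX\t1\t4"), ctx)
  expect_error(read_methylation_calls(ctx), "context")
})

test_that("bedGraph-style methylation input converts to counts", {
  df <- data.frame(chrom = "chr1", position = c(10L, 20L),
                   context = c("CG", "CG"), level = c(0.3, 1),
                   coverage = c(10L, 7L))
  calls <- methylation_from_bedgraph(df)
  expect_identical(calls$n_methylated, c(3L, 7L))
  expect_identical(calls$n_total, c(10L, 7L))
  df$level[1] <- 1.2
  expect_error(methylation_from_bedgraph(df), "\\[0, 1\\]")
})

test_that("pair tables validate duplication types and triple structure", {
  tr <- data.frame(ancestral_id = "a", parent_id = "p", child_id = "c",
                   dup_type = "WGD", stringsAsFactors = FALSE)
  expect_s3_class(pair_tables(duplicate_triples = tr), "pair_tables")
  tr$dup_type <- "XXX"
  expect_error(pair_tables(duplicate_triples = tr), "unknown duplication type")
  tr$dup_type <- "TD"
  tr$child_id <- "p"
  expect_error(pair_tables(duplicate_triples = tr), "identical parent and child")
})

test_that("count tables round-trip through long TSV and reject raggedness", {
  ct <- tiny_counts(matrix(1:6, 2), matrix(7:12, 2),
                    matrix(0:5, 2), matrix(2:7, 2))
  path <- tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- read_count_table(path)
  expect_identical(back$parentmix_A, ct$parentmix_A)
  expect_identical(back$allo_Cn, ct$allo_Cn)

  df <- utils::read.delim(path)
  df <- df[-1, ]  # drop one replicate observation
  ragged <- tempfile(fileext = ".tsv")
  write_tsv(df, ragged)
  expect_error(read_count_table(ragged), "unequal replication")

  expect_error(tiny_counts(c(1, -2), c(1, 1), c(1, 1), c(1, 1)),
               "non-negative integers")
})
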