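test_that("expression classes respect the stated cutpoints", {
  cls <- classify_expression(c(0.0005, 0.001, 5, 5.01, 50, 50.01, 0))
  expect_identical(as.character(cls),
                   c("non", "low", "low", "medium", "medium", "high", "non"))
  expect_error(classify_expression(-1), "non-negative")
})

test_that("region methylation pools coverage-weighted levels", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", position = c(1100L, 1500L),
                      context = "CG", n_methylated = c(3L, 7L),
                      n_total = c(10L, 10L), stringsAsFactors = FALSE)
  rm_ <- region_methylation(calls, genes, "gene_body", min_sites = 1)
  expect_equal(rm_$level, 0.5)   # (3+7)/(10+10)
  expect_identical(rm_$n_sites, 2L)

  # fully methylated sites give level 1
  calls$n_methylated <- calls$n_total
  expect_equal(region_methylation(calls, genes, "gene_body",
                                  min_sites = 1)$level, 1)

  # below min_sites the level is undefined
  expect_true(is.na(region_methylation(calls, genes, "gene_body",
                                       min_sites = 3)$level))
  expect_true(is.na(region_methylation(calls, genes, "downstream",
                                       min_sites = 1)$level))
})

test_that("promoter and downstream regions are strand-aware", {
  genes <- data.frame(gene_id = "gm", chrom = "chr1", start = 5000L,
                      end = 6000L, strand = "-", stringsAsFactors = FALSE)
  upstream_call <- data.frame(chrom = "chr1", position = 6500L, context = "CG",
                              n_methylated = 4L, n_total = 5L,
                              stringsAsFactors = FALSE)
  downstream_call <- data.frame(chrom = "chr1", position = 4500L, context = "CG",
                                n_methylated = 1L, n_total = 5L,
                                stringsAsFactors = FALSE)
  # minus strand: the promoter lies at coordinates greater than the TES
  expect_identical(region_methylation(upstream_call, genes, "promoter",
                                      min_sites = 1)$n_sites, 1L)
  expect_identical(region_methylation(upstream_call, genes, "downstream",
                                      min_sites = 1)$n_sites, 0L)
  expect_identical(region_methylation(downstream_call, genes, "downstream",
                                      min_sites = 1)$n_sites, 1L)
})

test_that("regions running past the chromosome start are truncated", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 500L,
                      end = 1500L, strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", position = c(10L, 400L), context = "CG",
                      n_methylated = c(2L, 2L), n_total = c(4L, 4L),
                      stringsAsFactors = FALSE)
  expect_message(
    rm_ <- region_methylation(calls, genes, "promoter", min_sites = 1),
    "truncated")
  expect_identical(rm_$n_sites, 2L)  # both calls fall in [1, 499]
})

test_that("context filtering restricts the pooled sites", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1L,
                      end = 100L, strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", position = c(10L, 20L, 30L),
                      context = c("CG", "CHG", "CHH"),
                      n_methylated = c(5L, 0L, 0L), n_total = c(5L, 5L, 5L),
                      stringsAsFactors = FALSE)
  expect_equal(region_methylation(calls, genes, "gene_body", context = "CG",
                                  min_sites = 1)$level, 1)
  expect_equal(region_methylation(calls, genes, "gene_body", context = "all",
                                  min_sites = 1)$level, 1 / 3)
})

test_that("uniform methylation yields flat meta-gene profiles", {
  sim <- simulate_methylome(71, n_genes = 40, genome_length = 4e5,
                            flank_level = 0.5,
                            body_levels = c(non = 0.5, low = 0.5,
                                            medium = 0.5, high = 0.5),
                            coverage = 400)
  classes <- classify_expression(sim$fpkm)
  prof <- metagene_profile(sim$calls, sim$genes, classes)
  filled <- prof[!is.na(prof$level), ]
  expect_true(all(abs(filled$level - 0.5) < 0.05))
  expect_true(all(filled$level >= 0 & filled$level <= 1))
  expect_identical(nrow(prof), 80L * 4L)
})

test_that("meta-gene profiles are invariant under genome mirroring", {
  sim <- simulate_methylome(72, n_genes = 60, genome_length = 5e5)
  classes <- classify_expression(sim$fpkm)
  prof <- metagene_profile(sim$calls, sim$genes, classes)
  mir <- mirror_methylome(sim$genes, sim$calls)
  prof_m <- metagene_profile(mir$calls, mir$genes, classes)
  expect_equal(prof$level, prof_m$level)
  expect_identical(prof$n_genes, prof_m$n_genes)
})

test_that("genes too short for the body bins are excluded with a count", {
  genes <- data.frame(gene_id = c("gShort", "gLong"), chrom = "chr1",
                      start = c(3000L, 10000L), end = c(3010L, 12000L),
                      strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", position = c(3005L, 11000L),
                      context = "CG", n_methylated = c(1L, 1L),
                      n_total = c(2L, 2L), stringsAsFactors = FALSE)
  classes <- stats::setNames(factor(c("low", "low"),
                                    levels = expression_classes),
                             genes$gene_id)
  expect_message(prof <- metagene_profile(calls, genes, classes),
                 "no genes in expression class")
  expect_identical(attr(prof, "n_excluded_short"), 1L)
})

test_that("methylation-expression association flags degenerate groups", {
  rl <- data.frame(gene_id = c("a", "b", "c"), region = "gene_body",
                   context = "all", level = c(0.5, 0.5, 0.5),
                   n_sites = 5L, stringsAsFactors = FALSE)
  fpkm <- c(a = 1, b = 10, c = 100)
  out <- methylation_expression_association(rl, fpkm)
  expect_true(is.na(out$r))
  expect_match(out$note, "zero variance")
  rl$level <- c(0.9, 0.5, 0.1)
  out2 <- methylation_expression_association(rl, fpkm)
  expect_lt(out2$r, 0)
})

test_that("region levels equal the pooled sums and are split-merge stable", {
  sim <- simulate_methylome(73, n_genes = 20, genome_length = 2e5)
  whole <- region_methylation(sim$calls, sim$genes, "gene_body")
  # independent recomputation of the coverage-weighted pool per gene
  manual <- vapply(seq_len(nrow(sim$genes)), function(i) {
    g <- sim$genes[i, ]
    inside <- sim$calls$position >= g$start & sim$calls$position <= g$end
    sum(sim$calls$n_methylated[inside]) / sum(sim$calls$n_total[inside])
  }, numeric(1))
  expect_equal(whole$level, manual)
  # splitting the call file in two conserves the pooled site counts
  half <- seq_len(nrow(sim$calls)) %% 2 == 0
  a <- region_methylation(sim$calls[half, ], sim$genes, "gene_body",
                          min_sites = 0)
  b <- region_methylation(sim$calls[!half, ], sim$genes, "gene_body",
                          min_sites = 0)
  expect_identical(a$n_sites + b$n_sites, whole$n_sites)
})
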