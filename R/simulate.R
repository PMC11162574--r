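## ---------------------------------------------------------------------------
## Synthetic-data generators. Each takes an explicit seed, draws everything
## from that seed (fixed seed => bitwise-identical output), and returns a
## machine-readable truth table aligned by id with the dataset it emits.
## ---------------------------------------------------------------------------

#' Simulate expression matrices and duplicate triples with planted fates
#'
#' Emulates the two-genome study design: a reference genome carrying the
#' ancestral genes and one side of the single-copy ortholog pairs, and a
#' duplicate-bearing genome carrying parent/child copies and the other
#' ortholog side, each profiled over four tissues.
#'
#' Log2-scale generative model: every gene has a baseline profile drawn
#' uniformly per tissue from `baseline_range`. Single-copy orthologs
#' accumulate independent Gaussian drift of SD `noise_sd` along each of the
#' two lineages, so their interspecies divergence (which calibrates E_div)
#' has SD `noise_sd * sqrt(2)` per tissue. Duplicate copies are drawn
#' around the measured ancestral profile according to their planted fate:
#' copies whose ancestral expression role is retained (both conserved
#' copies, the non-diverged neofunctionalization copy, and the
#' subfunctionalized split halves) drift with SD
#' `noise_sd * conserved_noise_factor`, modelling stabilizing selection on
#' retained-function copies; diverged copies carry full `noise_sd` drift
#' plus a `divergence_offset` shift in a random 1-3 tissue subset.
#' Subfunctionalized copies split the ancestral raw-scale profile over
#' complementary tissue subsets, so at zero noise their raw sum equals the
#' ancestor exactly.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_single Number of single-copy ortholog pairs (default 2000).
#' @param n_per_fate Triples planted per fate (default 100; the
#'   neofunctionalized quota is split between parent- and child-diverged).
#' @param noise_sd Per-tissue, per-lineage log2 drift SD (default 0.25).
#' @param divergence_offset Log2 shift applied to diverged copies
#'   (default 1.5).
#' @param conserved_noise_factor Multiplier on `noise_sd` for
#'   retained-function copies (default 0.5).
#' @param baseline_range Uniform range of baseline log2 expression
#'   (default 2-8).
#' @param tissues Tissue labels (default stem, leaf, flower, silique).
#' @param null_mode If `TRUE`, all duplicates are simulated to behave
#'   exactly like single-copy genes (independent full-drift copies; no
#'   offsets, no stabilizing selection) for null-calibration checks.
#' @return List: `expr_ref` and `expr_dup` (raw-scale
#'   [expression_matrix()]), `pairs` (a [pair_tables()] including a
#'   plausible Ka/Ks table keyed by child id), `truth` (data frame
#'   `child_id`, `fate_planted`).
#' @export
simulate_fate_dataset <- function(seed, n_single = 2000, n_per_fate = 100,
                                  noise_sd = 0.25, divergence_offset = 1.5,
                                  conserved_noise_factor = 0.5,
                                  baseline_range = c(2, 8),
                                  tissues = c("stem", "leaf", "flower", "silique"),
                                  null_mode = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && divergence_offset <= noise_sd) {
    warning("divergence_offset <= noise_sd: planted-fate recovery not guaranteed")
  }
  nt <- length(tissues)
  drift <- function(n, sd) matrix(stats::rnorm(n * nt, 0, sd), n, nt)
  sigma_c <- noise_sd * conserved_noise_factor

  ## single-copy ortholog pairs: two independent lineage drifts
  base_s <- matrix(stats::runif(n_single * nt, baseline_range[1], baseline_range[2]),
                   n_single, nt)
  s1 <- pmax(base_s + drift(n_single, noise_sd), 0)
  s2 <- pmax(base_s + drift(n_single, noise_sd), 0)

  n_tr <- 4L * n_per_fate
  anc <- matrix(stats::runif(n_tr * nt, baseline_range[1], baseline_range[2]),
                n_tr, nt)
  par_log <- chd_log <- matrix(0, n_tr, nt)
  fate_planted <- character(n_tr)

  ## random tissue subset of size 1..(nt-1) as a logical mask
  rand_mask <- function() {
    k <- sample(seq_len(nt - 1), 1)
    m <- rep(FALSE, nt)
    m[sample(nt, k)] <- TRUE
    m
  }
  shift_subset <- function(profile) {
    m <- rand_mask()
    dir <- sample(c(-1, 1), nt, replace = TRUE)
    profile + ifelse(m, dir * divergence_offset, 0)
  }

  for (i in seq_len(n_tr)) {
    fate_i <- (i - 1L) %/% n_per_fate + 1L
    a <- anc[i, ]
    if (null_mode) {
      ## duplicates indistinguishable from single-copy genes: their
      ## divergence from the measured ancestral profile spans two lineage
      ## branches, like a single-copy interspecies comparison (SD sqrt(2)*sd)
      p <- a + stats::rnorm(nt, 0, noise_sd * sqrt(2))
      cdl <- a + stats::rnorm(nt, 0, noise_sd * sqrt(2))
      fate_planted[i] <- "null"
    } else if (fate_i == 1L) {
      p <- a + stats::rnorm(nt, 0, sigma_c)
      cdl <- a + stats::rnorm(nt, 0, sigma_c)
      fate_planted[i] <- "conserved"
    } else if (fate_i == 2L) {
      diverged_parent <- i %% 2L == 0L
      kept <- a + stats::rnorm(nt, 0, sigma_c)
      div <- shift_subset(a + stats::rnorm(nt, 0, noise_sd))
      if (diverged_parent) {
        p <- div; cdl <- kept
        fate_planted[i] <- "neofunctionalized(parent)"
      } else {
        p <- kept; cdl <- div
        fate_planted[i] <- "neofunctionalized(child)"
      }
    } else if (fate_i == 3L) {
      m <- rand_mask()
      a_raw <- 2^a - 1
      p <- log2(a_raw * m + 1) + stats::rnorm(nt, 0, sigma_c)
      cdl <- log2(a_raw * (!m) + 1) + stats::rnorm(nt, 0, sigma_c)
      fate_planted[i] <- "subfunctionalized"
    } else {
      p <- shift_subset(a + stats::rnorm(nt, 0, noise_sd))
      cdl <- shift_subset(a + stats::rnorm(nt, 0, noise_sd))
      fate_planted[i] <- "specialized"
    }
    par_log[i, ] <- pmax(p, 0)
    chd_log[i, ] <- pmax(cdl, 0)
  }

  id <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  s1_ids <- id("S1_", n_single)
  s2_ids <- id("S2_", n_single)
  anc_ids <- id("ANC", n_tr)
  par_ids <- id("PAR", n_tr)
  chd_ids <- id("CHD", n_tr)

  to_raw <- function(m) 2^m - 1
  ref_vals <- rbind(to_raw(s1), to_raw(anc))
  rownames(ref_vals) <- c(s1_ids, anc_ids)
  colnames(ref_vals) <- tissues
  dup_vals <- rbind(to_raw(s2), to_raw(par_log), to_raw(chd_log))
  rownames(dup_vals) <- c(s2_ids, par_ids, chd_ids)
  colnames(dup_vals) <- tissues

  ks <- ifelse(stats::runif(n_tr) < 0.95,
               stats::runif(n_tr, 0.05, 2.5), stats::runif(n_tr, 3, 4))
  ka <- ks * stats::runif(n_tr, 0.05, 0.8)
  pairs <- pair_tables(
    ortholog_pairs = data.frame(gene_s1 = s1_ids, gene_s2 = s2_ids,
                                stringsAsFactors = FALSE),
    duplicate_triples = data.frame(ancestral_id = anc_ids, parent_id = par_ids,
                                   child_id = chd_ids,
                                   dup_type = rep_len(dup_types, n_tr),
                                   stringsAsFactors = FALSE),
    kaks = data.frame(id = chd_ids, ka = ka, ks = ks, kaks = ka / ks,
                      stringsAsFactors = FALSE))
  list(expr_ref = expression_matrix(ref_vals, "raw"),
       expr_dup = expression_matrix(dup_vals, "raw"),
       pairs = pairs,
       truth = data.frame(child_id = chd_ids, fate_planted = fate_planted,
                          stringsAsFactors = FALSE))
}

#' Simulate divergence records with planted correlations
#'
#' Generates per-duplicate records (expression divergence, Ka, Ks, Ka/Ks,
#' tau) whose population Pearson correlation between divergence and each
#' covariate equals the planted value: each covariate is built as
#' `rho*z + sqrt(1 - rho^2)*noise` on a shared latent divergence driver
#' `z`, then moved onto its natural scale by an affine map (which leaves
#' Pearson correlation untouched, up to rare boundary clamping).
#'
#' @param seed Integer RNG seed.
#' @param n Number of records (default 2000).
#' @param r_tau,r_ka,r_ks,r_kaks Planted correlations of expression
#'   divergence with each covariate (defaults 0.8, 0.45, 0.14, 0.40).
#' @return Data frame `id`, `divergence`, `ka`, `ks`, `kaks`, `tau` with
#'   attribute `planted` (the four correlations).
#' @export
simulate_divergence_records <- function(seed, n = 2000, r_tau = 0.8,
                                        r_ka = 0.45, r_ks = 0.14,
                                        r_kaks = 0.40) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  z <- stats::rnorm(n)
  mix <- function(r) r * z + sqrt(1 - r^2) * stats::rnorm(n)
  df <- data.frame(
    id = sprintf("REC%05d", seq_len(n)),
    divergence = pmax(0, 1.5 + 0.45 * z),
    ka = pmax(0.001, 0.30 + 0.10 * mix(r_ka)),
    ks = pmax(0.010, 1.20 + 0.35 * mix(r_ks)),
    kaks = pmax(0.001, 0.35 + 0.10 * mix(r_kaks)),
    tau = pmin(1, pmax(0, 0.5 + 0.14 * mix(r_tau))),
    stringsAsFactors = FALSE)
  attr(df, "planted") <- c(tau = r_tau, ka = r_ka, ks = r_ks, kaks = r_kaks)
  df
}

#' Simulate homoeolog count tables with planted cis/trans categories
#'
#' Negative-binomial replicate counts for homoeolog pairs in the
#' progenitor mix and the allopolyploid, with per-pair planted cis and
#' trans log2 effects. The progenitor-mix ratio carries cis + trans, the
#' allopolyploid ratio carries cis only, so the planted category follows
#' from the regulatory-category rules: I (cis only): cis != 0, trans = 0;
#' II (trans only): cis = 0, trans != 0; III (enhancing): both, same
#' direction; IV (opposing): trans = -(cis + e) so A and B disagree in
#' sign; V (compensatory): trans = -cis exactly; VI: both zero. Effect
#' magnitudes are drawn uniformly from `effect_range`.
#'
#' @param seed Integer RNG seed.
#' @param n_pairs Number of homoeolog pairs (default 1000).
#' @param categories Categories to plant, cycled equally (default I-VI).
#' @param effect_range Range of |log2 effect| magnitudes (default 1.5-3).
#' @param dispersion NB dispersion (default 0.05); 0 gives Poisson counts.
#' @param n_reps Replicates per compartment (default 3).
#' @param library_size Expected reads per replicate library (default 1e6).
#' @param expr_sd Log-normal SD of relative pair abundances (default 0.7).
#' @param noiseless If `TRUE`, counts are the rounded expected values
#'   (deterministic limit: no sampling noise at all).
#' @return List: `counts` (a [count_table()]), `truth` (data frame
#'   `pair_id`, `cis`, `trans`, `category`).
#' @export
simulate_count_dataset <- function(seed, n_pairs = 1000,
                                   categories = c("I", "II", "III", "IV", "V", "VI"),
                                   effect_range = c(1.5, 3), dispersion = 0.05,
                                   n_reps = 3, library_size = 1e6,
                                   expr_sd = 0.7, noiseless = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  category <- sample(rep_len(categories, n_pairs))
  e1 <- stats::runif(n_pairs, effect_range[1], effect_range[2])
  e2 <- stats::runif(n_pairs, effect_range[1], effect_range[2])
  s <- sample(c(-1, 1), n_pairs, replace = TRUE)
  cis <- trans <- numeric(n_pairs)
  set_eff <- function(cat, cis_v, trans_v) {
    i <- category == cat
    cis[i] <<- cis_v[i]
    trans[i] <<- trans_v[i]
  }
  zero <- numeric(n_pairs)
  set_eff("I", s * e1, zero)
  set_eff("II", zero, s * e1)
  set_eff("III", s * e1, s * e2)
  set_eff("IV", s * e1, -s * (e1 + e2))
  set_eff("V", s * e1, -s * e1)
  set_eff("VI", zero, zero)

  a_true <- cis + trans
  b_true <- cis
  w <- exp(stats::rnorm(n_pairs, 0, expr_sd))
  w <- w / sum(w)
  mu <- list(parentmix_A = library_size * w * 2^(a_true / 2),
             parentmix_C = library_size * w * 2^(-a_true / 2),
             allo_An = library_size * w * 2^(b_true / 2),
             allo_Cn = library_size * w * 2^(-b_true / 2))
  ids <- sprintf("HP%05d", seq_len(n_pairs))
  draw <- function(m) {
    out <- if (noiseless) {
      matrix(round(m), n_pairs, n_reps)
    } else if (dispersion == 0) {
      matrix(stats::rpois(n_pairs * n_reps, rep(m, n_reps)), n_pairs, n_reps)
    } else {
      matrix(stats::rnbinom(n_pairs * n_reps, mu = rep(m, n_reps),
                            size = 1 / dispersion), n_pairs, n_reps)
    }
    rownames(out) <- ids
    out
  }
  ct <- count_table(draw(mu$parentmix_A), draw(mu$parentmix_C),
                    draw(mu$allo_An), draw(mu$allo_Cn))
  list(counts = ct,
       truth = data.frame(pair_id = ids, cis = cis, trans = trans,
                          category = category, stringsAsFactors = FALSE))
}

#' Simulate a methylome with a planted meta-gene landscape
#'
#' Places non-overlapping gene loci (2 kb flank + body + 2 kb flank, plus a
#' gap) alternately on both strands of a linear genome, assigns each gene
#' an expression class and a class-consistent FPKM, and emits binomial
#' methylation calls at evenly spaced cytosines: flank cytosines methylated
#' at `flank_level`, gene-body cytosines at the planted per-class body
#' level.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes (default 500).
#' @param genome_length Genome length in bp (default 4e6); an error is
#'   raised if the requested loci do not fit.
#' @param gene_length_range Gene body length range in bp (default
#'   800-1600).
#' @param site_spacing Distance between simulated cytosines (default 20 bp).
#' @param coverage Reads per cytosine (default 20).
#' @param flank Flank width (default 2000 bp).
#' @param flank_level Methylation probability in flanks (default 0.8).
#' @param body_levels Named per-class body methylation probabilities
#'   (default decreasing with expression: non 0.5, low 0.35, medium 0.2,
#'   high 0.05).
#' @param gap Unsimulated spacer between loci (default 200 bp).
#' @return List: `genes` (gene-model data frame), `calls` (methylation-call
#'   data frame), `fpkm` (named vector), `truth` (list with `flank_level`,
#'   `body_levels`, per-gene `class`).
#' @export
simulate_methylome <- function(seed, n_genes = 500, genome_length = 4e6,
                               gene_length_range = c(800, 1600),
                               site_spacing = 20, coverage = 20, flank = 2000,
                               flank_level = 0.8,
                               body_levels = c(non = 0.5, low = 0.35,
                                               medium = 0.2, high = 0.05),
                               gap = 200) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (!identical(sort(names(body_levels)), sort(expression_classes))) {
    stop("body_levels must be named by the four expression classes")
  }
  if (any(c(body_levels, flank_level) < 0 | c(body_levels, flank_level) > 1)) {
    stop("methylation levels must lie in [0, 1]")
  }
  len <- round(stats::runif(n_genes, gene_length_range[1], gene_length_range[2]))
  slot <- flank + len + flank + gap
  slot_end <- cumsum(slot)
  if (slot_end[n_genes] > genome_length) {
    stop(sprintf("genome_length %g too short for %d gene loci (need %g bp)",
                 genome_length, n_genes, slot_end[n_genes]))
  }
  start <- slot_end - slot + flank + 1
  end <- start + len - 1
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = "chr1", start = as.integer(start),
                      end = as.integer(end),
                      strand = rep_len(c("+", "-"), n_genes),
                      stringsAsFactors = FALSE)
  cls <- sample(expression_classes, n_genes, replace = TRUE)
  fpkm <- numeric(n_genes)
  fpkm[cls == "non"] <- stats::runif(sum(cls == "non"), 0, 0.0009)
  fpkm[cls == "low"] <- stats::runif(sum(cls == "low"), 0.001, 5)
  fpkm[cls == "medium"] <- stats::runif(sum(cls == "medium"), 5.01, 50)
  fpkm[cls == "high"] <- stats::runif(sum(cls == "high"), 50.01, 500)
  names(fpkm) <- genes$gene_id

  call_list <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    pos <- seq.int(start[i] - flank, end[i] + flank, by = site_spacing)
    p <- ifelse(pos >= start[i] & pos <= end[i],
                body_levels[[cls[i]]], flank_level)
    call_list[[i]] <- data.frame(
      chrom = "chr1", position = as.integer(pos),
      context = rep_len(meth_contexts, length(pos)),
      n_methylated = stats::rbinom(length(pos), coverage, p),
      n_total = coverage, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, call_list)
  rownames(calls) <- NULL
  list(genes = genes, calls = calls, fpkm = fpkm,
       truth = list(flank_level = flank_level, body_levels = body_levels,
                    class = stats::setNames(factor(cls, expression_classes),
                                            genes$gene_id)))
}

#' Simulate gene-body methylation anticorrelated with expression
#'
#' Per-gene continuous gene-body methylation probabilities built jointly
#' with log2(FPKM + 1) from a bivariate-normal driver so their population
#' Pearson correlation equals the planted `r` (binomial call noise at the
#' given coverage attenuates the measured correlation only marginally).
#' Emits gene-body cytosine calls only.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes (default 1000).
#' @param r Planted correlation between body methylation level and
#'   log2(FPKM + 1) (default -0.5).
#' @param gene_length,site_spacing,coverage,gap Geometry and depth
#'   parameters.
#' @return List: `genes`, `calls`, `fpkm`, `truth` (list with `r` and the
#'   per-gene planted `p_body`).
#' @export
simulate_gbm_dataset <- function(seed, n_genes = 1000, r = -0.5,
                                 gene_length = 1000, site_spacing = 20,
                                 coverage = 20, gap = 500) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  z1 <- stats::rnorm(n_genes)
  z2 <- stats::rnorm(n_genes)
  logfpkm <- pmax(0, 3 + 1 * z1)
  fpkm <- 2^logfpkm - 1
  mix <- r * z1 + sqrt(1 - r^2) * z2
  p_body <- pmin(0.98, pmax(0.02, 0.45 + 0.1 * mix))
  slot <- gene_length + gap
  start <- (seq_len(n_genes) - 1L) * slot + 1L
  end <- start + gene_length - 1L
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = "chr1", start = as.integer(start),
                      end = as.integer(end),
                      strand = rep_len(c("+", "-"), n_genes),
                      stringsAsFactors = FALSE)
  names(fpkm) <- genes$gene_id
  call_list <- lapply(seq_len(n_genes), function(i) {
    pos <- seq.int(start[i], end[i], by = site_spacing)
    data.frame(chrom = "chr1", position = as.integer(pos),
               context = rep_len(meth_contexts, length(pos)),
               n_methylated = stats::rbinom(length(pos), coverage, p_body[i]),
               n_total = coverage, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, call_list)
  rownames(calls) <- NULL
  list(genes = genes, calls = calls, fpkm = fpkm,
       truth = list(r = r, p_body = stats::setNames(p_body, genes$gene_id)))
}

#' Simulate transmission test tables with planted patterns
#'
#' Draws each homoeolog pair's pattern from the supplied 3 x 3 pattern
#' frequency distribution, then constructs q-value/direction inputs that
#' realize the parental and progeny bias states deterministically
#' (balanced states get q uniformly above `alpha`, biased states q below
#' it with the matching sign).
#'
#' @param seed Integer RNG seed.
#' @param n_pairs Number of pairs (default 10000).
#' @param pattern_freqs Named frequencies over patterns I-IX; must sum to
#'   1. The default is a parental-legacy-heavy mix (group A 86%, balanced
#'   maintenance about 97%) with reversal patterns VIII/IX rarest.
#' @param alpha Significance threshold the inputs are built against
#'   (default 0.05).
#' @return List: `parental` and `progeny` (data frames `pair_id`, `q`,
#'   `sign`), `truth` (data frame `pair_id`, `pattern`, `group`).
#' @export
simulate_transmission <- function(seed, n_pairs = 10000,
                                  pattern_freqs = c(I = 0.11, II = 0.64,
                                                    III = 0.11, IV = 0.055,
                                                    V = 0.055, VI = 0.01,
                                                    VII = 0.01, VIII = 0.005,
                                                    IX = 0.005),
                                  alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (!identical(sort(names(pattern_freqs)), sort(transmission_patterns$pattern))) {
    stop("pattern_freqs must be named by patterns I..IX")
  }
  if (abs(sum(pattern_freqs) - 1) > 1e-8) {
    stop("pattern frequencies must sum to 1")
  }
  pat <- sample(names(pattern_freqs), n_pairs, replace = TRUE,
                prob = pattern_freqs)
  idx <- match(pat, transmission_patterns$pattern)
  ids <- sprintf("TP%05d", seq_len(n_pairs))
  realize <- function(states) {
    eq <- states == "A_eq_C"
    data.frame(pair_id = ids,
               q = ifelse(eq, stats::runif(n_pairs, alpha, 1),
                          stats::runif(n_pairs, 0, alpha * 0.98)),
               sign = ifelse(states == "A_gt_C", 1,
                             ifelse(states == "A_lt_C", -1, 0)),
               stringsAsFactors = FALSE)
  }
  list(parental = realize(transmission_patterns$parental[idx]),
       progeny = realize(transmission_patterns$progeny[idx]),
       truth = data.frame(pair_id = ids, pattern = pat,
                          group = transmission_patterns$group[idx],
                          stringsAsFactors = FALSE))
}
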