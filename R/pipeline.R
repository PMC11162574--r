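#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one place. `run_all()` merges a user
#' config (list or YAML file) over these defaults and rejects unknown
#' keys. The `sim` block controls the synthetic datasets the demonstration
#' pipeline generates.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    outdir = "allodup_out",
    q_ediv = 0.9,
    fdr_alpha = 0.05,
    pseudocount = 0.5,
    lib_norm = TRUE,
    low_expr_threshold = 1,
    max_ks = 3,
    min_sites = 3,
    n_body_bins = 40,
    flank_bin_width = 100,
    flank = 2000,
    bias_alpha = 0.05,
    sim = list(
      n_single = 2000,
      n_per_fate = 100,
      noise_sd = 0.25,
      divergence_offset = 1.5,
      conserved_noise_factor = 0.5,
      n_count_pairs = 1000,
      dispersion = 0.05,
      n_reps = 3,
      n_meth_genes = 500,
      meth_genome_length = 4e6,
      n_transmission = 10000
    )
  )
}

merge_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$sim)) {
    unknown <- setdiff(names(config$sim), names(def$sim))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste0("sim.", unknown, collapse = ", "))
    }
    def$sim[names(config$sim)] <- config$sim
    config$sim <- NULL
  }
  def[names(config)] <- config
  def
}

#' Run the complete analysis pipeline on simulated data
#'
#' Generates every input with planted truth, runs all five analysis stages
#' (preprocessing + fate classification, divergence correlations, cis/trans
#' category calling, methylation profiling, transmission classification),
#' and writes each stage's tables as TSV plus a JSON run manifest recording
#' the resolved configuration, seeds, E_div and filter counts. Given the
#' same seed and config the output files are byte-identical across runs.
#'
#' @param config Named list of overrides over [default_config()], or the
#'   path to a YAML file of them. Unknown keys are rejected by name.
#' @return Invisibly, a list with the stage results and the output paths.
#' @export
run_all <- function(config = list()) {
  cfg <- merge_config(config)
  outdir <- cfg$outdir
  indir <- file.path(outdir, "inputs")
  dir.create(indir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    paths[length(paths) + 1] <<- p
    p
  }

  ## ---- stage 1: expression, preprocessing, fate classification ----
  sim_fate <- simulate_fate_dataset(
    cfg$seed, n_single = cfg$sim$n_single, n_per_fate = cfg$sim$n_per_fate,
    noise_sd = cfg$sim$noise_sd, divergence_offset = cfg$sim$divergence_offset,
    conserved_noise_factor = cfg$sim$conserved_noise_factor)
  write_expression_matrix(sim_fate$expr_ref, file.path(indir, "expression_ref.tsv"))
  write_expression_matrix(sim_fate$expr_dup, file.path(indir, "expression_dup.tsv"))
  write_tsv(sim_fate$pairs$ortholog_pairs, file.path(indir, "ortholog_pairs.tsv"))
  write_tsv(sim_fate$pairs$duplicate_triples, file.path(indir, "duplicate_triples.tsv"))
  write_tsv(sim_fate$pairs$kaks, file.path(indir, "kaks.tsv"))
  write_tsv(sim_fate$truth, file.path(indir, "truth_fates.tsv"))

  ref_log <- log_transform(sim_fate$expr_ref)
  dup_log <- log_transform(sim_fate$expr_dup)
  flt_ref <- filter_low_expression(ref_log, cfg$low_expr_threshold)
  flt_dup <- filter_low_expression(dup_log, cfg$low_expr_threshold)
  flt_ks <- filter_ks(sim_fate$pairs, cfg$max_ks)
  complete <- drop_incomplete_triples(flt_ks$pairs,
                                      rownames(flt_ref$matrix),
                                      rownames(flt_dup$matrix))
  fate_res <- fate_analysis(flt_ref$matrix, flt_dup$matrix, complete$pairs,
                            q = cfg$q_ediv)
  emit(fate_res$calls, "fate_calls.tsv")
  ft <- fate_by_dup_type(fate_res)
  emit(as.data.frame(ft$counts, stringsAsFactors = FALSE), "fate_by_dup_type.tsv")

  ## ---- stage 2: divergence vs Ka/Ks/tau correlations ----
  kk <- complete$pairs$kaks
  calls <- fate_res$calls
  ki <- match(calls$child_id, kk$id)
  records <- data.frame(
    id = calls$child_id,
    divergence = calls$e_child,
    ka = kk$ka[ki], ks = kk$ks[ki], kaks = kk$kaks[ki],
    tau = tau(flt_dup$matrix[calls$child_id, , drop = FALSE]),
    stringsAsFactors = FALSE)
  corr <- correlate_divergence(records)
  emit(corr, "divergence_correlations.tsv")

  ## ---- stage 3: cis/trans regulatory categories ----
  sim_ct <- simulate_count_dataset(
    cfg$seed + 1L, n_pairs = cfg$sim$n_count_pairs,
    dispersion = cfg$sim$dispersion, n_reps = cfg$sim$n_reps)
  write_count_table(sim_ct$counts, file.path(indir, "homoeolog_counts.tsv"))
  write_tsv(sim_ct$truth, file.path(indir, "truth_cis_trans.tsv"))
  ct_calls <- call_cis_trans(sim_ct$counts, pseudocount = cfg$pseudocount,
                             lib_norm = cfg$lib_norm,
                             fdr_alpha = cfg$fdr_alpha)
  emit(ct_calls, "cis_trans_calls.tsv")
  emit(category_summary(ct_calls), "cis_trans_summary.tsv")

  ## ---- stage 4: methylation profiles ----
  sim_me <- simulate_methylome(
    cfg$seed + 2L, n_genes = cfg$sim$n_meth_genes,
    genome_length = cfg$sim$meth_genome_length,
    flank = cfg$flank)
  write_gff3_genes(sim_me$genes, file.path(indir, "genes.gff3"))
  write_methylation_calls(sim_me$calls, file.path(indir, "methylation_calls.tsv"))
  classes <- classify_expression(sim_me$fpkm)
  regions <- do.call(rbind, lapply(c("promoter", "gene_body", "downstream"),
                                   function(rg) {
    region_methylation(sim_me$calls, sim_me$genes, region = rg,
                       context = "all", min_sites = cfg$min_sites,
                       flank = cfg$flank)
  }))
  emit(regions, "region_methylation.tsv")
  prof <- metagene_profile(sim_me$calls, sim_me$genes, classes,
                           n_body_bins = cfg$n_body_bins,
                           flank_bin_width = cfg$flank_bin_width,
                           flank = cfg$flank)
  emit(prof, "metagene_profile.tsv")
  assoc <- methylation_expression_association(regions, sim_me$fpkm)
  emit(assoc, "methylation_expression.tsv")

  ## ---- stage 5: generational transmission ----
  sim_tr <- simulate_transmission(cfg$seed + 3L,
                                  n_pairs = cfg$sim$n_transmission,
                                  alpha = cfg$bias_alpha)
  write_tsv(sim_tr$parental, file.path(indir, "transmission_parental.tsv"))
  write_tsv(sim_tr$progeny, file.path(indir, "transmission_progeny.tsv"))
  write_tsv(sim_tr$truth, file.path(indir, "truth_transmission.tsv"))
  par_state <- bias_state(sim_tr$parental$q, sim_tr$parental$sign, cfg$bias_alpha)
  pro_state <- bias_state(sim_tr$progeny$q, sim_tr$progeny$sign, cfg$bias_alpha)
  rec <- assign_pattern(par_state, pro_state, pair_id = sim_tr$parental$pair_id)
  emit(rec, "transmission_records.tsv")
  tsum <- transmission_summary(rec)
  emit(cbind(tsum$patterns,
             group = transmission_patterns$group[
               match(tsum$patterns$pattern, transmission_patterns$pattern)]),
       "transmission_summary.tsv")

  ## ---- manifest ----
  ## outdir is where the run lives, not an analysis parameter: leaving it
  ## out keeps manifests byte-identical across same-seed runs anywhere
  cfg_rec <- cfg
  cfg_rec$outdir <- NULL
  manifest <- list(
    package = "allodup",
    version = as.character(utils::packageVersion("allodup")),
    seed = cfg$seed,
    config = cfg_rec,
    e_div = fate_res$e_div,
    q_ediv = fate_res$q,
    dispersion_estimate = attr(ct_calls, "dispersion"),
    filters = list(
      low_expression_ref_removed = flt_ref$report$n_removed,
      low_expression_dup_removed = flt_dup$report$n_removed,
      ks_removed = flt_ks$report$n_removed,
      incomplete_triples_dropped = complete$n_triples_dropped,
      incomplete_orthologs_dropped = complete$n_orthologs_dropped
    ),
    n = list(
      triples_classified = nrow(fate_res$calls),
      count_pairs = nrow(ct_calls),
      methylation_genes = nrow(sim_me$genes),
      transmission_pairs = nrow(rec)
    )
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths[length(paths) + 1] <- manifest_path

  invisible(list(config = cfg, paths = paths, fate = fate_res,
                 correlations = corr, cis_trans = ct_calls,
                 metagene = prof, region_methylation = regions,
                 methylation_association = assoc,
                 transmission = tsum, manifest = manifest))
}
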