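# End-to-end orchestration: synthetic generation -> depth harmonization ->
# propensity-weighted comparison -> germline analyses -> association tests,
# with every intermediate table written to disk and a manifest that makes
# the run reproducible from the configuration alone.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' caller agreement (2), consensus 8 of 10 downsampling iterations, 10%
#' depth-balance and covariate-balance targets, FDR 0.1, 100 label
#' permutations, 36-month survival cap, and the germline-SNP thresholds
#' (3 off-target reads for carrier inference, coverage 8 and base quality
#' 15 for the clustering matrix).
#'
#' @param n_caucasian,n_vietnamese,n_chinese Cohort sizes of the synthetic
#'   scenario.
#' @param n_background_genes,background_rate Null-gene count and mutation
#'   rate.
#' @param min_callers Minimum caller agreement.
#' @param n_iterations,min_times Downsampling iterations and consensus
#'   threshold.
#' @param balance_threshold Standardized-difference balance target (%).
#' @param min_freq Gene frequency floor for testing.
#' @param fdr_threshold FDR cutoff for biased genes.
#' @param n_perm Label permutations (0 skips the permutation stage).
#' @param survival_cap_months Follow-up cap for survival analysis.
#' @param snp_min_reads Minimum off-target reads for carrier inference.
#' @param snp_min_coverage,min_base_quality Clustering-matrix filters.
#' @param base_seed Base seed; stage seeds are derived as small fixed
#'   offsets.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_caucasian = 250, n_vietnamese = 125,
                       n_chinese = 125,
                       n_background_genes = 60, background_rate = 0.08,
                       min_callers = 2, n_iterations = 10, min_times = 8,
                       balance_threshold = 10, min_freq = 0.05,
                       fdr_threshold = 0.1, n_perm = 100,
                       survival_cap_months = 36, snp_min_reads = 3,
                       snp_min_coverage = 8, min_base_quality = 15,
                       base_seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_iterations < cfg$min_times) {
    stop_config("n_iterations must be >= min_times")
  }
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1) {
    stop_config("fdr_threshold must be in (0, 1]")
  }
  if (cfg$n_perm < 0) stop_config("n_perm must be >= 0")
  cfg$base_seed <- assert_seed(cfg$base_seed)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config A [run_config()].
#' @param path YAML path.
#' @return The path / the configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_msg <- function(...) message("[raceblend] ", ...)

#' Run the full pipeline on the built-in synthetic scenario
#'
#' Executes, in order: synthetic-cohort generation (clinical covariates with
#' the study's cohort skews, six injected population-biased genes, one
#' prognostic gene, one covariate-driven null gene, background genes, a
#' coupled high-Fst germline SNP, and cohort-specific sequencing depths);
#' depth harmonization with consensus calling; propensity-weighted
#' biased-gene detection with optional permutation validation; germline Fst
#' and sample clustering; and the association tests. Every intermediate
#' table is written as TSV under `out_dir`, together with `manifest.yaml`
#' and `summary.json`. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$base_seed

  stage_msg("stage 1/5: synthetic cohort generation")
  specs <- study_cohort_specs(
    n = c(Caucasian = config$n_caucasian, Vietnamese = config$n_vietnamese,
          Chinese = config$n_chinese))
  coupling <- default_snp_coupling()
  effects <- c(
    biased_gene_effects(),
    list(
      gene_effect_spec("CSMD3",
                       freq_by_group = c(Asian = 0.25, Caucasian = 0.25),
                       survival_hazard_ratio = 0.5),
      confounded_null_gene()
    )
  )
  # wire the germline coupling into the coupled gene's effect spec; the
  # group frequencies stay the target marginals, so the non-carrier
  # baseline is raised to offset the carriers' reduced odds
  lo <- log(coupling$mutation_odds_given_snp)
  for (i in seq_along(effects)) {
    if (effects[[i]]$gene == coupling$coupled_gene) {
      effects[[i]]$carrier_log_odds <- lo
      fb <- effects[[i]]$freq_by_group
      for (g in names(fb)) {
        q <- coupling$allele_freq_by_group[[g]]
        fb[[g]] <- carrier_adjusted_freq(fb[[g]], 1 - (1 - q)^2, lo)
      }
      effects[[i]]$freq_by_group <- fb
    }
  }
  patients <- generate_clinical(specs, seed = seed)
  germline <- generate_genotypes_and_expression(patients, coupling,
                                                seed = seed + 11L)
  mutations <- generate_mutation_matrix(
    patients, effects, n_background_genes = config$n_background_genes,
    background_rate = config$background_rate, seed = seed + 12L,
    carriers = germline$carrier)
  patients <- apply_survival_effects(patients, mutations, effects,
                                     seed = seed + 13L)
  counts <- generate_readcounts(mutations, patients, specs,
                                seed = seed + 14L, n_contam_sites = 5)
  write_clinical(patients, file.path(out_dir, "clinical.tsv"))
  write_genotypes(germline$genotypes, file.path(out_dir, "genotypes.tsv"))
  write_tsv_file(germline$expression, file.path(out_dir, "expression.tsv"))
  write_tsv_file(counts, file.path(out_dir, "readcounts.tsv"))

  stage_msg("stage 2/5: depth harmonization and consensus calling")
  normal_panel <- call_normals(counts)
  depths <- exon_depths(counts, patients)
  fractions <- compute_downsampling_fractions(depths)
  params <- caller_params()
  consensus <- consensus_calls(counts, fractions, patients, params,
                               n_iterations = config$n_iterations,
                               min_times = config$min_times,
                               base_seed = seed + 20L)
  # panel-of-normals filter on the consensus calls
  kept <- filter_germline_panel(consensus[consensus$consensus, , drop = FALSE],
                                normal_panel)
  stage_msg("  candidate sites: ", nrow(consensus),
            "; consensus: ", sum(consensus$consensus),
            "; after normal-panel filter: ", nrow(kept))
  write_tsv_file(fractions, file.path(out_dir, "downsampling_fractions.tsv"))
  write_tsv_file(consensus, file.path(out_dir, "consensus_calls.tsv"))
  records <- data.frame(
    sample_id = kept$sample_id, gene = kept$gene, chrom = kept$chrom,
    pos = kept$pos, ref = kept$ref, alt = kept$alt,
    classification = "missense", callers = "thresholdA;thresholdB",
    vaf = NA_real_, stringsAsFactors = FALSE)
  write_mutations(records, file.path(out_dir, "mutations.maf.tsv"))

  stage_msg("stage 3/5: propensity-weighted comparison")
  matrix_called <- build_mutation_matrix(records, patients)
  gene_results <- race_biased_genes(matrix_called, patients,
                                    min_freq = config$min_freq,
                                    fdr_threshold = config$fdr_threshold)
  balance <- attr(gene_results, "balance")
  write_tsv_file(gene_results, file.path(out_dir, "gene_tests.tsv"))
  write_tsv_file(balance$covariates, file.path(out_dir, "balance_report.tsv"))
  perm <- NULL
  if (config$n_perm > 0) {
    stage_msg("  permutation validation (", config$n_perm, " shuffles)")
    perm <- permutation_significance(matrix_called, patients,
                                     n_perm = config$n_perm,
                                     seed = seed + 30L,
                                     min_freq = config$min_freq,
                                     fdr_threshold = config$fdr_threshold)
    jsonlite::write_json(perm[c("observed_significant", "permuted_counts",
                                "empirical_p")],
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stage_msg("  permutation stage skipped (n_perm = 0)")
  }

  stage_msg("stage 4/5: germline Fst and sample clustering")
  fst <- fst_from_genotypes(germline$genotypes, patients$group)
  fst <- fst[order(-fst$fst), ]
  write_tsv_file(fst, file.path(out_dir, "fst.tsv"))
  clust <- cluster_samples(germline$genotypes,
                           cohorts = stats::setNames(patients$cohort,
                                                     patients$sample_id))
  write_tsv_file(data.frame(sample_id = names(clust$assignment),
                            cluster = unname(clust$assignment)),
                 file.path(out_dir, "clusters.tsv"))
  writeLines(clust$newick, file.path(out_dir, "dendrogram.nwk"))

  stage_msg("stage 5/5: association tests")
  coupled_gene <- coupling$coupled_gene
  surv <- km_logrank(patients$os_months, patients$os_event,
                     ifelse(mutations[patients$sample_id, "CSMD3"] == 1,
                            "mutated", "wildtype"),
                     cap_months = config$survival_cap_months)
  write_tsv_file(surv$curves, file.path(out_dir, "survival_curves.tsv"))
  # carrier/mutation exclusivity within the Asian samples only: pooling
  # populations would confound carrier status with the gene's higher
  # Asian mutation frequency
  asian <- patients$sample_id[patients$group == "Asian"]
  excl <- exclusivity_test(germline$carrier[asian],
                           mutations[asian, coupled_gene])
  expr_carrier <- germline$expression$expression[
    germline$carrier[germline$expression$sample_id] == 1]
  expr_noncarrier <- germline$expression$expression[
    germline$carrier[germline$expression$sample_id] == 0]
  summary <- list(
    n_samples = nrow(patients),
    consensus_mutations = nrow(kept),
    significant_genes = gene_results$gene[gene_results$significant],
    balanced = balance$balanced,
    score_std_diff_after = balance$score_std_diff_after,
    permutation_empirical_p = if (!is.null(perm)) perm$empirical_p else NA,
    top_fst_snp = fst$snp_id[1],
    top_fst = fst$fst[1],
    survival_logrank_p = surv$p_value,
    exclusivity_p = excl$p_value,
    mean_expression_carrier = mean(expr_carrier),
    mean_expression_noncarrier = mean(expr_noncarrier)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("raceblend")),
    config = unclass(config),
    stage_seeds = list(clinical = seed, genotypes = seed + 11L,
                       mutations = seed + 12L, survival = seed + 13L,
                       readcounts = seed + 14L,
                       consensus_base = seed + 20L,
                       permutation = seed + 30L),
    thresholds = list(caller = unclass(params)),
    excluded_exons = attr(fractions, "excluded_exons")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  stage_msg("done; outputs in ", out_dir)
  invisible(list(patients = patients, mutations = mutations,
                 counts = counts, consensus = consensus,
                 gene_results = gene_results, balance = balance,
                 permutation = perm, fst = fst, clusters = clust,
                 survival = surv, exclusivity = excl, summary = summary))
}
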