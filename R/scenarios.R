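# Built-in scenario definitions.
#
# The covariate distributions below are the observed cohort compositions of
# the esophageal squamous cell carcinoma study populations (three
# whole-exome cohorts: Caucasian n=39, Vietnamese n=41, Chinese n=78), kept
# as categorical weights. They encode the real covariate skews -- Asian
# cohorts more male, more stage II, Caucasian cohorts older with stage I/IV
# present and a small "unknown" fraction for smoking/alcohol -- which is
# exactly the confounding structure the propensity adjustment must undo.

STUDY_COHORT_COUNTS <- list(
  Caucasian = list(
    age = c(0, 6, 19, 9, 4, 4), gender = c(male = 29, female = 10),
    stage = c(I = 6, II = 17, III = 14, IV = 2),
    smoking = c(ever = 25, never = 11, unknown = 3),
    alcohol = c(yes = 25, no = 12, unknown = 2)
  ),
  Vietnamese = list(
    age = c(2, 11, 15, 9, 4, 0), gender = c(male = 39, female = 2),
    stage = c(I = 0, II = 31, III = 9, IV = 1),
    smoking = c(ever = 22, never = 19, unknown = 0),
    alcohol = c(yes = 30, no = 11, unknown = 0)
  ),
  Chinese = list(
    age = c(0, 11, 35, 27, 5, 0), gender = c(male = 65, female = 13),
    stage = c(I = 0, II = 63, III = 15, IV = 0),
    smoking = c(ever = 46, never = 32, unknown = 0),
    alcohol = c(yes = 36, no = 42, unknown = 0)
  )
)

AGE_BREAKS <- c(30, 40, 50, 60, 70, 80, 90)

counts_to_dists <- function(cn) {
  list(
    age = list(breaks = AGE_BREAKS, probs = cn$age / sum(cn$age)),
    gender = cn$gender / sum(cn$gender),
    stage = cn$stage / sum(cn$stage),
    smoking = cn$smoking / sum(cn$smoking),
    alcohol = cn$alcohol / sum(cn$alcohol)
  )
}

#' Study-cohort covariate distributions
#'
#' Covariate distributions matching the observed composition of the three
#' whole-exome ESCC cohorts, or of the combined Asian (Chinese + Vietnamese)
#' cohort.
#'
#' @param cohort One of `"Caucasian"`, `"Vietnamese"`, `"Chinese"`,
#'   `"Asian"`.
#' @return A `covariate_dists` list suitable for [cohort_spec()].
#' @export
study_covariate_dists <- function(cohort = c("Caucasian", "Vietnamese",
                                             "Chinese", "Asian")) {
  cohort <- match.arg(cohort)
  if (cohort == "Asian") {
    v <- STUDY_COHORT_COUNTS$Vietnamese
    z <- STUDY_COHORT_COUNTS$Chinese
    cn <- Map(function(a, b) a + b, v, z)
    return(counts_to_dists(cn))
  }
  counts_to_dists(STUDY_COHORT_COUNTS[[cohort]])
}

#' Study-sized cohort specifications
#'
#' The three whole-exome cohorts at their study sizes and covariate
#' compositions, with the Chinese cohort sequenced roughly twice as deep as
#' the other two (the depth asymmetry the harmonization step removes).
#'
#' @param n Named sizes per cohort.
#' @param mean_depth Named mean per-exon depths per cohort.
#' @param depth_dispersion Negative-binomial size parameter shared by all
#'   cohorts.
#' @return Named list of [cohort_spec()] objects.
#' @export
study_cohort_specs <- function(n = c(Caucasian = 39, Vietnamese = 41,
                                     Chinese = 78),
                               mean_depth = c(Caucasian = 100,
                                              Vietnamese = 105,
                                              Chinese = 200),
                               depth_dispersion = 8) {
  specs <- lapply(names(n), function(nm) {
    cohort_spec(nm, n[[nm]],
                covariate_dists = study_covariate_dists(nm),
                mean_depth = mean_depth[[nm]],
                depth_dispersion = depth_dispersion)
  })
  stats::setNames(specs, names(n))
}

#' Two balanced-size cohorts with the study's covariate skews
#'
#' One Caucasian and one Chinese cohort of equal size; the Chinese cohort
#' uses the combined Asian covariate composition. This is the workhorse
#' scenario for calibration experiments (type-I error, parameter recovery)
#' where equal group sizes are wanted but the realistic covariate
#' confounding must be retained.
#'
#' @param n_per_group Samples per group.
#' @param mean_depth Named depths (defaults: Caucasian 100, Chinese 200).
#' @return Named list of two [cohort_spec()]s.
#' @export
two_group_specs <- function(n_per_group = 200,
                            mean_depth = c(Caucasian = 100, Chinese = 200)) {
  list(
    Caucasian = cohort_spec("Caucasian", n_per_group,
                            covariate_dists = study_covariate_dists("Caucasian"),
                            mean_depth = mean_depth[["Caucasian"]]),
    Chinese = cohort_spec("Chinese", n_per_group,
                          covariate_dists = study_covariate_dists("Asian"),
                          mean_depth = mean_depth[["Chinese"]])
  )
}

#' Covariate-driven null gene
#'
#' A gene whose mutation probability is identical across groups but depends
#' strongly on gender, stage and age -- covariates whose distributions differ
#' between the study cohorts. Its naive between-group frequency difference is
#' therefore biased away from zero; a correctly weighted test must not
#' declare it population-biased.
#'
#' @param gene Gene symbol.
#' @param base_freq Group-invariant baseline mutation probability.
#' @return A [gene_effect_spec()].
#' @export
confounded_null_gene <- function(gene = "NULLG", base_freq = 0.25) {
  gene_effect_spec(
    gene,
    freq_by_group = c(Asian = base_freq, Caucasian = base_freq),
    covariate_modifiers = list(
      gender = c(male = log(3)),
      stage = c(II = log(3)),
      age = -0.04
    )
  )
}

#' Six injected population-biased genes
#'
#' Three genes mutated more often in Asian samples and three in Caucasian
#' samples, named after recurrently mutated esophageal-cancer genes, with
#' odds ratios well above 3 at frequencies >= 0.1 -- the recovery scenario
#' for the weighted test.
#'
#' @param freq_high,freq_low Mutation probabilities in the enriched /
#'   depleted group.
#' @return List of six [gene_effect_spec()]s.
#' @export
biased_gene_effects <- function(freq_high = 0.30, freq_low = 0.10) {
  asian <- c("TP53", "NFE2L2", "EP300")
  cauc <- c("KRTAP9-1", "LRFN5", "MAP2")
  c(
    lapply(asian, function(g) gene_effect_spec(
      g, freq_by_group = c(Asian = freq_high, Caucasian = freq_low))),
    lapply(cauc, function(g) gene_effect_spec(
      g, freq_by_group = c(Asian = freq_low, Caucasian = freq_high)))
  )
}

#' Default coupled-SNP specification
#'
#' A germline variant common in Asian and rare in Caucasian populations
#' (hence high Fst), whose carriers have reduced odds of somatic mutation in
#' the coupled gene (mutual exclusivity) and lower expression of it.
#'
#' @param coupled_gene Gene the SNP interacts with.
#' @return A [snp_coupling_spec()].
#' @export
default_snp_coupling <- function(coupled_gene = "NFE2L2") {
  snp_coupling_spec(
    snp_id = "rs_synthetic_highfst",
    allele_freq_by_group = c(Asian = 0.40, Caucasian = 0.01),
    mutation_odds_given_snp = 0.25,
    expression_shift = -0.8,
    coupled_gene = coupled_gene
  )
}
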