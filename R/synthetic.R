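# Synthetic three-cohort generator.
#
# The generator produces cohorts with the statistical structure the analysis
# downstream has to cope with: clinical covariates whose distributions differ
# by cohort (and therefore confound a naive between-group comparison),
# population-biased mutation frequencies, cohort-specific sequencing depth,
# and a germline variant whose carrier status is coupled to somatic mutation
# and expression of one gene.

#' Cohort specification
#'
#' Describes one patient cohort: its size, the distributions of its clinical
#' covariates, and its sequencing-depth profile. Per-exon depth is modelled as
#' negative binomial with mean `mean_depth` (times a shared per-exon capture
#' multiplier) and dispersion `depth_dispersion`; Poisson is the limiting case
#' as the dispersion grows.
#'
#' @param name Cohort label. `"Chinese"` and `"Vietnamese"` map to the
#'   `"Asian"` comparison group, `"Caucasian"` to `"Caucasian"`; any other
#'   label requires an explicit `group`.
#' @param n_samples Number of patients (>= 1).
#' @param covariate_dists Named list of covariate distributions. Categorical
#'   covariates (`gender`, `stage`, `smoking`, `alcohol`) are named
#'   probability vectors summing to 1; `age` is a list with `breaks` (bin
#'   edges in years) and `probs` (bin probabilities). Missing entries fall
#'   back to uniform defaults.
#' @param mean_depth Expected per-exon tumor coverage (reads), > 0.
#' @param depth_dispersion Negative-binomial size parameter (> 0); larger
#'   values mean less overdispersion.
#' @param group Comparison group; only needed for cohort names outside the
#'   built-in mapping.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec("Caucasian", 39,
#'             covariate_dists = list(gender = c(male = 29/39, female = 10/39)))
#' @export
cohort_spec <- function(name, n_samples, covariate_dists = list(),
                        mean_depth = 100, depth_dispersion = 8,
                        group = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop_config("n_samples must be >= 1")
  }
  if (mean_depth <= 0) stop_config("mean_depth must be > 0")
  if (depth_dispersion <= 0) stop_config("depth_dispersion must be > 0")
  if (is.null(group)) {
    if (!name %in% names(COHORT_GROUPS)) {
      stop_config("cohort '", name, "' has no built-in group; supply `group`")
    }
    group <- unname(COHORT_GROUPS[name])
  }
  dists <- utils::modifyList(default_covariate_dists(), covariate_dists)
  for (cov in c("gender", "stage", "smoking", "alcohol")) {
    p <- dists[[cov]]
    if (is.null(names(p)) || any(p < 0)) {
      stop_config("distribution for '", cov, "' must be a named non-negative vector")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop_config("probabilities for '", cov, "' must sum to 1 (got ",
                  format(sum(p)), ")")
    }
  }
  age <- dists$age
  if (length(age$breaks) != length(age$probs) + 1L) {
    stop_config("age breaks must be one longer than age probs")
  }
  if (abs(sum(age$probs) - 1) > 1e-9) {
    stop_config("age bin probabilities must sum to 1")
  }
  structure(
    list(name = name, group = group, n_samples = as.integer(n_samples),
         covariate_dists = dists, mean_depth = mean_depth,
         depth_dispersion = depth_dispersion),
    class = "cohort_spec"
  )
}

default_covariate_dists <- function() {
  list(
    age = list(breaks = c(30, 40, 50, 60, 70, 80, 90),
               probs = rep(1 / 6, 6)),
    gender = c(male = 0.5, female = 0.5),
    stage = c(I = 0.25, II = 0.25, III = 0.25, IV = 0.25),
    smoking = c(ever = 0.45, never = 0.45, unknown = 0.10),
    alcohol = c(yes = 0.45, no = 0.45, unknown = 0.10)
  )
}

#' Gene effect specification
#'
#' Mutation model for one gene: a baseline mutation probability per
#' comparison group, optional covariate modifiers acting additively on the
#' log-odds scale, an optional log-odds shift for carriers of a coupled
#' germline variant, and a multiplicative hazard effect of mutated status on
#' survival.
#'
#' @param gene Gene symbol.
#' @param freq_by_group Named vector of mutation probabilities per group,
#'   each in \[0, 1\].
#' @param covariate_modifiers Named list of log-odds shifts. Categorical
#'   entries are named vectors keyed by level, e.g.
#'   `list(gender = c(male = 0.7))`; an `age` entry is a per-year slope
#'   applied to `(age - 60)`.
#' @param survival_hazard_ratio Multiplicative hazard of death for mutated
#'   samples (> 0; 1 = no effect).
#' @param carrier_log_odds Log-odds shift of mutation for carriers of the
#'   coupled germline variant (0 = no coupling; negative values encode
#'   mutual exclusivity).
#' @return An object of class `gene_effect_spec`.
#' @export
gene_effect_spec <- function(gene, freq_by_group,
                             covariate_modifiers = list(),
                             survival_hazard_ratio = 1,
                             carrier_log_odds = 0) {
  assert_prob(freq_by_group, paste0("freq_by_group for ", gene))
  if (is.null(names(freq_by_group))) {
    stop_config("freq_by_group must be named by group")
  }
  if (survival_hazard_ratio <= 0) stop_config("survival_hazard_ratio must be > 0")
  structure(
    list(gene = gene, freq_by_group = freq_by_group,
         covariate_modifiers = covariate_modifiers,
         survival_hazard_ratio = survival_hazard_ratio,
         carrier_log_odds = carrier_log_odds),
    class = "gene_effect_spec"
  )
}

#' Coupled germline variant specification
#'
#' A single germline SNP with group-specific alternate-allele frequencies,
#' whose carrier status multiplies the somatic mutation odds of a coupled
#' gene (values < 1 encode mutual exclusivity) and shifts the gene's
#' log-expression additively.
#'
#' @param snp_id SNP identifier.
#' @param allele_freq_by_group Named vector of alternate-allele frequencies
#'   per group, in \[0, 1\].
#' @param mutation_odds_given_snp Odds multiplier of somatic mutation in
#'   carriers (> 0).
#' @param expression_shift Additive effect of carrier status on
#'   log-expression.
#' @param coupled_gene Symbol of the somatically mutated gene the SNP
#'   interacts with.
#' @return An object of class `snp_coupling_spec`.
#' @export
snp_coupling_spec <- function(snp_id, allele_freq_by_group,
                              mutation_odds_given_snp = 1,
                              expression_shift = 0,
                              coupled_gene = NULL) {
  assert_prob(allele_freq_by_group, "allele_freq_by_group")
  if (is.null(names(allele_freq_by_group))) {
    stop_config("allele_freq_by_group must be named by group")
  }
  if (mutation_odds_given_snp <= 0) {
    stop_config("mutation_odds_given_snp must be > 0")
  }
  structure(
    list(snp_id = snp_id, allele_freq_by_group = allele_freq_by_group,
         mutation_odds_given_snp = mutation_odds_given_snp,
         expression_shift = expression_shift, coupled_gene = coupled_gene),
    class = "snp_coupling_spec"
  )
}

#' Generate clinical tables for one or more cohorts
#'
#' Draws one patient per row with cohort, comparison group, age (years),
#' gender, tumor stage, smoking and alcohol history from the spec
#' distributions, plus a baseline survival outcome (exponential event times
#' with uniform administrative censoring). Gene-specific survival effects are
#' applied afterwards with [apply_survival_effects()].
#'
#' @param specs A `cohort_spec` or list of them.
#' @param seed Integer seed; identical seeds yield identical tables.
#' @param baseline_hazard Monthly baseline hazard of death.
#' @param censor_max_months Upper bound of the uniform censoring time.
#' @return A data.frame of patients with columns `sample_id`, `cohort`,
#'   `group`, `age`, `gender`, `stage`, `smoking`, `alcohol`, `os_months`,
#'   `os_event`.
#' @export
generate_clinical <- function(specs, seed, baseline_hazard = 0.02,
                              censor_max_months = 72) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  seed <- assert_seed(seed)
  set.seed(seed)
  out <- lapply(specs, function(sp) {
    n <- sp$n_samples
    d <- sp$covariate_dists
    bin <- sample.int(length(d$age$probs), n, replace = TRUE, prob = d$age$probs)
    lo <- d$age$breaks[bin]
    hi <- d$age$breaks[bin + 1L]
    age <- round(stats::runif(n, lo, hi), 1)
    ev_time <- stats::rexp(n, rate = baseline_hazard)
    cn_time <- stats::runif(n, 0, censor_max_months)
    data.frame(
      sample_id = sprintf("%s_%03d", toupper(substr(sp$name, 1, 3)), seq_len(n)),
      cohort = sp$name,
      group = sp$group,
      age = age,
      gender = sample(names(d$gender), n, replace = TRUE, prob = d$gender),
      stage = sample(names(d$stage), n, replace = TRUE, prob = d$stage),
      smoking = sample(names(d$smoking), n, replace = TRUE, prob = d$smoking),
      alcohol = sample(names(d$alcohol), n, replace = TRUE, prob = d$alcohol),
      os_months = round(pmin(ev_time, cn_time), 2),
      os_event = as.integer(ev_time <= cn_time),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Baseline (non-carrier) mutation probability such that the group marginal
# equals `target` once a fraction `carrier_frac` of the group carries the
# coupled variant with log-odds shift `log_odds`.
carrier_adjusted_freq <- function(target, carrier_frac, log_odds) {
  if (target %in% c(0, 1) || carrier_frac == 0 || log_odds == 0) return(target)
  f <- function(b) {
    (1 - carrier_frac) * stats::plogis(b) +
      carrier_frac * stats::plogis(b + log_odds) - target
  }
  stats::plogis(stats::uniroot(f, c(-30, 30), tol = 1e-12)$root)
}

# Per-sample log-odds shift from a gene's covariate modifiers.
modifier_shift <- function(patients, modifiers) {
  shift <- numeric(nrow(patients))
  for (cov in names(modifiers)) {
    m <- modifiers[[cov]]
    if (cov == "age") {
      shift <- shift + m * (patients$age - 60)
    } else {
      vals <- as.character(patients[[cov]])
      hit <- vals %in% names(m)
      shift[hit] <- shift[hit] + m[vals[hit]]
    }
  }
  shift
}

#' Generate a binary sample-by-gene mutation matrix
#'
#' Each sample x gene status is a Bernoulli draw whose probability is the
#' group baseline from the gene's effect spec, shifted on the log-odds scale
#' by covariate modifiers and (for carriers of a coupled germline variant) by
#' the gene's carrier log-odds. Background genes mutate at a common rate in
#' all groups.
#'
#' @param patients Clinical table from [generate_clinical()].
#' @param effects List of [gene_effect_spec()] objects.
#' @param n_background_genes Number of additional null genes.
#' @param background_rate Mutation probability of background genes.
#' @param seed Integer seed.
#' @param carriers Optional named 0/1 vector (by `sample_id`) of carrier
#'   status for the coupled germline variant.
#' @return Integer matrix (samples x genes) with dimnames.
#' @export
generate_mutation_matrix <- function(patients, effects,
                                     n_background_genes = 0,
                                     background_rate = 0.05,
                                     seed = 1, carriers = NULL) {
  seed <- assert_seed(seed)
  assert_prob(background_rate, "background_rate")
  set.seed(seed)
  n <- nrow(patients)
  genes <- vapply(effects, function(e) e$gene, character(1))
  bg <- if (n_background_genes > 0) sprintf("BG%04d", seq_len(n_background_genes)) else character(0)
  mat <- matrix(0L, nrow = n, ncol = length(genes) + length(bg),
                dimnames = list(patients$sample_id, c(genes, bg)))
  carrier <- rep(0L, n)
  if (!is.null(carriers)) {
    carrier <- as.integer(carriers[patients$sample_id] > 0)
    carrier[is.na(carrier)] <- 0L
  }
  for (e in effects) {
    missing_grp <- setdiff(unique(patients$group), names(e$freq_by_group))
    if (length(missing_grp)) {
      stop_data("gene ", e$gene, ": no mutation frequency for group(s) ",
                paste(missing_grp, collapse = ", "))
    }
    base <- e$freq_by_group[patients$group]
    logit <- stats::qlogis(base) + modifier_shift(patients, e$covariate_modifiers) +
      e$carrier_log_odds * carrier
    p <- stats::plogis(logit)
    p[base == 0] <- 0   # -Inf logit survives shifts, but be explicit
    p[base == 1] <- 1
    mat[, e$gene] <- stats::rbinom(n, 1L, p)
  }
  for (g in bg) mat[, g] <- stats::rbinom(n, 1L, background_rate)
  mat
}

#' Overwrite survival outcomes with gene-specific hazard effects
#'
#' Redraws exponential event times with each sample's hazard multiplied by
#' the hazard ratios of the genes it carries mutated, then applies uniform
#' censoring. Used to create scenarios where mutation status is prognostic.
#'
#' @inheritParams generate_clinical
#' @param patients Clinical table.
#' @param mutations Matrix from [generate_mutation_matrix()].
#' @param effects List of `gene_effect_spec`s (hazard ratios of 1 are inert).
#' @return The patients table with `os_months` / `os_event` replaced.
#' @export
apply_survival_effects <- function(patients, mutations, effects, seed,
                                   baseline_hazard = 0.02,
                                   censor_max_months = 72) {
  seed <- assert_seed(seed)
  set.seed(seed)
  loghr <- numeric(nrow(patients))
  for (e in effects) {
    if (e$survival_hazard_ratio != 1 && e$gene %in% colnames(mutations)) {
      loghr <- loghr + log(e$survival_hazard_ratio) *
        mutations[patients$sample_id, e$gene]
    }
  }
  ev <- stats::rexp(nrow(patients), rate = baseline_hazard * exp(loghr))
  cn <- stats::runif(nrow(patients), 0, censor_max_months)
  patients$os_months <- round(pmin(ev, cn), 2)
  patients$os_event <- as.integer(ev <= cn)
  patients
}

#' Generate per-site tumor/normal read counts
#'
#' Each gene is modelled as one exon at a fixed genomic position. For every
#' sample x gene pair a tumor depth is drawn (negative binomial around the
#' cohort's `mean_depth` times a shared per-exon capture multiplier) and, at
#' mutated sites, alt reads are binomial at a Beta-distributed variant allele
#' fraction centred on `vaf_mean`. Matched normals carry ref-only reads
#' except at injected germline-contamination sites, which appear with alt
#' support in several normals and exercise the panel-of-normals filter.
#'
#' @param mutations Matrix from [generate_mutation_matrix()].
#' @param patients Clinical table.
#' @param spec_by_cohort Named list of `cohort_spec`s keyed by cohort.
#' @param vaf_mean Mean variant allele fraction in (0, 1].
#' @param seed Integer seed.
#' @param vaf_concentration Beta concentration of the VAF distribution.
#' @param exon_log_sd SD of the shared log-normal per-exon capture
#'   multiplier.
#' @param n_contam_sites Number of injected germline-contamination sites.
#' @param contam_normals Number of normals carrying each contamination site.
#' @return A data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `exon_id`, `t_ref`, `t_alt`, `n_ref`, `n_alt`.
#' @export
generate_readcounts <- function(mutations, patients, spec_by_cohort,
                                vaf_mean = 0.3, seed = 1,
                                vaf_concentration = 2,
                                exon_log_sd = 0.25,
                                n_contam_sites = 0, contam_normals = 3) {
  seed <- assert_seed(seed)
  if (vaf_mean <= 0 || vaf_mean > 1) stop_config("vaf_mean must be in (0, 1]")
  set.seed(seed)
  genes <- colnames(mutations)
  G <- length(genes)
  n <- nrow(patients)
  exon_mult <- exp(stats::rnorm(G, 0, exon_log_sd))
  names(exon_mult) <- genes
  mu_cohort <- vapply(spec_by_cohort, function(s) s$mean_depth, numeric(1))
  size_cohort <- vapply(spec_by_cohort, function(s) s$depth_dispersion, numeric(1))
  mu <- mu_cohort[patients$cohort]
  size <- size_cohort[patients$cohort]
  if (anyNA(mu)) stop_data("spec_by_cohort is missing a cohort present in patients")

  rows <- vector("list", G)
  for (j in seq_len(G)) {
    depth <- stats::rnbinom(n, size = size, mu = mu * exon_mult[j])
    ndepth <- stats::rnbinom(n, size = size, mu = mu * exon_mult[j])
    mut <- mutations[patients$sample_id, genes[j]] == 1L
    vaf <- if (vaf_mean == 1) rep(1, n) else
      stats::rbeta(n, vaf_mean * vaf_concentration,
                   (1 - vaf_mean) * vaf_concentration)
    t_alt <- ifelse(mut, stats::rbinom(n, depth, vaf), 0L)
    rows[[j]] <- data.frame(
      sample_id = patients$sample_id,
      chrom = "1",
      pos = j * 1000L,
      ref = "C", alt = "T",
      gene = genes[j],
      exon_id = genes[j],
      t_ref = as.integer(depth - t_alt),
      t_alt = as.integer(t_alt),
      n_ref = as.integer(ndepth),
      n_alt = 0L,
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, rows)
  if (n_contam_sites > 0) {
    # germline leakage: same off-exon site alt-supported in several normals
    for (k in seq_len(n_contam_sites)) {
      idx <- sample.int(n, min(contam_normals, n))
      pos <- 1000L * G + k
      dep <- stats::rnbinom(length(idx), size = size[idx], mu = mu[idx])
      alt <- stats::rbinom(length(idx), dep, 0.5)
      counts <- rbind(counts, data.frame(
        sample_id = patients$sample_id[idx],
        chrom = "1", pos = pos, ref = "G", alt = "A",
        gene = sprintf("CONTAM%03d", k), exon_id = sprintf("CONTAM%03d", k),
        t_ref = as.integer(dep - alt), t_alt = as.integer(alt),
        n_ref = as.integer(dep - alt), n_alt = as.integer(alt),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(counts) <- NULL
  counts
}

#' Generate germline genotypes and coupled gene expression
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at group-specific
#' allele frequencies: the coupled SNP at the frequencies of the coupling
#' spec, plus `n_neutral_snps` neutral SNPs whose group frequencies scatter
#' around a shared ancestral frequency with Balding-Nichols divergence
#' `neutral_divergence`. Expression of the coupled gene is
#' `baseline + expression_shift * carrier + noise` on the log scale.
#'
#' @param patients Clinical table.
#' @param coupling A [snp_coupling_spec()].
#' @param n_neutral_snps Number of neutral background SNPs (the aggregate
#'   signal the sample clustering relies on; a desk-scale stand-in for a
#'   genome-wide common-SNP panel).
#' @param seed Integer seed.
#' @param neutral_divergence Balding-Nichols F for neutral SNPs (0 = none).
#' @param expr_baseline Baseline log-expression.
#' @param expr_sd SD of expression noise.
#' @return List with `genotypes` (samples x SNPs matrix of 0/1/2, coupled SNP
#'   first), `expression` (data.frame `sample_id`, `expression`), and
#'   `carrier` (named 0/1 vector for the coupled SNP).
#' @export
generate_genotypes_and_expression <- function(patients, coupling,
                                              n_neutral_snps = 1000,
                                              seed = 1,
                                              neutral_divergence = 0.03,
                                              expr_baseline = 5,
                                              expr_sd = 0.5) {
  stopifnot(inherits(coupling, "snp_coupling_spec"))
  seed <- assert_seed(seed)
  set.seed(seed)
  n <- nrow(patients)
  grp <- patients$group
  missing_grp <- setdiff(unique(grp), names(coupling$allele_freq_by_group))
  if (length(missing_grp)) {
    stop_data("coupling lacks allele frequency for group(s) ",
              paste(missing_grp, collapse = ", "))
  }
  groups <- unique(grp)
  q <- coupling$allele_freq_by_group[grp]
  coupled <- stats::rbinom(n, 2L, q)

  neutral <- matrix(0L, n, n_neutral_snps)
  if (n_neutral_snps > 0) {
    Fdiv <- neutral_divergence
    for (s in seq_len(n_neutral_snps)) {
      anc <- stats::runif(1, 0.05, 0.95)
      pg <- if (Fdiv > 0) {
        stats::setNames(stats::rbeta(length(groups),
                                     anc * (1 - Fdiv) / Fdiv,
                                     (1 - anc) * (1 - Fdiv) / Fdiv), groups)
      } else {
        stats::setNames(rep(anc, length(groups)), groups)
      }
      neutral[, s] <- stats::rbinom(n, 2L, pg[grp])
    }
  }
  geno <- cbind(coupled, neutral)
  colnames(geno) <- c(coupling$snp_id,
                      if (n_neutral_snps > 0) sprintf("SNP%04d", seq_len(n_neutral_snps)))
  rownames(geno) <- patients$sample_id
  carrier <- stats::setNames(as.integer(coupled > 0), patients$sample_id)
  expression <- data.frame(
    sample_id = patients$sample_id,
    expression = expr_baseline + coupling$expression_shift * carrier +
      stats::rnorm(n, 0, expr_sd),
    stringsAsFactors = FALSE
  )
  list(genotypes = geno, expression = expression, carrier = carrier)
}
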