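# Synthetic cohort generator: spec validation, determinism, marginal
# calibration, and the injected-confounding property the propensity
# adjustment relies on.

test_that("cohort_spec rejects invalid configurations", {
  expect_error(cohort_spec("Caucasian", 0), class = "raceblend_config_error")
  expect_error(
    cohort_spec("Caucasian", 10,
                covariate_dists = list(gender = c(male = 0.7, female = 0.4))),
    "sum to 1")
  expect_error(cohort_spec("Caucasian", 10, mean_depth = 0), "mean_depth")
  expect_error(cohort_spec("Martian", 10), "no built-in group")
  expect_error(
    gene_effect_spec("G", c(Asian = 1.2, Caucasian = 0.1)), "\\[0, 1\\]")
  expect_error(
    gene_effect_spec("G", c(Asian = 0.2, Caucasian = 0.1),
                     survival_hazard_ratio = -1), "hazard")
})

test_that("generation is deterministic given the seed", {
  specs <- study_cohort_specs(n = c(Caucasian = 15, Vietnamese = 15, Chinese = 15))
  p1 <- generate_clinical(specs, seed = 5)
  p2 <- generate_clinical(specs, seed = 5)
  expect_identical(p1, p2)
  eff <- biased_gene_effects()
  m1 <- generate_mutation_matrix(p1, eff, n_background_genes = 5, seed = 9)
  m2 <- generate_mutation_matrix(p2, eff, n_background_genes = 5, seed = 9)
  expect_identical(m1, m2)
  c1 <- generate_readcounts(m1, p1, specs, seed = 3)
  c2 <- generate_readcounts(m2, p2, specs, seed = 3)
  expect_identical(c1, c2)
  g1 <- generate_genotypes_and_expression(p1, default_snp_coupling(),
                                          n_neutral_snps = 20, seed = 4)
  g2 <- generate_genotypes_and_expression(p2, default_snp_coupling(),
                                          n_neutral_snps = 20, seed = 4)
  expect_identical(g1, g2)
  expect_false(identical(generate_clinical(specs, seed = 6), p1))
})

test_that("long-run male fraction matches the Caucasian cohort composition", {
  spec <- cohort_spec("Caucasian", 39,
                      covariate_dists = study_covariate_dists("Caucasian"))
  males <- vapply(1:150, function(s) {
    sum(generate_clinical(spec, seed = s)$gender == "male")
  }, numeric(1))
  p_hat <- sum(males) / (39 * 150)
  p_true <- 29 / 39
  se <- sqrt(p_true * (1 - p_true) / (39 * 150))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("per-group mutation frequencies are calibrated", {
  specs <- two_group_specs(500)
  eff <- list(gene_effect_spec("G", c(Asian = 0.3, Caucasian = 0.05)))
  tot <- c(Asian = 0, Caucasian = 0)
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    p <- generate_clinical(specs, seed = s)
    m <- generate_mutation_matrix(p, eff, seed = s + 1000)
    tot <- tot + tapply(m[, "G"], p$group, sum)[names(tot)]
  }
  n_tot <- 500 * n_seeds
  for (g in names(tot)) {
    p_true <- c(Asian = 0.3, Caucasian = 0.05)[[g]]
    se <- sqrt(p_true * (1 - p_true) / n_tot)
    expect_lt(abs(tot[[g]] / n_tot - p_true), 3 * se)
  }
})

test_that("degenerate mutation probabilities behave exactly", {
  specs <- two_group_specs(30)
  p <- generate_clinical(specs, seed = 2)
  always <- generate_mutation_matrix(
    p, list(gene_effect_spec("A", c(Asian = 1, Caucasian = 1))),
    n_background_genes = 3, background_rate = 0, seed = 7)
  expect_true(all(always[, "A"] == 1L))
  expect_true(all(always[, -1] == 0L))
})

test_that("unknown group labels are reported by name", {
  specs <- two_group_specs(10)
  p <- generate_clinical(specs, seed = 1)
  expect_error(
    generate_mutation_matrix(p, list(gene_effect_spec("G", c(Asian = 0.1))),
                             seed = 1),
    "Caucasian")
})

test_that("read counts reflect VAF and cohort depth settings", {
  specs <- two_group_specs(60, mean_depth = c(Caucasian = 100, Chinese = 200))
  p <- generate_clinical(specs, seed = 11)
  eff <- list(gene_effect_spec("G", c(Asian = 1, Caucasian = 1)))
  m <- generate_mutation_matrix(p, eff, seed = 12)

  pure <- generate_readcounts(m, p, specs, vaf_mean = 1, seed = 13)
  expect_true(all(pure$t_ref == 0L))
  expect_true(all(pure$t_alt >= 0L))

  cnt <- generate_readcounts(m, p, specs, seed = 14)
  depth <- cnt$t_ref + cnt$t_alt
  cohort <- p$cohort[match(cnt$sample_id, p$sample_id)]
  ratio <- mean(depth[cohort == "Chinese"]) / mean(depth[cohort == "Caucasian"])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)

  none <- generate_mutation_matrix(
    p, list(gene_effect_spec("G", c(Asian = 0, Caucasian = 0))), seed = 15)
  cnt0 <- generate_readcounts(none, p, specs, seed = 16)
  expect_true(all(cnt0$t_alt == 0L))
})

test_that("genotype generation honours allele frequencies and null shifts", {
  specs <- two_group_specs(200)
  p <- generate_clinical(specs, seed = 21)
  zero <- snp_coupling_spec("rs0", c(Asian = 0, Caucasian = 0))
  g0 <- generate_genotypes_and_expression(p, zero, n_neutral_snps = 0, seed = 22)
  expect_true(all(g0$genotypes == 0L))

  null_expr <- snp_coupling_spec("rs1", c(Asian = 0.5, Caucasian = 0.5),
                                 expression_shift = 0)
  g1 <- generate_genotypes_and_expression(p, null_expr, n_neutral_snps = 0,
                                          seed = 23, expr_sd = 0.5)
  d <- tapply(g1$expression$expression, g1$carrier[g1$expression$sample_id], mean)
  expect_lt(abs(d[["1"]] - d[["0"]]), 3 * 0.5 * sqrt(2 / 100))
})

test_that("covariate-driven null genes are confounded between groups", {
  # the property the propensity adjustment must undo: equal freq_by_group,
  # covariate modifiers + cohort-skewed covariates => biased naive contrast
  specs <- two_group_specs(2000)
  p <- generate_clinical(specs, seed = 31)
  m <- generate_mutation_matrix(p, list(confounded_null_gene()), seed = 32)
  freq <- tapply(m[, 1], p$group, mean)
  expect_gt(abs(freq[["Asian"]] - freq[["Caucasian"]]), 0.04)
})
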