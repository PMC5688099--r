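# Propensity scores, matching weights, balance diagnostics and the
# weighted chi-squared biased-gene machinery.

test_that("matching-weight formula evaluates directly", {
  expect_equal(matching_weight(0.5, TRUE), 1)
  expect_equal(matching_weight(0.5, FALSE), 1)
  expect_equal(matching_weight(0.8, TRUE), 0.25)   # reference-group sample
  expect_equal(matching_weight(0.8, FALSE), 1)     # counterpart
  s <- runif(50, 0.01, 0.99)
  expect_true(all(matching_weight(s, TRUE) > 0 & matching_weight(s, TRUE) <= 1))
})

test_that("covariate-free propensity equals the group prevalence", {
  specs <- two_group_specs(40)
  p <- generate_clinical(specs, seed = 2)
  pr <- fit_propensity(p, covariates = character(0))
  expect_true(all(abs(pr$score - mean(p$group == "Caucasian")) < 1e-12))
})

test_that("single-level covariates are dropped with a warning", {
  specs <- two_group_specs(40)
  p <- generate_clinical(specs, seed = 3)
  p$gender <- "male"
  expect_warning(pr <- fit_propensity(p), "gender")
  expect_equal(nrow(pr), nrow(p))
})

test_that("complete separation raises an explicit error", {
  specs <- two_group_specs(40)
  p <- generate_clinical(specs, seed = 4)
  p$age <- ifelse(p$group == "Caucasian", 80, 40)  # perfectly separating
  expect_error(fit_propensity(p, covariates = "age"), "separation")
})

test_that("standardized difference has its closed-form values", {
  x <- rnorm(100)
  expect_equal(standardized_difference(x, x), 0)
  expect_equal(standardized_difference(c(-1, 1), c(0, 2)), 100)
  expect_equal(standardized_difference(c(1, 1), c(2, 2)), Inf)
  expect_equal(standardized_difference(c(1, 1), c(1, 1)), 0)
  expect_error(standardized_difference(1, c(1, 2)), "2 samples")
  # weights that equalize a confounded covariate reduce the difference
  x1 <- c(rep(1, 80), rep(0, 20))   # 80% exposed
  x2 <- c(rep(1, 20), rep(0, 80))   # 20% exposed
  w1 <- ifelse(x1 == 1, 0.25, 1)    # down-weight the excess
  w2 <- ifelse(x2 == 1, 1, 0.25)
  before <- standardized_difference(x1, x2)
  after <- standardized_difference(x1, x2, w1, w2)
  expect_lt(after, before)
  expect_lt(after, 1e-9)            # exact equalization in this construction
})

test_that("weighted chi-squared reduces to Pearson at unit weights", {
  set.seed(8)
  for (i in 1:20) {
    n <- 120
    grp <- rep(c("Asian", "Caucasian"), each = n / 2)
    x <- rbinom(n, 1, ifelse(grp == "Asian", 0.4, 0.25))
    if (length(unique(x)) < 2) next
    ours <- weighted_chisq(x, grp)
    ref <- suppressWarnings(stats::chisq.test(table(grp, x), correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("weighted chi-squared degenerate cases are exact", {
  grp <- rep(c("A", "B"), each = 10)
  expect_equal(weighted_chisq(rep(1, 20), grp)$statistic, 0)
  expect_equal(weighted_chisq(rep(0, 20), grp)$p_value, 1)
  x <- c(rep(1, 3), rep(0, 7), rep(1, 3), rep(0, 7))
  expect_equal(weighted_chisq(x, grp)$statistic, 0)
  expect_error(weighted_chisq(x, grp, c(rep(0, 10), rep(1, 10))),
               "zero total weight")
})

test_that("study-skewed cohorts are unbalanced raw and balanced after weighting", {
  specs <- two_group_specs(300)
  p <- generate_clinical(specs, seed = 41)
  pr <- fit_propensity(p)
  bal <- check_balance(p, pr)
  expect_gt(max(bal$covariates$std_diff_before), 10)
  expect_true(bal$balanced)
  expect_lt(bal$score_std_diff_after, 10)
  finite <- is.finite(bal$covariates$std_diff_after)
  expect_true(all(bal$covariates$std_diff_after[finite] <=
                    bal$covariates$std_diff_before[finite] + 1e-9 |
                    bal$covariates$std_diff_after[finite] < 10))
  strict <- check_balance(p, pr, threshold = 0)
  expect_false(strict$balanced)
})

test_that("identically distributed cohorts are balanced before weighting", {
  specs <- list(
    Caucasian = cohort_spec("Caucasian", 250),
    Chinese = cohort_spec("Chinese", 250)
  )  # same default covariate distributions
  p <- generate_clinical(specs, seed = 42)
  pr <- fit_propensity(p)
  bal <- check_balance(p, pr)
  expect_lt(max(bal$covariates$std_diff_before), 25)  # sampling noise only
  expect_true(bal$balanced)
})

test_that("biased-gene scan reduces to classical chi-squared + BH at unit weights", {
  specs <- two_group_specs(150)
  p <- generate_clinical(specs, seed = 51)
  m <- generate_mutation_matrix(p, biased_gene_effects(),
                                n_background_genes = 10,
                                background_rate = 0.2, seed = 52)
  unit <- data.frame(sample_id = p$sample_id, group = p$group,
                     score = 0.5, matching_weight = 1,
                     stringsAsFactors = FALSE)
  res <- race_biased_genes(m, p, propensity = unit, check = FALSE)
  classical <- vapply(res$gene, function(g) {
    suppressWarnings(stats::chisq.test(table(p$group, m[, g]),
                                       correct = FALSE)$p.value)
  }, numeric(1))
  expect_equal(res$p_value, unname(classical), tolerance = 1e-10)
  expect_equal(res$fdr, unname(stats::p.adjust(classical, "BH")),
               tolerance = 1e-10)
})

test_that("frequency floor and single-gene FDR behave per contract", {
  specs <- two_group_specs(80)
  p <- generate_clinical(specs, seed = 61)
  m <- generate_mutation_matrix(
    p, list(gene_effect_spec("G", c(Asian = 0.5, Caucasian = 0.2))), seed = 62)
  res <- race_biased_genes(m, p, check = FALSE)
  expect_equal(nrow(res), 1)
  expect_equal(res$fdr, res$p_value)     # BH with m = 1
  expect_warning(empty <- race_biased_genes(m, p, min_freq = 1, check = FALSE),
                 "frequency floor")
  expect_equal(nrow(empty), 0)
})

test_that("permutation machinery is deterministic and bounded below", {
  specs <- two_group_specs(120)
  p <- generate_clinical(specs, seed = 71)
  m <- generate_mutation_matrix(p, biased_gene_effects(),
                                n_background_genes = 5,
                                background_rate = 0.1, seed = 72)
  r1 <- permutation_significance(m, p, n_perm = 9, seed = 5)
  r2 <- permutation_significance(m, p, n_perm = 9, seed = 5)
  expect_identical(r1$permuted_counts, r2$permuted_counts)
  # strong injected effects: observed count tops every permutation
  expect_gte(r1$observed_significant, 5)
  expect_equal(r1$empirical_p, 1 / 10)
  r3 <- permutation_significance(m, p, n_perm = 1, seed = 6)
  expect_true(r3$empirical_p %in% c(0.5, 1))
})
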