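# Biological-confounder removal: propensity-score matching weights and the
# weighted chi-squared test for population-biased mutated genes.
#
# Clinical covariates (age, gender, stage, smoking, alcohol) differ between
# patient populations and themselves influence mutation status, so raw
# between-group frequency comparisons are confounded. Each sample receives a
# matching weight min(e, 1-e) / P(own group), where e is the fitted
# propensity of the reference group: samples typical of both groups keep
# weight near 1, samples characteristic of only their own group are
# down-weighted, emulating 1:1 matching without discarding anyone. Gene
# frequencies are then compared with a chi-squared test on the weighted
# contingency table rescaled to each group's effective sample size.

DEFAULT_COVARIATES <- c("age", "gender", "stage", "smoking", "alcohol")

#' Matching weight from a propensity score
#'
#' `min(e, 1 - e)` divided by the probability of the sample's own group:
#' `e` for reference-group samples, `1 - e` otherwise, where `e` is the
#' propensity of the reference group. Weights lie in (0, 1]; a sample whose
#' covariates are equally plausible in both groups (e = 0.5) keeps weight 1.
#'
#' @param score Propensity of the reference group, in (0, 1).
#' @param is_reference Logical; does the sample belong to the reference
#'   group?
#' @return Matching weights.
#' @export
matching_weight <- function(score, is_reference) {
  assert_prob(score, "score")
  is_reference <- rep_len(is_reference, length(score))
  own <- ifelse(is_reference, score, 1 - score)
  pmin(score, 1 - score) / own
}

#' Fit propensity scores and matching weights
#'
#' Maximum-likelihood logistic regression of group membership on the
#' clinical covariates (age continuous, the rest indicator-coded, with
#' "unknown" retained as an explicit level). Fitted probabilities are
#' clipped to `[1e-6, 1 - 1e-6]`; matching weights are
#' `min(e, 1 - e) / e` for reference-group samples and
#' `min(e, 1 - e) / (1 - e)` otherwise, where `e` is the propensity of the
#' reference group.
#'
#' @param patients Patients table with a two-level `group` column.
#' @param covariates Covariate names to adjust for.
#' @param reference_group Group whose propensity `e` models (default
#'   `"Caucasian"`).
#' @return Data.frame `sample_id`, `group`, `score`, `matching_weight` with
#'   the fitted model in attribute `"model"`.
#' @export
fit_propensity <- function(patients, covariates = DEFAULT_COVARIATES,
                           reference_group = "Caucasian") {
  groups <- unique(patients$group)
  if (length(groups) != 2) {
    stop_data("exactly two groups required, got: ",
              paste(groups, collapse = ", "))
  }
  if (!reference_group %in% groups) {
    stop_data("reference group '", reference_group, "' absent from data")
  }
  missing_cov <- setdiff(covariates, names(patients))
  if (length(missing_cov)) {
    stop_data("covariate(s) not in patients table: ",
              paste(missing_cov, collapse = ", "))
  }
  usable <- character(0)
  for (cov in covariates) {
    v <- patients[[cov]]
    if (length(unique(v)) < 2) {
      warning("covariate '", cov, "' has a single level; dropped from the model")
    } else {
      usable <- c(usable, cov)
    }
  }
  y <- as.integer(patients$group == reference_group)
  if (length(usable) == 0) {
    score <- rep(mean(y), length(y))
  } else {
    dat <- patients[usable]
    for (cov in usable) if (!is.numeric(dat[[cov]])) dat[[cov]] <- factor(dat[[cov]])
    dat$.y <- y
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    )
    score <- stats::fitted(fit)
    # Complete separation: the model classifies every sample perfectly and
    # the MLE diverges. Isolated boundary scores (a covariate level present
    # in one group only) are legitimate and handled by clipping below.
    if (fit$deviance < 1e-6) {
      stop_data("complete separation in the propensity model; ",
                "reduce the covariate set")
    }
  }
  score <- pmin(pmax(score, 1e-6), 1 - 1e-6)
  out <- data.frame(sample_id = patients$sample_id,
                    group = patients$group,
                    score = score,
                    matching_weight = matching_weight(score, y == 1L),
                    stringsAsFactors = FALSE)
  if (length(usable)) attr(out, "model") <- fit
  attr(out, "reference_group") <- reference_group
  attr(out, "covariates_used") <- usable
  rownames(out) <- NULL
  out
}

#' Standardized difference between two groups (percent)
#'
#' `100 * |m1 - m2| / sqrt((v1 + v2) / 2)` with (optionally weighted) means
#' and variances; the conventional scale-free balance diagnostic, with < 10%
#' regarded as balanced. Zero pooled variance with unequal means yields
#' `Inf`.
#'
#' @param x1,x2 Values in each group (for a categorical covariate, pass one
#'   0/1 indicator per level).
#' @param w1,w2 Optional non-negative weights.
#' @return The standardized difference in percent.
#' @export
standardized_difference <- function(x1, x2, w1 = NULL, w2 = NULL) {
  if (length(x1) < 2 || length(x2) < 2) {
    stop_data("need at least 2 samples per group")
  }
  w1 <- w1 %||% rep(1, length(x1))
  w2 <- w2 %||% rep(1, length(x2))
  m1 <- wtd_mean(x1, w1); m2 <- wtd_mean(x2, w2)
  v1 <- wtd_var(x1, w1);  v2 <- wtd_var(x2, w2)
  pooled <- (v1 + v2) / 2
  if (pooled == 0) {
    return(if (isTRUE(all.equal(m1, m2))) 0 else Inf)
  }
  100 * abs(m1 - m2) / sqrt(pooled)
}

#' Covariate and propensity-score balance report
#'
#' Standardized differences per covariate (per indicator level for
#' categorical covariates) before and after matching-weight adjustment, plus
#' the weighted standardized difference of the propensity scores themselves;
#' the cohorts are considered balanced when the latter is below `threshold`.
#'
#' @param patients Patients table.
#' @param propensity Result of [fit_propensity()].
#' @param covariates Covariates to report on.
#' @param threshold Balance threshold in percent (default 10).
#' @return List of class `balance_report` with elements `covariates`
#'   (data.frame `covariate`, `level`, `std_diff_before`, `std_diff_after`),
#'   `score_std_diff_after`, `threshold` and `balanced`.
#' @export
check_balance <- function(patients, propensity,
                          covariates = DEFAULT_COVARIATES, threshold = 10) {
  m <- match(patients$sample_id, propensity$sample_id)
  if (anyNA(m)) stop_data("propensity results missing for some samples")
  w <- propensity$matching_weight[m]
  grp <- patients$group
  gl <- sort(unique(grp))
  i1 <- grp == gl[1]; i2 <- grp == gl[2]
  rows <- list()
  for (cov in covariates) {
    v <- patients[[cov]]
    if (is.numeric(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = "",
        std_diff_before = standardized_difference(v[i1], v[i2]),
        std_diff_after = standardized_difference(v[i1], v[i2], w[i1], w[i2]),
        stringsAsFactors = FALSE)
    } else {
      for (lev in sort(unique(v))) {
        ind <- as.numeric(v == lev)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cov, level = lev,
          std_diff_before = standardized_difference(ind[i1], ind[i2]),
          std_diff_after = standardized_difference(ind[i1], ind[i2], w[i1], w[i2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  score <- propensity$score[m]
  score_sd <- standardized_difference(score[i1], score[i2], w[i1], w[i2])
  structure(list(covariates = do.call(rbind, rows),
                 score_std_diff_after = score_sd,
                 threshold = threshold,
                 balanced = score_sd < threshold),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report (threshold ", x$threshold, "%)\n", sep = "")
  print(x$covariates, row.names = FALSE, digits = 3)
  cat(sprintf("Weighted propensity-score standardized difference: %.2f%% (%s)\n",
              x$score_std_diff_after,
              if (x$balanced) "balanced" else "NOT balanced"))
  invisible(x)
}

#' Weighted chi-squared test of a binary trait between two groups
#'
#' Builds the weighted 2x2 table of group x mutated, rescales each group's
#' row to its effective sample size `(sum w)^2 / sum w^2` (guarding against
#' anti-conservative inference under unequal weights), and computes the
#' Pearson chi-squared statistic with 1 df on the rescaled table. With all
#' weights equal to 1 this reduces exactly to the classical (uncorrected)
#' Pearson chi-squared test.
#'
#' @param mutated Per-sample 0/1 status.
#' @param group Per-sample group labels (two levels).
#' @param weights Per-sample non-negative weights.
#' @return List `statistic`, `p_value`, `table` (effective-size-rescaled
#'   2x2), `weighted_freq` (named per-group weighted mutation frequencies).
#' @export
weighted_chisq <- function(mutated, group, weights = NULL) {
  weights <- weights %||% rep(1, length(mutated))
  stopifnot(length(mutated) == length(group),
            length(weights) == length(mutated))
  gl <- sort(unique(as.character(group)))
  if (length(gl) != 2) stop_data("exactly two groups required")
  tab <- matrix(0, 2, 2, dimnames = list(gl, c("wildtype", "mutated")))
  freq <- stats::setNames(numeric(2), gl)
  for (k in 1:2) {
    sel <- group == gl[k]
    w <- weights[sel]; x <- mutated[sel]
    sw <- sum(w)
    if (sw <= 0) stop_data("group '", gl[k], "' has zero total weight")
    freq[k] <- sum(w * x) / sw
    neff <- effective_n(w)
    tab[k, ] <- c((1 - freq[k]), freq[k]) * neff
  }
  cs <- colSums(tab)
  if (any(cs == 0)) {          # all-mutated or all-wildtype
    return(list(statistic = 0, p_value = 1, table = tab, weighted_freq = freq))
  }
  expected <- outer(rowSums(tab), cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, weighted_freq = freq)
}

#' Detect population-biased mutated genes
#'
#' Runs [weighted_chisq()] per gene (restricted to genes whose raw mutation
#' frequency reaches `min_freq` in at least one group), applies
#' Benjamini-Hochberg FDR control across the tested genes, and labels each
#' gene's bias direction from the weighted frequencies.
#'
#' @param mutations Binary sample x gene matrix.
#' @param patients Patients table.
#' @param propensity Optional precomputed [fit_propensity()] result; fitted
#'   on the fly otherwise.
#' @param covariates Covariates for the propensity model.
#' @param min_freq Frequency floor for a gene to be tested.
#' @param fdr_threshold FDR cutoff for the `significant` flag.
#' @param check Balance check: warn (with a `balanced = FALSE` attribute)
#'   when the weighted propensity scores are not balanced.
#' @return Data.frame (gene, per-group weighted frequencies, statistic,
#'   p_value, fdr, direction, significant), sorted by FDR then statistic,
#'   with attributes `"propensity"` and `"balance"`.
#' @export
race_biased_genes <- function(mutations, patients, propensity = NULL,
                              covariates = DEFAULT_COVARIATES,
                              min_freq = 0.05, fdr_threshold = 0.1,
                              check = TRUE) {
  if (is.null(propensity)) {
    propensity <- fit_propensity(patients, covariates)
  }
  m <- match(patients$sample_id, propensity$sample_id)
  w <- propensity$matching_weight[m]
  grp <- patients$group
  gl <- sort(unique(grp))
  balance <- NULL
  if (check) {
    balance <- check_balance(patients, propensity, covariates)
    if (!balance$balanced) {
      warning("weighted propensity scores not balanced (",
              sprintf("%.1f%%", balance$score_std_diff_after),
              "); interpret results with caution")
    }
  }
  mutations <- mutations[patients$sample_id, , drop = FALSE]
  raw1 <- colMeans(mutations[grp == gl[1], , drop = FALSE])
  raw2 <- colMeans(mutations[grp == gl[2], , drop = FALSE])
  testable <- colnames(mutations)[pmax(raw1, raw2) >= min_freq]
  if (length(testable) == 0) {
    warning("no genes pass the frequency floor; empty result")
    res <- data.frame(gene = character(0), freq_1 = numeric(0),
                      freq_2 = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      direction = character(0), significant = logical(0))
    names(res)[2:3] <- paste0("freq_", tolower(gl))
    return(res)
  }
  tests <- lapply(testable, function(g) {
    weighted_chisq(mutations[, g], grp, w)
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  stat <- vapply(tests, `[[`, numeric(1), "statistic")
  f1 <- vapply(tests, function(t) t$weighted_freq[[gl[1]]], numeric(1))
  f2 <- vapply(tests, function(t) t$weighted_freq[[gl[2]]], numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(f1 == f2, "none",
                      ifelse(f1 > f2,
                             paste0(tolower(gl[1]), "_higher"),
                             paste0(tolower(gl[2]), "_higher")))
  res <- data.frame(gene = testable, freq_1 = f1, freq_2 = f2,
                    statistic = stat, p_value = p, fdr = fdr,
                    direction = direction,
                    significant = fdr <= fdr_threshold,
                    stringsAsFactors = FALSE)
  names(res)[2:3] <- paste0("freq_", tolower(gl))
  res <- res[order(res$fdr, -res$statistic, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "propensity") <- propensity
  attr(res, "balance") <- balance
  res
}

#' Permutation validation of the biased-gene count
#'
#' Shuffles the group labels, refits the propensity model and reruns the
#' full biased-gene scan per permutation, recording the number of
#' FDR-significant genes. The empirical p-value is
#' `(1 + #permutations >= observed) / (n_perm + 1)`. Permutations that fail
#' (e.g. separation in the refitted model) are redrawn and counted in
#' attribute `"n_resampled"`.
#'
#' @inheritParams race_biased_genes
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return List `observed_significant`, `permuted_counts`, `empirical_p`.
#' @export
permutation_significance <- function(mutations, patients, n_perm = 100,
                                     seed = 1,
                                     covariates = DEFAULT_COVARIATES,
                                     min_freq = 0.05, fdr_threshold = 0.1) {
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  seed <- assert_seed(seed)
  obs <- race_biased_genes(mutations, patients, covariates = covariates,
                           min_freq = min_freq,
                           fdr_threshold = fdr_threshold, check = FALSE)
  observed <- sum(obs$significant)
  counts <- integer(n_perm)
  n_resampled <- 0L
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    repeat {
      perm <- patients
      perm$group <- sample(perm$group)
      res <- tryCatch(
        race_biased_genes(mutations, perm, covariates = covariates,
                          min_freq = min_freq,
                          fdr_threshold = fdr_threshold, check = FALSE),
        error = function(e) NULL)
      if (!is.null(res)) break
      n_resampled <- n_resampled + 1L
      message("permutation ", i, " failed; resampled")
    }
    counts[i] <- sum(res$significant)
  }
  out <- list(observed_significant = observed,
              permuted_counts = counts,
              empirical_p = (1 + sum(counts >= observed)) / (n_perm + 1))
  attr(out, "n_resampled") <- n_resampled
  out
}
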