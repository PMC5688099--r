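# raceblend

Cross-population comparison of somatic mutation frequencies with explicit
control of technical and biological confounders.

Comparing tumor mutation frequencies between patient populations (say, an
Asian and a Caucasian cohort of esophageal squamous cell carcinoma) is
confounded twice: cohorts sequenced at different depths detect mutations
with different sensitivity, and clinical covariates that influence mutation
status — age, gender, tumor stage, smoking and alcohol history — are
distributed differently across cohorts. `raceblend` is for analysts who
need that comparison done defensibly, and for methodologists who want the
machinery testable end to end without controlled-access sequencing data.

## What it computes

**Depth harmonization.** Per exon, read counts of every cohort are
binomially thinned to the minimum cohort depth (fraction = min depth /
cohort depth), the thin-and-call cycle is repeated 10 times, and only
mutations called in ≥ 8 iterations are kept (consensus calls). Balance is
measured by the pooled-variance standardized difference,
100·|d₁−d₂|/√((v₁+v₂)/2) < 10% for every cohort pair per exon. Upstream
filters: ≥ 2 callers per record, and removal of sites variant in more than
one panel normal.

**Propensity adjustment.** With *e* the logistic-regression propensity of
the reference group given the covariates, each sample gets the matching
weight

    w = min(e, 1 − e) / P(own group)

which emulates 1:1 matching without discarding samples. When the weighted
propensity scores have standardized difference < 10%, per-gene frequencies
are compared with a weighted chi-squared test: the weighted 2×2 table is
rescaled to each group's effective sample size n_eff = (Σw)²/Σw² and the
Pearson statistic referred to χ²₁ (with unit weights this is exactly the
classical test). Benjamini–Hochberg FDR ≤ 0.1 flags population-biased
genes; label permutation with full propensity refit validates the count of
discoveries.

**Companions.** Hudson's two-population Fst, coverage-filtered 0/1/2
genotype coding with Ward hierarchical clustering, exact fixed-margin
mutual-exclusivity tests, Kaplan–Meier/log-rank survival (capped at 36
months), and the paired Wilcoxon signed-rank test for carrier vs
non-carrier expression. A synthetic three-cohort generator reproduces the
covariate skews, depth asymmetry, injected biased genes and a coupled
high-Fst germline SNP, so every stage ships with property-based tests.

## Worked example

```r
library(raceblend)

specs     <- two_group_specs(n_per_group = 200)   # study-skewed covariates
patients  <- generate_clinical(specs, seed = 1)
effects   <- c(biased_gene_effects(),             # 6 injected biased genes
               list(confounded_null_gene()))      # covariate-driven null
mutations <- generate_mutation_matrix(patients, effects,
                                      n_background_genes = 50,
                                      background_rate = 0.08, seed = 2)

propensity <- fit_propensity(patients)
check_balance(patients, propensity)
```

```
Balance report (threshold 10%)
 covariate   level std_diff_before std_diff_after
       age                    29.3         2.8448
    gender    male            37.5         2.5512
     stage      II            68.2         0.3340
   smoking    ever            21.5         3.8490
   alcohol     yes            20.3         0.4369
   ...
Weighted propensity-score standardized difference: 3.64% (balanced)
```

Raw covariate imbalances of 20–68% standardized difference collapse below
4% after matching-weight adjustment; the weighted propensity scores differ
by 3.64%, i.e. the cohorts are balanced and the per-gene test is licensed.

```r
results <- race_biased_genes(mutations, patients)
head(results, 7)
```

```
      gene freq_asian freq_caucasian statistic  p_value      fdr        direction significant
1    EP300      0.365         0.1127     24.03 9.47e-07 5.40e-05     asian_higher        TRUE
2    LRFN5      0.068         0.2704     21.53 3.48e-06 9.93e-05 caucasian_higher        TRUE
3     MAP2      0.115         0.3160     17.48 2.90e-05 5.51e-04 caucasian_higher        TRUE
4   NFE2L2      0.316         0.1135     16.73 4.31e-05 5.71e-04     asian_higher        TRUE
5     TP53      0.266         0.0801     16.44 5.01e-05 5.71e-04     asian_higher        TRUE
6 KRTAP9-1      0.125         0.3037     13.75 2.09e-04 1.99e-03 caucasian_higher        TRUE
7   BG0040      0.122         0.0525      4.16 4.14e-02 3.37e-01     asian_higher       FALSE
```

All six injected genes are recovered at FDR < 0.1 with the correct
direction; the covariate-driven null gene and the 50 background genes are
not flagged. `freq_asian`/`freq_caucasian` are the *weighted* mutation
frequencies; `statistic` is the effective-sample-size-rescaled chi-squared.

The full pipeline — generation, harmonization, comparison, germline and
association stages, with every intermediate table, a manifest and a summary
written to disk — runs as

```r
run_pipeline(run_config(base_seed = 7), "run1")
```

or from a shell via the thin wrapper `inst/cli/raceblend.R`.

## Vignette

`vignettes/methods.Rmd` documents the statistical model, every tunable
threshold with its default and rationale, what the synthetic generator does
and does not emulate, numerical edge-case policies, and known limitations.
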