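---
title: "Methods: cross-population comparison of somatic mutation frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-population comparison of somatic mutation frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raceblend)
```

## The problem

Comparing somatic mutation frequencies between patient populations — for
example Asian and Caucasian cohorts with esophageal squamous cell carcinoma —
is confounded twice over. Technically, cohorts sequenced at different depths
have different detection sensitivity, so the deeper cohort's apparent
mutation burden is inflated. Biologically, clinical covariates that
themselves influence mutation status (age at diagnosis, gender, tumor stage,
smoking and alcohol history) are distributed differently across cohorts, so
a raw between-group contrast mixes population effects with covariate
effects. `raceblend` implements both corrections as a reusable, fully
synthetic-testable pipeline: per-exon read downsampling with consensus
calling, then propensity-score matching weights feeding a weighted
chi-squared test per gene.

## Depth harmonization

Per exon and cohort, the mean tumor depth is computed and every cohort is
binomially thinned towards the per-exon minimum:
`fraction = min_depth / cohort_depth`, applied independently to ref and alt
read counts. Thinning at count level is distributionally equivalent to
discarding each read with probability `1 - fraction` for any decision that
depends on counts alone. Because the fractions are derived from the observed
per-exon means, the expected thinned depths are equal by construction and
the residual standardized difference
(`100·|d₁−d₂| / sqrt((v₁+v₂)/2)`, the same pooled-variance form used for
covariate balance) reflects only thinning noise; the conventional target is
<10% for **all** cohort pairs per exon, not just the extremes.

Thinning followed by threshold calling is repeated (default 10 iterations,
seeds `base_seed + i`, recorded in the manifest) and only sites called in at
least 8 of 10 iterations are kept (*consensus calls*). The threshold caller
(minimum alt reads 4, VAF ≥ 0.02, depth ≥ 10, matched-normal alt fraction
≤ 0.05) is a stand-in for a multi-caller ensemble: external callers operate
on reads, which the package deliberately does not model. Its `strand_bias`
flag is accepted but inert, since synthetic counts carry no strand
information. Two upstream filters mirror standard practice: records must be
reported by at least two callers, and sites seen as variant in more than one
panel normal are removed as germline leakage.

Orthogonal-platform validation is summarized by `validation_rate()`: among
discovery calls whose site reaches ≥ 200× on the validation platform, the
percentage confirmed, reported to one decimal.

## Propensity adjustment and the weighted chi-squared test

The propensity score `e` is the fitted probability, from a maximum-likelihood
logistic regression, that a sample belongs to the reference group
(Caucasian) given its covariates. Age enters linearly in years; categorical
covariates are indicator-coded, with "unknown" smoking/alcohol retained as
an explicit third level so no sample is dropped. Each sample then receives
the matching weight

```
w = min(e, 1 − e) / P(own group),
```

i.e. `min(e, 1−e)/e` for reference-group samples and `min(e, 1−e)/(1−e)`
otherwise. Weights lie in (0, 1]: samples whose covariates are equally
plausible in both groups keep weight ≈ 1, samples typical of only their own
group are down-weighted — weighting that emulates 1:1 matching without
discarding anyone. Balance is declared when the weighted standardized
difference of the propensity scores is below 10%; per-covariate
standardized differences before/after weighting are reported alongside.

Fitted probabilities are clipped to `[1e-6, 1 − 1e-6]`. Covariate levels
present in only one group (the study cohorts have several: stage I and the
"unknown" levels occur only in the Caucasian cohort) produce boundary
scores; the clip plus the matching-weight formula drive such samples'
weights towards 0, which is the statistically correct treatment — they have
no counterpart to be matched to. A hard error is raised only on *complete*
separation (residual deviance ≈ 0), where the model itself is degenerate;
the error suggests reducing the covariate set.

Per gene, the weighted 2×2 table of group × mutated is formed from the
weighted frequencies, each group's row rescaled to its effective sample
size `n_eff = (Σw)² / Σw²`, and the Pearson chi-squared statistic computed
with 1 df. The `n_eff` rescaling is this package's explicit construction
choice: weighted counts at face value would overstate the information in
unequally weighted samples and make the test anti-conservative. With unit
weights the procedure reduces *exactly* to the classical uncorrected
Pearson chi-squared — the correctness anchor the test suite asserts.
Genes are screened at a raw frequency floor (`min_freq`, default 0.05, the
conventional display threshold for recurrently mutated genes), p-values are
corrected by Benjamini–Hochberg across the tested genes, and genes at FDR
≤ 0.1 are flagged with their direction taken from the weighted frequencies.
Statistical validity is additionally checked by label permutation: group
labels are shuffled, the propensity model *refit*, the whole scan rerun
(default 100 times), and the observed count of significant genes compared
with the permuted counts, `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`.

## Germline analyses

`hudson_fst()` implements Hudson's two-population estimator,
`[(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)] / [p₁(1−p₂) + p₂(1−p₁)]`,
with allele counts `n` (2× diploid samples). A zero denominator is defined
as 0; negative raw estimates (ordinary sampling noise at low divergence)
are clipped to 0 for reporting while the raw value is retained for audit.
The test suite cross-checks the estimator against an independently coded
Weir–Cockerham (1984) oracle on island-model simulations. Which estimator
the original analysis used is not recoverable; Hudson's is a deliberate,
documented choice (frequency-based, natural for two fixed population
panels), and the oracle comparison bounds the practical difference.

Sample clustering uses Euclidean distance on 0/1/2 genotype codes with Ward
linkage (`ward.D2`), cut at two clusters. Ward is the default rather than
average linkage because average linkage chains on noisy genotype matrices —
in development it occasionally isolated a single outlying sample instead of
splitting the two populations. Both metric and linkage remain arguments;
the contract is cluster recovery, not dendrogram shape. SNPs enter the
matrix only with coverage ≥ 8 in *every* sample and base quality ≥ 15;
carrier status at a single site may instead be inferred from sparse
off-target evidence (callable at ≥ 3 reads, carrier at ≥ 1 alt read — a
deliberately lenient rule for shallow coverage, thresholds exposed).

## Association tests

Pairwise mutual exclusivity uses the exact fixed-margin hypergeometric tail:
the probability of at most the observed co-occurrence count given both
margins. It replaces MCMC-based marginal-probability machinery with an
exact, deterministic equivalent for *pairs*; higher-order exclusivity is
out of scope. Survival contrasts use the Kaplan–Meier product-limit
estimator and the standard aggregated-risk-set log-rank test, with
follow-up administratively censored at 36 months (the cap only recodes
later observations, so earlier risk sets are untouched). Expression
contrasts between variant carriers and non-carriers use the paired Wilcoxon
signed-rank test: exact (via the signed-rank null distribution, or full
2ⁿ sign enumeration when ranks are tied) up to n = 25 informative pairs,
normal approximation with tie and continuity correction above.

## The synthetic generator

Every stage is exercised by `run_pipeline()` on synthetic cohorts built to
carry the statistical structure that matters:

* **Covariate skews.** Cohort compositions follow the observed three-cohort
  ESCC study populations (Caucasian n=39, Vietnamese n=41, Chinese n=78):
  Asian cohorts more male and predominantly stage II; the Caucasian cohort
  older, with stage I/IV and small "unknown" smoking/alcohol fractions.
  These are the real confounding patterns the adjustment must undo.
* **Mutations.** Per sample × gene Bernoulli draws; log-odds =
  logit(group frequency) + covariate modifiers + carrier shift. Covariate
  modifiers are *scenario parameters*, stated in the spec object, so the
  injected confounding is fully auditable; they are not estimates of real
  per-gene covariate effects, which the underlying study does not report.
* **Depth.** Per-exon negative-binomial tumor/normal depths (dispersion 8,
  Poisson as the dispersion → ∞ limit) around cohort means with a shared
  log-normal per-exon capture multiplier (SD 0.25); the Chinese cohort is
  set twice as deep as the others, reproducing the asymmetry the
  harmonization step removes.
* **VAF.** Beta with mean 0.3 and concentration 2 — a substantial subclonal
  tail. This is the regime in which depth genuinely limits sensitivity;
  with tightly clustered clonal VAFs, downsampling would be nearly
  inconsequential.
* **Germline coupling.** One SNP common in the Asian group (alt frequency
  0.40 vs 0.01) under Hardy–Weinberg, whose carriers have 0.25× the odds of
  somatic mutation in the coupled gene and a −0.8 shift in its
  log-expression. 1000 neutral SNPs scatter with Balding–Nichols divergence
  F = 0.03 — enough aggregate signal for two-population clustering (the
  panel is a desk-scale stand-in for a genome-wide common-SNP set) while
  keeping the coupled SNP's Fst (≈ 0.39) clearly the maximum, mirroring a
  locally exceptional high-Fst variant. When the pipeline wires the
  coupling into the coupled gene, the gene's group frequencies are treated
  as target *marginals*: the non-carrier baseline is solved numerically so
  the carriers' reduced odds do not erode the injected between-group bias.
* **Survival.** Exponential event times with uniform administrative
  censoring; a prognostic gene multiplies the hazard (demo: HR 0.5).

What the generator does **not** emulate: raw reads (counts are the lowest
level), strand artifacts, mutational signatures and annotation, linkage
disequilibrium between SNPs, per-gene covariate interactions estimated from
data, and correlated mutations across genes. Passing tests therefore
certify the statistical machinery under the stated generative assumptions,
not performance on any particular real dataset.

## Numerical and test-design choices

Degenerate inputs are given defined outcomes rather than errors wherever a
defined outcome exists: all-mutated/all-wildtype genes give statistic 0 and
p 1; a zero Fst denominator gives 0; empty margins make the exclusivity
test degenerate with p 1; all-zero paired differences give p 1; a zero
assessable-call set makes the validation rate NA with a warning. Errors are
reserved for schema violations (unknown cohort labels, invalid codes,
ref = alt records reported with their line number), zero group weights,
and configuration mistakes, with configuration and data errors carried as
distinct condition classes so the command-line wrapper can map them to
exit codes.

Problem sizes in the test suite are chosen to keep the full run in tens of
seconds while leaving clear margins: type-I calibration uses 1000
replicates at n = 200 per group (binomial SE ≈ 0.007 around 0.05);
parameter recovery uses 20 seeds at n = 500 per group with 6 injected genes
among 200 nulls; harmonization checks use three cohorts of 80 samples and
30 exons; the Fst oracle runs 120 SNPs at four divergence levels; the
clustering check uses the study-sized 158-sample design. Determinism is
part of every contract: all generators and the consensus and permutation
machinery take explicit seeds, and pipeline reruns with the same
configuration are byte-identical.

## Known limitations

The weighted chi-squared construction (effective-sample-size rescaling) is
one reasonable choice among several; the underlying study names the test
but not its variance construction, so numerical agreement with the original
is not guaranteed, only the classical reduction at unit weights. Only
two-group comparisons and the matching-weight scheme are supported (no
stratification or matched-pair variants, no >2-group tests). The Fst
estimator choice is likewise documented rather than confirmed. Carrier
inference from off-target reads ignores base-calling error, so a single
erroneous alt read can mislabel a sample at minimal coverage; raising
`min_alt` trades sensitivity for robustness.
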