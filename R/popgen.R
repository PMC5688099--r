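# Germline-side computations: Hudson's Fst, SNP coverage filtering and
# 0/1/2 coding, hierarchical sample clustering, and carrier-status inference
# from sparse (off-target) read support.

#' Hudson's two-population Fst estimator
#'
#' Per SNP: numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`; the ratio is reported raw and clipped
#' to `[0, 1]` (sampling noise can push the raw estimate below 0). A zero
#' denominator (both populations fixed for the reference allele) is defined
#' as Fst 0.
#'
#' @param p1,p2 Alternate-allele frequencies in each population, in
#'   \[0, 1\].
#' @param n1,n2 Allele counts (2 x diploid samples), each > 1.
#' @param snp_id Optional SNP identifiers.
#' @return Data.frame `snp_id`, `p1`, `p2`, `n1`, `n2`, `fst_raw`, `fst`.
#' @export
hudson_fst <- function(p1, n1, p2, n2, snp_id = NULL) {
  assert_prob(p1, "p1"); assert_prob(p2, "p2")
  if (any(n1 <= 1) || any(n2 <= 1)) {
    stop_data("allele counts must exceed 1 in both populations")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  raw <- ifelse(den == 0, 0, num / den)
  data.frame(
    snp_id = snp_id %||% sprintf("snp%d", seq_along(raw)),
    p1 = p1, p2 = p2, n1 = n1, n2 = n2,
    fst_raw = raw,
    fst = pmin(pmax(raw, 0), 1),
    stringsAsFactors = FALSE
  )
}

#' Fst from a genotype matrix and group labels
#'
#' Computes per-SNP alternate-allele frequencies and allele counts from
#' 0/1/2 genotypes (missing genotypes excluded per SNP) and applies
#' [hudson_fst()] between the two groups.
#'
#' @param genotypes Samples x SNPs matrix of 0/1/2 (NA allowed).
#' @param groups Per-sample group labels (two levels, ordered rows).
#' @return The [hudson_fst()] data.frame, one row per SNP.
#' @export
fst_from_genotypes <- function(genotypes, groups) {
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop_data("exactly two groups required")
  stat <- function(g) {
    sub <- genotypes[groups == g, , drop = FALSE]
    n <- 2 * colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / n
    list(p = p, n = n)
  }
  a <- stat(gl[1]); b <- stat(gl[2])
  hudson_fst(a$p, a$n, b$p, b$n, snp_id = colnames(genotypes))
}

#' Coverage/base-quality filter and 0/1/2 coding of common SNPs
#'
#' Retains a SNP only if its coverage is at least `min_coverage` in every
#' sample (rows failing `min_base_quality` count as uncovered), and returns
#' the wide genotype matrix for the surviving SNPs.
#'
#' @param snp_table Long data.frame with `sample_id`, `snp_id`, `genotype`
#'   (0/1/2), `coverage` and optionally `base_quality`.
#' @param min_coverage Minimum per-sample coverage (default 8).
#' @param min_base_quality Minimum mean base quality (default 15).
#' @return Samples x SNPs integer matrix of the retained SNPs.
#' @export
snp_filter_and_code <- function(snp_table, min_coverage = 8,
                                min_base_quality = 15) {
  cov <- snp_table$coverage
  if (!is.null(snp_table$base_quality)) {
    cov[snp_table$base_quality < min_base_quality] <- 0
  }
  samples <- unique(snp_table$sample_id)
  snps <- unique(snp_table$snp_id)
  covm <- matrix(0, length(samples), length(snps),
                 dimnames = list(samples, snps))
  idx <- cbind(match(snp_table$sample_id, samples),
               match(snp_table$snp_id, snps))
  covm[idx] <- cov
  keep <- colSums(covm >= min_coverage) == length(samples)
  geno <- matrix(NA_integer_, length(samples), length(snps),
                 dimnames = list(samples, snps))
  geno[idx] <- as.integer(snp_table$genotype)
  geno[, keep, drop = FALSE]
}

#' Hierarchical clustering of samples on genotype codes
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage by default;
#' both configurable) of samples on their 0/1/2 genotype vectors, cut into
#' `k` clusters. Ward linkage is the default because it favours compact,
#' balanced clusters and resists the chaining that single/average linkage
#' show on noisy genotype data. Missing genotypes are imputed to the SNP's
#' mean code; samples exceeding `max_missing` missingness abort the
#' clustering.
#'
#' @param genotypes Samples x SNPs matrix of 0/1/2 (NA allowed).
#' @param k Number of clusters to cut (default 2).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param max_missing Maximum tolerated per-sample missing fraction.
#' @param cohorts Optional named cohort labels for the cross-tabulation.
#' @return List `hclust`, `assignment` (named cluster ids), `crosstab`
#'   (cluster x cohort, when cohorts given) and `newick` (dendrogram as a
#'   Newick string).
#' @export
cluster_samples <- function(genotypes, k = 2, metric = "euclidean",
                            linkage = "ward.D2", max_missing = 0.2,
                            cohorts = NULL) {
  if (nrow(genotypes) < 2) stop_data("need at least two samples to cluster")
  miss <- rowMeans(is.na(genotypes))
  if (any(miss > max_missing)) {
    stop_data(sum(miss > max_missing),
              " sample(s) exceed the missing-genotype threshold")
  }
  if (anyNA(genotypes)) {
    mu <- colMeans(genotypes, na.rm = TRUE)
    for (j in which(colSums(is.na(genotypes)) > 0)) {
      genotypes[is.na(genotypes[, j]), j] <- mu[j]
    }
  }
  hc <- stats::hclust(stats::dist(genotypes, method = metric),
                      method = linkage)
  assignment <- stats::cutree(hc, k = k)
  crosstab <- NULL
  if (!is.null(cohorts)) {
    crosstab <- table(cluster = assignment,
                      cohort = cohorts[names(assignment)])
  }
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, assignment = assignment, crosstab = crosstab,
       newick = newick)
}

#' Infer germline carrier status from sparse read support
#'
#' Designed for off-target read evidence: a sample is uncallable below
#' `min_reads` total coverage at the site; otherwise it is a carrier iff at
#' least `min_alt` reads support the alternate allele (lenient by design --
#' off-target coverage is shallow).
#'
#' @param reads Data.frame `sample_id`, `snp_id`, `ref_reads`, `alt_reads`.
#' @param min_reads Minimum total reads for a call (default 3).
#' @param min_alt Minimum alt reads for carrier status (default 1).
#' @return Data.frame `sample_id`, `snp_id`, `status` (carrier /
#'   non-carrier / uncallable), `ref_reads`, `alt_reads`.
#' @export
infer_snp_status <- function(reads, min_reads = 3, min_alt = 1) {
  total <- reads$ref_reads + reads$alt_reads
  status <- ifelse(total < min_reads, "uncallable",
                   ifelse(reads$alt_reads >= min_alt, "carrier", "non-carrier"))
  data.frame(sample_id = reads$sample_id, snp_id = reads$snp_id,
             status = status, ref_reads = reads$ref_reads,
             alt_reads = reads$alt_reads, stringsAsFactors = FALSE)
}
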