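# Technical-confounder removal: caller merging, panel-of-normals germline
# filtering, per-exon depth downsampling with repeated re-calling, consensus
# aggregation, and orthogonal-platform validation-rate computation.
#
# Cohorts sequenced at different depths have different mutation detection
# sensitivity; comparing their raw burdens confounds biology with coverage.
# The remedy implemented here thins read counts binomially so that every
# exon has comparable expected depth across cohorts, repeats the thinning +
# calling several times, and keeps only mutations called in most iterations.

#' Threshold caller parameters
#'
#' Parameters of the simple count-threshold somatic caller operating on
#' tumor/normal read counts. The external callers of a production pipeline
#' are out of scope here; this caller provides the same decision surface
#' (alt-read support, VAF, depth, absence of normal support) on count data.
#'
#' @param min_alt_reads Minimum tumor alt reads.
#' @param min_vaf Minimum tumor variant allele fraction, in (0, 1].
#' @param min_depth Minimum tumor depth (ref + alt).
#' @param max_normal_vaf Maximum alt fraction tolerated in the matched
#'   normal before the site is considered germline.
#' @param strand_bias Accepted for interface compatibility; synthetic counts
#'   carry no strand information, so this flag is a documented no-op.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(min_alt_reads = 4, min_vaf = 0.02, min_depth = 10,
                          max_normal_vaf = 0.05, strand_bias = FALSE) {
  if (min_vaf <= 0 || min_vaf > 1) stop_config("min_vaf must be in (0, 1]")
  if (min_alt_reads < 0 || min_depth < 0) stop_config("counts must be >= 0")
  structure(list(min_alt_reads = min_alt_reads, min_vaf = min_vaf,
                 min_depth = min_depth, max_normal_vaf = max_normal_vaf,
                 strand_bias = strand_bias),
            class = "caller_params")
}

#' Keep mutations reported by at least `min_callers` callers
#'
#' @param records Mutation records whose `callers` column holds
#'   semicolon-separated caller names.
#' @param min_callers Minimum number of distinct callers (default 2).
#' @return The filtered records.
#' @export
merge_callers <- function(records, min_callers = 2) {
  if (nrow(records) == 0) return(records)
  sets <- strsplit(as.character(records$callers), ";", fixed = TRUE)
  n_callers <- vapply(sets, function(s) length(unique(s[nzchar(s)])), integer(1))
  if (any(n_callers == 0)) {
    stop_data("record(s) with empty caller set at row(s) ",
              paste(utils::head(which(n_callers == 0), 5), collapse = ", "))
  }
  records[n_callers >= min_callers, , drop = FALSE]
}

#' Panel-of-normals germline filter
#'
#' Removes records at sites observed as variant in more than `max_normals`
#' normal samples (sites seen in a single normal are retained). The removed
#' records are attached as attribute `"removed"` for auditing.
#'
#' @param records Mutation records.
#' @param normal_calls Data.frame of per-normal variant sites with columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param max_normals Maximum number of normals a site may appear in.
#' @return Filtered records with attribute `"removed"`.
#' @export
filter_germline_panel <- function(records, normal_calls, max_normals = 1) {
  if (is.null(normal_calls) || nrow(normal_calls) == 0) {
    attr(records, "removed") <- records[0, , drop = FALSE]
    return(records)
  }
  uniq <- unique(normal_calls[c("sample_id", "chrom", "pos", "ref", "alt")])
  tab <- table(site_key(uniq, with_sample = FALSE))
  flagged <- names(tab)[tab > max_normals]
  drop <- site_key(records, with_sample = FALSE) %in% flagged
  out <- records[!drop, , drop = FALSE]
  attr(out, "removed") <- records[drop, , drop = FALSE]
  out
}

#' Call variant sites in normal samples
#'
#' Simple screen used to build the panel of normals from count data: a
#' normal is considered variant at a site if it shows at least
#' `min_alt` alt reads at alt fraction `min_vaf` or more.
#'
#' @param counts Site read-count table.
#' @param min_alt Minimum normal alt reads.
#' @param min_vaf Minimum normal alt fraction.
#' @return Data.frame of per-normal variant sites.
#' @export
call_normals <- function(counts, min_alt = 2, min_vaf = 0.05) {
  dep <- counts$n_ref + counts$n_alt
  hit <- counts$n_alt >= min_alt & dep > 0 & counts$n_alt / pmax(dep, 1) >= min_vaf
  counts[hit, c("sample_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
}

#' Per-exon mean depth by cohort
#'
#' @param counts Site read-count table.
#' @param patients Patients table mapping `sample_id` to `cohort`.
#' @return Data.frame `exon_id`, `cohort`, `mean_depth`.
#' @export
exon_depths <- function(counts, patients) {
  cohort <- patients$cohort[match(counts$sample_id, patients$sample_id)]
  if (anyNA(cohort)) stop_data("read counts reference unknown sample ids")
  depth <- counts$t_ref + counts$t_alt
  agg <- stats::aggregate(depth,
                          by = list(exon_id = counts$exon_id, cohort = cohort),
                          FUN = mean)
  names(agg)[3] <- "mean_depth"
  agg[order(agg$exon_id, agg$cohort), , drop = FALSE]
}

#' Compute per-cohort, per-exon downsampling fractions
#'
#' For each exon the cohort with the lowest mean depth keeps all its reads
#' (fraction 1); every other cohort is thinned to that minimum, so that the
#' expected thinned mean depths are equal (standardized difference 0, well
#' under the 10% balance target). Exons absent in at least one cohort are
#' excluded and reported in attribute `"excluded_exons"`.
#'
#' @param depths Data.frame `exon_id`, `cohort`, `mean_depth` (from
#'   [exon_depths()]).
#' @return Data.frame `exon_id`, `cohort`, `fraction` with the exclusion
#'   attribute.
#' @export
compute_downsampling_fractions <- function(depths) {
  if (any(depths$mean_depth <= 0)) stop_config("depths must be > 0")
  cohorts <- unique(depths$cohort)
  cnt <- table(depths$exon_id)
  excluded <- names(cnt)[cnt < length(cohorts)]
  keep <- !depths$exon_id %in% excluded
  d <- depths[keep, , drop = FALSE]
  min_by_exon <- tapply(d$mean_depth, d$exon_id, min)
  frac <- pmin(1, unname(min_by_exon[as.character(d$exon_id)]) / d$mean_depth)
  out <- data.frame(exon_id = d$exon_id, cohort = d$cohort, fraction = frac,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_exons") <- excluded
  out
}

#' Per-exon pairwise standardized depth differences between cohorts
#'
#' For every exon and every pair of cohorts, the standardized difference
#' (percent) of the per-sample tumor depths -- the balance diagnostic the
#' downsampling step must drive below 10% for all pairs, not just the
#' extremes.
#'
#' @param counts Site read-count table (raw or thinned).
#' @param patients Patients table.
#' @return Data.frame `exon_id`, `cohort_a`, `cohort_b`, `std_diff`.
#' @export
depth_std_diff <- function(counts, patients) {
  cohort <- patients$cohort[match(counts$sample_id, patients$sample_id)]
  depth <- counts$t_ref + counts$t_alt
  cohorts <- sort(unique(cohort))
  rows <- list()
  for (ex in unique(counts$exon_id)) {
    sel <- counts$exon_id == ex
    for (i in seq_along(cohorts)) for (j in seq_along(cohorts)) {
      if (i >= j) next
      d1 <- depth[sel & cohort == cohorts[i]]
      d2 <- depth[sel & cohort == cohorts[j]]
      if (length(d1) < 2 || length(d2) < 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = ex, cohort_a = cohorts[i], cohort_b = cohorts[j],
        std_diff = standardized_difference(d1, d2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

resolve_fractions <- function(counts, fraction, patients = NULL) {
  if (is.data.frame(fraction)) {
    if (is.null(patients)) {
      stop_config("patients required to map samples to cohorts for a fraction table")
    }
    cohort <- patients$cohort[match(counts$sample_id, patients$sample_id)]
    key <- paste(counts$exon_id, cohort, sep = "\r")
    fkey <- paste(fraction$exon_id, fraction$cohort, sep = "\r")
    f <- fraction$fraction[match(key, fkey)]
    f[is.na(f)] <- 1   # exons without a computed fraction are left untouched
    f
  } else {
    rep_len(fraction, nrow(counts))
  }
}

#' Binomially thin tumor read counts
#'
#' Each of `t_ref` and `t_alt` is independently replaced by a
#' Binomial(count, fraction) draw -- the count-level equivalent of discarding
#' each read with probability `1 - fraction`. Normal counts are untouched.
#'
#' @param counts Site read-count table.
#' @param fraction Either a scalar/vector of per-site fractions in (0, 1],
#'   or a fraction table from [compute_downsampling_fractions()] (then
#'   `patients` is required).
#' @param seed Integer seed.
#' @param patients Patients table (only for fraction tables).
#' @return The counts with thinned `t_ref` / `t_alt`.
#' @export
thin_counts <- function(counts, fraction, seed, patients = NULL) {
  seed <- assert_seed(seed)
  f <- resolve_fractions(counts, fraction, patients)
  if (any(f <= 0 | f > 1)) stop_config("fractions must be in (0, 1]")
  set.seed(seed)
  thin1 <- f < 1
  out <- counts
  out$t_ref[thin1] <- stats::rbinom(sum(thin1), counts$t_ref[thin1], f[thin1])
  out$t_alt[thin1] <- stats::rbinom(sum(thin1), counts$t_alt[thin1], f[thin1])
  out
}

#' Threshold somatic caller on count data
#'
#' A site is called iff tumor alt reads, tumor VAF and tumor depth meet
#' their thresholds and the matched normal's alt fraction stays below the
#' germline ceiling. Zero tumor depth is never called.
#'
#' @param counts Site read-count table.
#' @param params A [caller_params()] object.
#' @return Logical vector, one entry per row of `counts`.
#' @export
call_site <- function(counts, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  tdep <- counts$t_ref + counts$t_alt
  ndep <- counts$n_ref + counts$n_alt
  nvaf <- ifelse(ndep > 0, counts$n_alt / ndep, 0)
  tdep > 0 &
    counts$t_alt >= params$min_alt_reads &
    counts$t_alt / pmax(tdep, 1) >= params$min_vaf &
    tdep >= params$min_depth &
    nvaf <= params$max_normal_vaf
}

#' Consensus mutation calls over repeated downsampling iterations
#'
#' Runs thin-then-call `n_iterations` times with distinct seeds
#' (`base_seed + i` by default) and reports, per candidate site (tumor alt
#' reads > 0 before thinning), how many iterations called it; consensus
#' requires at least `min_times` calls.
#'
#' @param counts Site read-count table.
#' @param fractions Fraction table from [compute_downsampling_fractions()],
#'   or a scalar fraction.
#' @param patients Patients table.
#' @param params A [caller_params()].
#' @param n_iterations Number of downsampling iterations.
#' @param min_times Minimum calls for consensus (<= `n_iterations`).
#' @param base_seed Base seed; iteration i uses `base_seed + i`.
#' @param seeds Optional explicit per-iteration seeds (must be distinct).
#' @return Data.frame of candidate sites with `times_called` and logical
#'   `consensus`.
#' @export
consensus_calls <- function(counts, fractions, patients,
                            params = caller_params(),
                            n_iterations = 10, min_times = 8,
                            base_seed = 1, seeds = NULL) {
  if (n_iterations < min_times) {
    stop_config("n_iterations must be >= min_times")
  }
  if (is.null(seeds)) seeds <- assert_seed(base_seed) + seq_len(n_iterations)
  if (length(seeds) != n_iterations) {
    stop_config("need exactly one seed per iteration")
  }
  if (anyDuplicated(seeds)) stop_config("duplicate iteration seeds")
  cand <- counts[counts$t_alt > 0, , drop = FALSE]
  times <- integer(nrow(cand))
  for (i in seq_len(n_iterations)) {
    thinned <- thin_counts(cand, fractions, seed = seeds[i], patients = patients)
    times <- times + call_site(thinned, params)
  }
  out <- cand[c("sample_id", "chrom", "pos", "ref", "alt", "gene", "exon_id")]
  out$times_called <- times
  out$consensus <- times >= min_times
  rownames(out) <- NULL
  out
}

#' True-positive validation rate against an orthogonal platform
#'
#' Discovery calls are assessed only where the validation platform has
#' adequate depth (default >= 200x); the rate is the percentage of assessed
#' calls confirmed by the validation platform, reported to one decimal.
#'
#' @param wes_calls Data.frame of discovery calls (`sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param targeted Data.frame of validation-platform results with the same
#'   site columns plus `depth` and logical `called`.
#' @param min_targeted_depth Minimum validation depth for a site to be
#'   assessable.
#' @return List `n_assessed`, `n_confirmed`, `rate_percent` (NA with a
#'   warning when nothing is assessable).
#' @export
validation_rate <- function(wes_calls, targeted, min_targeted_depth = 200) {
  key_w <- site_key(wes_calls)
  deep <- targeted[targeted$depth >= min_targeted_depth, , drop = FALSE]
  key_deep <- site_key(deep)
  assessed <- key_w %in% key_deep
  confirmed_keys <- site_key(deep[deep$called, , drop = FALSE])
  n_assessed <- sum(assessed)
  if (n_assessed == 0) {
    warning("no discovery calls assessable at the required validation depth")
    return(list(n_assessed = 0L, n_confirmed = 0L, rate_percent = NA_real_))
  }
  n_confirmed <- sum(key_w[assessed] %in% confirmed_keys)
  list(n_assessed = n_assessed, n_confirmed = n_confirmed,
       rate_percent = round(100 * n_confirmed / n_assessed, 1))
}
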