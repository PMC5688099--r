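# Caller merging, germline panel filter, binomial thinning, threshold
# calling, consensus aggregation and the validation-rate computation.

site_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("caller-agreement filter keeps only multi-caller records", {
  rec <- site_df(sample_id = "S1", gene = "G", chrom = "1", pos = 1:3,
                 ref = "C", alt = "T", classification = "missense",
                 callers = c("mutect2", "mutect2;muse",
                             "mutect2;muse;radia;varscan2;somaticsniper"),
                 vaf = 0.3)
  expect_equal(merge_callers(rec)$pos, 2:3)
  expect_equal(merge_callers(rec, min_callers = 1), rec)
  rec$callers[1] <- ""
  expect_error(merge_callers(rec), "empty caller set")
})

test_that("panel-of-normals removes sites seen in more than one normal", {
  rec <- site_df(sample_id = c("T1", "T2", "T3"), chrom = "1",
                 pos = c(10L, 20L, 30L), ref = "C", alt = "T")
  normals <- site_df(sample_id = c("N1", "N2", "N1"), chrom = "1",
                     pos = c(10L, 10L, 20L), ref = "C", alt = "T")
  out <- filter_germline_panel(rec, normals)
  expect_equal(out$pos, c(20L, 30L))          # pos 10 in 2 normals: removed
  expect_equal(attr(out, "removed")$pos, 10L) # pos 20 in exactly 1: kept
  expect_equal(filter_germline_panel(rec, normals[0, ])$pos, rec$pos)
})

test_that("downsampling fractions equalize expected depths", {
  eq <- data.frame(exon_id = "e1", cohort = c("A", "B"), mean_depth = c(120, 120))
  expect_true(all(compute_downsampling_fractions(eq)$fraction == 1))

  two <- data.frame(exon_id = "e1", cohort = c("A", "B"), mean_depth = c(200, 100))
  fr <- compute_downsampling_fractions(two)
  expect_equal(fr$fraction[fr$cohort == "A"], 0.5)
  expect_equal(fr$fraction[fr$cohort == "B"], 1)

  holes <- data.frame(exon_id = c("e1", "e1", "e2"),
                      cohort = c("A", "B", "A"),
                      mean_depth = c(200, 100, 50))
  fr <- compute_downsampling_fractions(holes)
  expect_equal(attr(fr, "excluded_exons"), "e2")
  expect_false("e2" %in% fr$exon_id)
})

test_that("thinning matches binomial moments and never increases counts", {
  cnt <- site_df(sample_id = "S", chrom = "1", pos = 1:5000, ref = "C",
                 alt = "T", exon_id = "e", t_ref = 200L, t_alt = 100L,
                 n_ref = 50L, n_alt = 0L)
  thin <- thin_counts(cnt, 0.5, seed = 99)
  expect_lt(abs(mean(thin$t_alt) - 50), 3 * sqrt(25 / 5000))
  expect_lt(abs(var(thin$t_alt) - 25), 3)
  expect_true(all(thin$t_alt <= cnt$t_alt & thin$t_ref <= cnt$t_ref))
  expect_identical(thin_counts(cnt, 1, seed = 1), cnt)
  cnt$t_alt <- 0L
  expect_true(all(thin_counts(cnt, 0.3, seed = 2)$t_alt == 0L))
  expect_error(thin_counts(cnt, 0, seed = 1), "fractions")
})

test_that("threshold caller applies every rule", {
  params <- caller_params(min_alt_reads = 4, min_vaf = 0.05, min_depth = 20)
  base <- site_df(sample_id = "S", chrom = "1", pos = 1L, ref = "C", alt = "T",
                  t_ref = 90L, t_alt = 10L, n_ref = 60L, n_alt = 0L)
  expect_true(call_site(base, params))
  zero <- base; zero$t_alt <- 0L
  expect_false(call_site(zero, params))
  shallow <- base; shallow$t_ref <- 5L; shallow$t_alt <- 10L
  expect_false(call_site(shallow, params))      # depth 15 < 20 despite VAF 0.67
  empty <- base; empty$t_ref <- 0L; empty$t_alt <- 0L
  expect_false(call_site(empty, params))        # zero depth, no division error
  germ <- base; germ$n_alt <- 30L
  expect_false(call_site(germ, params))
})

test_that("consensus is deterministic without thinning randomness", {
  params <- caller_params()
  cnt <- site_df(sample_id = c("S1", "S2"), chrom = "1", pos = c(1L, 2L),
                 ref = "C", alt = "T", gene = "G", exon_id = "e",
                 t_ref = c(100L, 100L), t_alt = c(50L, 1L),
                 n_ref = 100L, n_alt = 0L)
  patients <- data.frame(sample_id = c("S1", "S2"), cohort = "Chinese",
                         stringsAsFactors = FALSE)
  res <- consensus_calls(cnt, 1, patients, params, base_seed = 3)
  expect_true(all(res$times_called %in% c(0L, 10L)))
  expect_equal(res$consensus, c(TRUE, FALSE))
  expect_error(consensus_calls(cnt, 1, patients, params,
                               seeds = c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9)),
               "duplicate")
  expect_error(consensus_calls(cnt, 1, patients, params, n_iterations = 5,
                               min_times = 8), "min_times")
})

test_that("sites far above threshold survive thinning with near-certainty", {
  # expected post-thinning alt reads 40 >> min_alt 4: consensus essentially sure
  params <- caller_params()
  cnt <- site_df(sample_id = "S1", chrom = "1", pos = 1L, ref = "C", alt = "T",
                 gene = "G", exon_id = "e", t_ref = 120L, t_alt = 80L,
                 n_ref = 100L, n_alt = 0L)
  patients <- data.frame(sample_id = "S1", cohort = "Chinese",
                         stringsAsFactors = FALSE)
  hits <- vapply(1:50, function(s) {
    consensus_calls(cnt, 0.5, patients, params, base_seed = s * 17)$consensus
  }, logical(1))
  expect_true(all(hits))
})

test_that("validation rate handles full, zero and empty overlap", {
  wes <- site_df(sample_id = "S", chrom = "1", pos = 1:10, ref = "C", alt = "T")
  targ <- site_df(sample_id = "S", chrom = "1", pos = 1:10, ref = "C",
                  alt = "T", depth = 300L, called = TRUE)
  expect_equal(validation_rate(wes, targ)$rate_percent, 100.0)
  targ$called <- FALSE
  expect_equal(validation_rate(wes, targ)$rate_percent, 0.0)
  targ$depth <- 50L
  expect_warning(res <- validation_rate(wes, targ), "assessable")
  expect_true(is.na(res$rate_percent))
})
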