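# Downstream association tests: pairwise mutual exclusivity, Kaplan-Meier /
# log-rank survival comparison, and the paired signed-rank test used for
# carrier-vs-non-carrier expression contrasts.

#' One-sided mutual-exclusivity test for two binary alterations
#'
#' Exact fixed-margin (hypergeometric) tail test: the p-value is the
#' probability, under independence with both margins fixed, of observing at
#' most the observed number of co-occurrences. Small values indicate the two
#' alterations overlap less than expected, i.e. mutual exclusivity. Samples
#' with missing status in either feature are excluded first; a zero margin
#' makes the test degenerate (p = 1).
#'
#' @param a,b Per-sample 0/1 vectors over the same sample universe (NA =
#'   not evaluable).
#' @return List `table` (2x2 co-occurrence counts), `n`, `p_value`,
#'   `degenerate`.
#' @export
exclusivity_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- as.integer(a[ok] > 0); b <- as.integer(b[ok] > 0)
  n <- length(a)
  ka <- sum(a); kb <- sum(b); k <- sum(a & b)
  tab <- matrix(c(sum(!a & !b), sum(!a & b), sum(a & !b), k), 2, 2,
                dimnames = list(a = c("0", "1"), b = c("0", "1")))
  if (ka == 0 || kb == 0 || ka == n || kb == n) {
    return(list(table = tab, n = n, p_value = 1, degenerate = TRUE))
  }
  p <- stats::phyper(k, ka, n - ka, kb)
  list(table = tab, n = n, p_value = p, degenerate = FALSE)
}

#' Kaplan-Meier curves and two-group log-rank test with follow-up cap
#'
#' Follow-up beyond `cap_months` is administratively censored at the cap,
#' then the product-limit estimator is computed per group and the standard
#' two-group log-rank statistic (observed vs expected events over the
#' pooled risk sets, aggregated over tied event times) is referred to a
#' chi-squared distribution with 1 df.
#'
#' @param times Non-negative follow-up times (months).
#' @param events 1 = death observed, 0 = censored.
#' @param group Per-sample two-level grouping (e.g. mutated vs wild-type).
#' @param cap_months Follow-up cap (default 36; NULL disables).
#' @return List `curves` (data.frame `group`, `time`, `n_risk`, `n_event`,
#'   `estimate`), `statistic`, `p_value`.
#' @export
km_logrank <- function(times, events, group, cap_months = 36) {
  if (any(times < 0)) stop_data("negative follow-up time")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop_data("exactly two non-empty groups required")
  }
  if (!is.null(cap_months)) {
    events <- ifelse(times > cap_months, 0L, events)
    times <- pmin(times, cap_months)
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata_id),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    estimate = fit$surv, stringsAsFactors = FALSE
  )
  if (sum(events) == 0) {
    return(list(curves = curves, statistic = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(curves = curves, statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' dropped; with 25 or fewer informative pairs and untied ranks the exact
#' signed-rank null distribution is used, otherwise a normal approximation
#' with tie correction and continuity correction. All-zero differences give
#' a degenerate p of 1.
#'
#' @param x,y Paired measurements of equal length.
#' @return List `statistic` (positive-rank sum V), `n` (informative pairs),
#'   `p_value`, `exact`, `degenerate`.
#' @export
paired_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0L, p_value = 1, exact = TRUE,
                degenerate = TRUE))
  }
  if (n < 3) {
    warning("fewer than 3 informative pairs; test has no power")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (n <= 25 && !ties) {
    p_low <- stats::psignrank(V, n)
    p_high <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(statistic = V, n = n, p_value = p, exact = TRUE,
                degenerate = FALSE))
  }
  if (n <= 12) {
    # tied ranks but still enumerable: exact distribution over all 2^n signs
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(V_all <= V), mean(V_all >= V)))
    return(list(statistic = V, n = n, p_value = p, exact = TRUE,
                degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, n = n, p_value = p, exact = FALSE, degenerate = FALSE)
}
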