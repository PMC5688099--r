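# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_config <- function(...) {
  stop(structure(
    class = c("raceblend_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
stop_data <- function(...) {
  stop(structure(
    class = c("raceblend_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(what, " must lie in [0, 1]")
  }
  invisible(x)
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("'seed' must be a single integer")
  }
  as.integer(seed)
}

# Weighted mean and (population-form) weighted variance, used by the
# standardized-difference machinery.
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Effective sample size of a weight vector: (sum w)^2 / sum w^2.
effective_n <- function(w) sum(w)^2 / sum(w^2)

# Fixed cohort -> super-population mapping used throughout.
COHORT_GROUPS <- c(Chinese = "Asian", Vietnamese = "Asian",
                   Caucasian = "Caucasian")

cohort_to_group <- function(cohort) {
  grp <- unname(COHORT_GROUPS[as.character(cohort)])
  if (anyNA(grp)) {
    bad <- unique(as.character(cohort)[is.na(grp)])
    stop_data("unknown cohort label(s): ", paste(bad, collapse = ", "))
  }
  grp
}

# Site key used to match mutation records / read-count rows across tables.
site_key <- function(df, with_sample = TRUE) {
  base <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  if (with_sample) paste(df$sample_id, base, sep = ":") else base
}

# Deterministic TSV writer (fixed quoting/NA conventions so that reruns are
# byte-identical).
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", quote = "", comment.char = "")
}
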