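# Readers/writers for the tabular formats the pipeline touches.
#
# Conventions: tab-separated, header row, 1-based inclusive genomic
# coordinates (MAF convention). Schema violations fail loudly with the
# offending line or column named; nothing is coerced silently.

CLASSIFICATIONS <- c("missense", "nonsense", "nonstop", "silent", "other")
NON_SILENT <- c("missense", "nonsense", "nonstop")

MAF_COLUMNS <- c(Hugo_Symbol = "gene", Chromosome = "chrom",
                 Start_Position = "pos", Reference_Allele = "ref",
                 Tumor_Seq_Allele2 = "alt",
                 Variant_Classification = "classification",
                 Tumor_Sample_Barcode = "sample_id",
                 Callers = "callers", VAF = "vaf")

#' Read somatic mutation records (MAF-dialect TSV)
#'
#' Expected columns: `Hugo_Symbol`, `Chromosome`, `Start_Position` (1-based),
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification` (one of
#' missense, nonsense, nonstop, silent, other), `Tumor_Sample_Barcode`, plus
#' the extensions `Callers` (semicolon-separated caller names, may be empty)
#' and `VAF` (fraction, may be NA for targeted-panel records).
#'
#' @param path File path.
#' @return A data.frame of validated records with internal column names
#'   (`sample_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, `classification`,
#'   `callers`, `vaf`) and a logical `silent` flag.
#' @export
read_mutations <- function(path) {
  raw <- read_tsv_file(path)
  missing_cols <- setdiff(names(MAF_COLUMNS), names(raw))
  if (length(missing_cols)) {
    stop_data("mutation file lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[names(MAF_COLUMNS)], unname(MAF_COLUMNS))
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$vaf <- as.numeric(df$vaf)
  line_no <- seq_len(nrow(df)) + 1L  # account for header
  bad <- which(df$ref == df$alt)
  if (length(bad)) {
    stop_data("ref equals alt at line ", bad[1] + 1L, " of ", path)
  }
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) {
    stop_data("invalid position at line ", line_no[bad[1]], " of ", path)
  }
  bad <- which(!df$classification %in% CLASSIFICATIONS)
  if (length(bad)) {
    stop_data("unknown classification '", df$classification[bad[1]],
              "' at line ", line_no[bad[1]], " of ", path)
  }
  ok <- which(!is.na(df$vaf))
  if (length(ok)) assert_prob(df$vaf[ok], "VAF")
  df$silent <- df$classification == "silent"
  df
}

#' Write somatic mutation records (MAF-dialect TSV)
#'
#' Inverse of [read_mutations()]; the pair round-trips losslessly.
#'
#' @param records Data.frame with internal mutation-record columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mutations <- function(records, path) {
  out <- stats::setNames(records[unname(MAF_COLUMNS)], names(MAF_COLUMNS))
  write_tsv_file(out, path)
}

CLINICAL_COLUMNS <- c("sample_id", "cohort", "age", "gender", "stage",
                      "smoking", "alcohol", "os_months", "os_event")

#' Read a clinical covariate table
#'
#' Validates the closed vocabularies (gender male/female; stage I-IV;
#' smoking ever/never/unknown; alcohol yes/no/unknown), requires known
#' cohort labels (Caucasian, Vietnamese, Chinese) and non-negative survival
#' times, and derives the comparison `group` column (Chinese and Vietnamese
#' form the Asian group).
#'
#' @param path File path.
#' @return A typed, validated patients data.frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_file(path)
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_data("clinical file lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- df[CLINICAL_COLUMNS]
  df$group <- cohort_to_group(df$cohort)   # errors on unknown cohorts
  vocab <- list(gender = c("male", "female"),
                stage = c("I", "II", "III", "IV"),
                smoking = c("ever", "never", "unknown"),
                alcohol = c("yes", "no", "unknown"))
  for (cov in names(vocab)) {
    if (anyNA(df[[cov]])) {
      stop_data("missing values in column '", cov, "' of ", path)
    }
    bad <- setdiff(unique(df[[cov]]), vocab[[cov]])
    if (length(bad)) {
      stop_data("invalid level(s) in column '", cov, "': ",
                paste(bad, collapse = ", "))
    }
  }
  df$age <- as.numeric(df$age)
  df$os_months <- as.numeric(df$os_months)
  df$os_event <- as.integer(df$os_event)
  if (any(is.na(df$os_months)) || any(df$os_months < 0)) {
    stop_data("os_months must be non-negative")
  }
  if (!all(df$os_event %in% c(0L, 1L))) {
    stop_data("os_event must be 0 (censored) or 1 (death)")
  }
  df[c("sample_id", "cohort", "group", setdiff(CLINICAL_COLUMNS,
                                               c("sample_id", "cohort")))]
}

#' Write a clinical covariate table
#' @param patients Patients data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clinical <- function(patients, path) {
  write_tsv_file(patients[CLINICAL_COLUMNS], path)
}

#' Read / write a genotype matrix (samples x SNPs TSV)
#'
#' Codes are 0 (wild-type), 1 (heterozygous), 2 (homozygous alternate) or NA
#' (missing, distinct from 0).
#'
#' @param path File path.
#' @return Integer matrix with sample-id rownames and SNP-id colnames.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_file(path)
  if (names(df)[1] != "sample_id") {
    stop_data("genotype file must start with a sample_id column")
  }
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$sample_id
  storage.mode(mat) <- "integer"
  bad <- mat[!is.na(mat)]
  if (any(!bad %in% 0:2)) stop_data("genotype codes must be 0, 1, 2 or NA")
  mat
}

#' @rdname read_genotypes
#' @param genotypes Samples x SNPs matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Build a binary sample-by-gene mutation matrix from records
#'
#' A sample scores 1 for a gene if at least one qualifying record exists
#' (idempotent over duplicate records). All patients appear as rows, genes
#' observed in the qualifying records as columns.
#'
#' @param records Mutation records (from [read_mutations()] or equivalent).
#' @param patients Patients table; every record's sample id must appear here.
#' @param non_silent_only If TRUE (default), silent records are ignored.
#' @return Integer matrix (samples x genes).
#' @export
build_mutation_matrix <- function(records, patients, non_silent_only = TRUE) {
  orphan <- setdiff(unique(records$sample_id), patients$sample_id)
  if (length(orphan)) {
    stop_data("mutation records reference unknown sample id(s): ",
              paste(orphan, collapse = ", "))
  }
  genes <- sort(unique(records$gene))   # keep all genes as columns,
  if (non_silent_only) {                # even if only silent records remain
    records <- records[records$classification %in% NON_SILENT, ]
  }
  mat <- matrix(0L, nrow(patients), length(genes),
                dimnames = list(patients$sample_id, genes))
  if (nrow(records)) {
    idx <- cbind(match(records$sample_id, patients$sample_id),
                 match(records$gene, genes))
    mat[idx] <- 1L
  }
  mat
}
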