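# Reading, validating and writing GWAS summary statistics as delimited text.

sumstat_columns <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-delimited file with a header, maps columns to the canonical
#' schema, and validates every row. Malformed rows are not silently dropped:
#' each rejected row is returned in the audit with a machine-readable reason.
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Defaults to the
#'   identity mapping.
#' @param sep Field separator (default tab).
#' @return A data frame of validated records with an `audit` attribute
#'   (data frame: `variant_id`, `stage`, `reason`) listing rejected rows.
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_map)) {
    column_map <- stats::setNames(sumstat_columns, sumstat_columns)
  }
  missing_cols <- setdiff(sumstat_columns, names(column_map))
  if (length(missing_cols)) {
    stop("column_map lacks entries for: ", paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(unname(column_map[sumstat_columns]), names(raw))
  if (length(absent)) {
    stop("mandatory columns missing from file: ", paste(absent, collapse = ", "))
  }
  df <- raw[, unname(column_map[sumstat_columns]), drop = FALSE]
  names(df) <- sumstat_columns
  validate_sumstats(df)
}

#' Validate a summary-statistic data frame
#'
#' Coerces numeric columns, upper-cases alleles, and partitions rows into
#' valid records and audited rejections (`nonpositive_se`, `eaf_out_of_range`,
#' `identical_alleles`, `nonfinite_stat`, `pval_out_of_range`).
#'
#' @param df Data frame with the canonical columns.
#' @return Validated data frame with an `audit` attribute.
#' @export
validate_sumstats <- function(df) {
  missing_cols <- setdiff(sumstat_columns, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, sumstat_columns, drop = FALSE]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  bad(!is.finite(df$beta) | !is.finite(df$se) | !is.finite(df$eaf) |
        !is.finite(df$pos) | !is.finite(df$n), "nonfinite_stat")
  bad(df$se <= 0, "nonpositive_se")
  bad(df$eaf <= 0 | df$eaf >= 1, "eaf_out_of_range")
  bad(df$effect_allele == df$other_allele, "identical_alleles")
  bad(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval_out_of_range")

  keep <- is.na(reason)
  audit <- data.frame(
    variant_id = df$variant_id[!keep],
    stage = rep("read", sum(!keep)),
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Write summary statistics as tab-delimited text
#'
#' @param df Summary-statistic data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reference dosage panel as delimited text
#'
#' One header row of variant ids, one row per individual, tab-delimited.
#'
#' @param panel Dosage matrix with variant-id column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a reference dosage panel written by [write_reference_panel()]
#'
#' @param path File path.
#' @return Integer dosage matrix with variant ids as column names.
#' @export
read_reference_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(df)
}
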