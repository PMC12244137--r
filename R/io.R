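## Cohort table readers/writers. Plain CSV/TSV with a one-line header; the
## censoring flag travels as a 0/1 column; numeric columns are written with
## 17 significant digits so the round trip is value-identical.

#' Read and write cohort tables
#'
#' `write_cohort()` writes a cohort as delimited text (comma for `.csv`,
#' tab for `.tsv`/`.txt`) with the censor flag as a 0/1 column;
#' `read_cohort()` reads it back, validates the mandatory columns and
#' invariants (collecting all row-level problems into one error), and passes
#' unknown extra columns through with a message.
#'
#' @param cohort a cohort table.
#' @param path file path; the delimiter is sniffed from the extension.
#' @return `read_cohort()` returns a validated `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$estradiol_censored <- as.integer(as.logical(df$estradiol_censored))
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param loq censoring limit used in consistency checks.
#' @export
read_cohort <- function(path, loq = 0.09) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(cohort_columns(), "estradiol_true",
                                paste0("hamd_", 1:17)))
  if (length(extra)) {
    message("extra column(s) passed through: ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$estradiol_censored %in% c(0L, 1L))) {
    stop("estradiol_censored must be 0/1")
  }
  df$estradiol_censored <- as.logical(df$estradiol_censored)
  for (cn in c(paste0("bp_", c("neostriatum", "hippocampus", "amygdala",
                               "prefrontal")), "testosterone", "estradiol",
               "age", "dose")) {
    if (!is.numeric(df[[cn]])) stop(sprintf("non-numeric column '%s'", cn))
  }
  validate_cohort(df, loq = loq)
  class(df) <- c("cohort_table", "data.frame")
  df
}
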