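#' Read a cohort table
#'
#' Reads a delimited text file (comma-separated, header row) of per-subject
#' demographics, outcome scores, optional diagnosis, and volume file
#' references, mapping arbitrary column names onto the canonical schema used
#' throughout the package: `subject_id`, `age` (years), `gender` (0/1,
#' reference = male), `education` (years), one or more outcome columns,
#' optional `diagnosis` (CN / MCI / Dementia) and `volume_ref`.
#'
#' Rows missing any required field (id or a covariate) are excluded here;
#' the number excluded is reported via `attr(x, "n_excluded")` and a message.
#' Missing *outcome* values are kept and handled complete-case per analysis.
#'
#' @param path CSV file path.
#' @param schema named list mapping canonical names to file column names.
#'   Entries: `subject_id`, `age`, `gender`, `education`, `outcomes`
#'   (character vector), optionally `diagnosis`, `volume_ref`.
#' @return data.frame with canonical column names; attribute `n_excluded`
#'   counts dropped rows.
#' @export
read_cohort <- function(path,
                        schema = list(subject_id = "subject_id", age = "age",
                                      gender = "gender",
                                      education = "education",
                                      outcomes = "outcome")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "gender", "education")
  for (f in req)
    if (is.null(schema[[f]])) stop(sprintf("schema lacks entry '%s'", f))
  mapped <- c(unlist(schema[req]), schema$outcomes,
              schema$diagnosis, schema$volume_ref)
  missing_cols <- setdiff(mapped, names(df))
  if (length(missing_cols))
    stop(sprintf("mapped column(s) not in '%s': %s", path,
                 paste(missing_cols, collapse = ", ")))
  out <- data.frame(subject_id = as.character(df[[schema$subject_id]]),
                    age = as.numeric(df[[schema$age]]),
                    gender = as.numeric(df[[schema$gender]]),
                    education = as.numeric(df[[schema$education]]),
                    stringsAsFactors = FALSE)
  for (oc in schema$outcomes) out[[oc]] <- as.numeric(df[[oc]])
  if (!is.null(schema$diagnosis))
    out$diagnosis <- as.character(df[[schema$diagnosis]])
  if (!is.null(schema$volume_ref))
    out$volume_ref <- as.character(df[[schema$volume_ref]])
  keep <- !is.na(out$subject_id) & nzchar(out$subject_id) &
    is.finite(out$age) & is.finite(out$gender) & is.finite(out$education)
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (anyDuplicated(out$subject_id))
    stop(sprintf("duplicate subject_id in '%s': %s", path,
                 paste(unique(out$subject_id[duplicated(out$subject_id)]),
                       collapse = ", ")))
  rownames(out) <- NULL
  if (n_excluded > 0)
    message(sprintf("read_cohort: excluded %d row(s) with missing required fields",
                    n_excluded))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Complete cases of a cohort for one analysis
#'
#' A subject missing the current outcome or any covariate is dropped for that
#' analysis only.
#'
#' @param cohort cohort data.frame.
#' @param outcome outcome column name.
#' @return row-subset of `cohort` with an attribute `n_excluded`.
#' @export
complete_for_outcome <- function(cohort, outcome) {
  if (!outcome %in% names(cohort))
    stop(sprintf("outcome column '%s' not present in cohort", outcome))
  keep <- is.finite(cohort$age) & is.finite(cohort$gender) &
    is.finite(cohort$education) & is.finite(cohort[[outcome]])
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
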