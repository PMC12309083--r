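#' Median (with range) of a clinical field
#'
#' Standard median — the mean of the two central order statistics for even
#' n — over the non-missing values of `age`, `os` or `pfs`, together with
#' the observed range.
#'
#' @param records a `clinical_cohort` (see [read_clinical_table()]).
#' @param field `"age"`, `"os"` or `"pfs"`.
#' @return List with `median`, `min`, `max`, `n` (non-missing), `n_missing`.
#' @export
median_of <- function(records, field = c("age", "os", "pfs")) {
  field <- match.arg(field)
  stopifnot(inherits(records, "clinical_cohort"))
  v <- records[[field]]
  v <- v[!is.na(v)]
  if (!length(v))
    stop(sprintf("no non-missing values of '%s' to take a median of", field))
  list(median = stats::median(v), min = min(v), max = max(v),
       n = length(v), n_missing = nrow(records) - length(v))
}

#' Sex counts of a cohort
#'
#' @inheritParams median_of
#' @return Named integer vector `c(female = ..., male = ...)`.
#' @export
sex_counts <- function(records) {
  stopifnot(inherits(records, "clinical_cohort"))
  c(female = sum(records$sex == "female"),
    male = sum(records$sex == "male"))
}

#' Cohort descriptive summary
#'
#' Cohort size, sex counts, medians and ranges for age / PFS / OS, a
#' histology frequency table and a localization-by-side cross table. PFS
#' and OS are taken from the table's columns as printed; with
#' `recompute_intervals = TRUE` they are instead re-derived from the
#' year-month diagnosis / recurrence / last-follow-up dates, and rows where
#' the two disagree are listed in `notes` — a cross-check for transcription
#' errors.
#'
#' @inheritParams median_of
#' @param recompute_intervals re-derive PFS/OS in months from the dates.
#' @return A `cohort_summary` object (list; see fields in Details).
#' @export
cohort_summary <- function(records, recompute_intervals = FALSE) {
  stopifnot(inherits(records, "clinical_cohort"))
  if (nrow(records) == 0L) stop("cannot summarise an empty cohort")
  if (anyDuplicated(records$patient))
    stop("duplicate patient ids in cohort")

  notes <- character(0)
  if (recompute_intervals) {
    pfs2 <- records$recurrence_date - records$dx_date
    os2 <- records$last_date - records$dx_date
    diff_rows <- which((!is.na(pfs2) & !is.na(records$pfs) & pfs2 != records$pfs) |
                         (!is.na(os2) & !is.na(records$os) & os2 != records$os))
    for (i in diff_rows)
      notes <- c(notes, sprintf(
        "patient %s: tabulated PFS/OS (%s/%s) differ from date-derived (%s/%s)",
        records$patient[i], records$pfs[i], records$os[i], pfs2[i], os2[i]))
    records$pfs <- pfs2
    records$os <- os2
  }

  out <- list(
    n = nrow(records),
    sex = sex_counts(records),
    age = median_of(records, "age"),
    pfs = if (any(!is.na(records$pfs))) median_of(records, "pfs") else NULL,
    os = if (any(!is.na(records$os))) median_of(records, "os") else NULL,
    histology = table(records$histology),
    localization_by_side = table(records$localization, tolower(records$side)),
    recomputed_intervals = recompute_intervals,
    notes = notes)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d (%d female, %d male)\n",
              x$n, x$sex["female"], x$sex["male"]))
  fmt <- function(m, unit)
    sprintf("median %.1f %s (range %g-%g, n=%d)", m$median, unit, m$min, m$max, m$n)
  cat("  age: ", fmt(x$age, "years"), "\n", sep = "")
  if (!is.null(x$pfs)) cat("  PFS: ", fmt(x$pfs, "months"), "\n", sep = "")
  if (!is.null(x$os)) cat("  OS:  ", fmt(x$os, "months"), "\n", sep = "")
  cat("  histology:\n")
  for (h in names(x$histology))
    cat(sprintf("    %s: %d\n", h, x$histology[[h]]))
  for (note in x$notes) cat("  note: ", note, "\n", sep = "")
  invisible(x)
}

cohort_summary_as_list <- function(x) {
  med <- function(m) if (is.null(m)) NULL else
    list(median = m$median, min = m$min, max = m$max, n = m$n)
  list(n = x$n,
       n_female = unname(x$sex["female"]), n_male = unname(x$sex["male"]),
       age_years = med(x$age), pfs_months = med(x$pfs), os_months = med(x$os),
       histology = as.list(x$histology),
       notes = x$notes)
}
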