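# Column contract for the long-format cohort table.
.mandatory_cols <- c("patient_id", "timepoint", "ftv_cm3", "mtm_per_ml",
                     "ctdna_status")
.known_cols <- c(.mandatory_cols, "age", "treatment_arm", "subtype",
                 "ct_stage", "cn_stage", "grade", "mammaprint", "pcr",
                 "drfs_years", "drfs_event")
.numeric_cols <- c("ftv_cm3", "mtm_per_ml", "age", "pcr", "drfs_years",
                   "drfs_event")

# Minimal structural coercion used by every analysis entry point.
as_cohort_df <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (!is.data.frame(cohort)) stop("'cohort' must be a data frame")
  miss <- setdiff(.mandatory_cols, names(cohort))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  cohort
}

#' Validate a long-format cohort table
#'
#' Checks the structural invariants of the patient-by-timepoint table:
#' known timepoint labels, at most one row per (patient, timepoint), and
#' consistency between ctDNA status and concentration (positive iff
#' MTM/mL > 0 where both are present). Violations are reported, never
#' silently repaired.
#'
#' @param cohort a cohort data frame.
#' @return List of class `cohort_validation`: `n_rows`, `n_patients`,
#'   `rows_per_timepoint`, `missing_per_timepoint` (patients lacking each
#'   timepoint), and `violations` (data frame of row, rule, detail).
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_cohort_df(cohort)
  viol <- list()
  bad_tp <- which(!cohort$timepoint %in% TIMEPOINTS)
  if (length(bad_tp))
    viol[[length(viol) + 1L]] <- data.frame(
      row = bad_tp, rule = "timepoint",
      detail = sprintf("unknown timepoint '%s'", cohort$timepoint[bad_tp]))
  dup <- duplicated(cohort[, c("patient_id", "timepoint")])
  if (any(dup))
    viol[[length(viol) + 1L]] <- data.frame(
      row = which(dup), rule = "duplicate",
      detail = sprintf("duplicate row for %s/%s",
                       cohort$patient_id[dup], cohort$timepoint[dup]))
  both <- !is.na(cohort$ctdna_status) & !is.na(cohort$mtm_per_ml)
  mismatch <- both & ((cohort$ctdna_status == "positive") !=
                        (cohort$mtm_per_ml > 0))
  if (any(mismatch))
    viol[[length(viol) + 1L]] <- data.frame(
      row = which(mismatch), rule = "status_concentration",
      detail = sprintf("ctdna_status '%s' inconsistent with mtm_per_ml %g",
                       cohort$ctdna_status[mismatch],
                       cohort$mtm_per_ml[mismatch]))
  bad_num <- which(!is.na(cohort$ftv_cm3) & cohort$ftv_cm3 < 0)
  if (length(bad_num))
    viol[[length(viol) + 1L]] <- data.frame(
      row = bad_num, rule = "ftv_nonnegative", detail = "negative FTV")

  ids <- unique(cohort$patient_id)
  per_tp <- table(factor(cohort$timepoint, levels = TIMEPOINTS))
  missing_tp <- length(ids) - as.integer(per_tp)
  structure(list(
    n_rows = nrow(cohort),
    n_patients = length(ids),
    rows_per_timepoint = setNames(as.integer(per_tp), TIMEPOINTS),
    missing_per_timepoint = setNames(missing_tp, TIMEPOINTS),
    violations = if (length(viol)) do.call(rbind, viol)
                 else data.frame(row = integer(), rule = character(),
                                 detail = character())
  ), class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d rows\n", x$n_patients, x$n_rows))
  cat("  rows per timepoint:",
      paste(sprintf("%s=%d", names(x$rows_per_timepoint),
                    x$rows_per_timepoint), collapse = " "), "\n")
  if (nrow(x$violations) == 0) cat("  no invariant violations\n")
  else {
    cat(sprintf("  %d invariant violation(s):\n", nrow(x$violations)))
    print(head(x$violations, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Reads, types and validates a long-format patient-by-timepoint CSV/TSV
#' (columns as written by [write_cohort()]). Unknown columns raise a
#' warning and are kept; missing mandatory columns or unparseable numeric
#' fields are errors naming the offending rows. The validation report is
#' attached as attribute `"validation"`.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator (default `,`).
#' @return The cohort data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(.mandatory_cols, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(raw), .known_cols)
  if (length(unknown))
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "))
  for (cn in intersect(.numeric_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(parsed))
    if (length(bad))
      stop(sprintf("unparseable numeric value(s) in '%s' at data row(s): %s",
                   cn, paste(head(bad, 10), collapse = ", ")))
    raw[[cn]] <- parsed
  }
  if ("pcr" %in% names(raw)) raw$pcr <- as.integer(raw$pcr)
  if ("drfs_event" %in% names(raw)) raw$drfs_event <- as.integer(raw$drfs_event)
  attr(raw, "validation") <- validate_cohort(raw)
  raw
}

#' @rdname read_cohort
#' @param cohort cohort data frame (or [simulate_cohort()] result).
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  cohort <- as_cohort_df(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.count_block <- function(x, levels = NULL) {
  x <- x[!is.na(x)]
  tab <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
  data.frame(level = names(tab),
             n = as.integer(tab),
             pct = as.integer(round(100 * as.integer(tab) / sum(tab))),
             stringsAsFactors = FALSE)
}

#' Descriptive cohort summary
#'
#' One-row-per-patient descriptive table in the style of a clinical
#' characteristics table: mean age with range, then counts and
#' integer-rounded percentages by treatment arm, subtype, clinical T and N
#' stage, grade, MammaPrint risk category, and pCR. Optional columns with
#' missing entries show a reduced denominator.
#'
#' @param cohort a cohort data frame.
#' @return Object of class `cohort_summary`: `n_patients`, `age` (mean,
#'   range, n), and `blocks`, a named list of count/percentage data frames
#'   each carrying attribute `n` (its denominator).
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as_cohort_df(cohort)
  # one row per patient (covariates are constant within patient)
  pp <- cohort[!duplicated(cohort$patient_id), , drop = FALSE]
  blocks <- list()
  specs <- list(treatment = "treatment_arm", subtype = "subtype",
                clinical_t_stage = "ct_stage", clinical_n_stage = "cn_stage",
                grade = "grade", mammaprint = "mammaprint", pcr = "pcr")
  for (nm in names(specs)) {
    col <- specs[[nm]]
    if (!col %in% names(pp)) next
    vals <- pp[[col]]
    if (col == "pcr") vals <- ifelse(is.na(vals), NA, ifelse(vals == 1, "pCR", "no pCR"))
    b <- .count_block(vals)
    attr(b, "n") <- sum(!is.na(vals))
    blocks[[nm]] <- b
  }
  age <- if ("age" %in% names(pp)) {
    a <- pp$age[!is.na(pp$age)]
    list(mean = mean(a), range = range(a), n = length(a))
  } else NULL
  structure(list(n_patients = nrow(pp), age = age, blocks = blocks),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Patient and tumor characteristics (N = %d)\n", x$n_patients))
  if (!is.null(x$age))
    cat(sprintf("Mean age (range): %.1f (%g-%g)\n", x$age$mean,
                x$age$range[1], x$age$range[2]))
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    n <- attr(b, "n")
    cat(sprintf("%s%s\n", gsub("_", " ", nm),
                if (n < x$n_patients) sprintf(" (n = %d)", n) else ""))
    for (i in seq_len(nrow(b)))
      cat(sprintf("  %-22s %3d (%d%%)\n", b$level[i], b$n[i], b$pct[i]))
  }
  invisible(x)
}
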