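# Cohort metadata: one row per patient with age at surgery, etiology,
# histology, Engel outcome and follow-up. The binary outcome label is
# SF (seizure- and drug-free, Engel IA exactly) vs NSF (everything else);
# with the bundled cohort this gives the 15/6 split.

.engel_codes <- c("IA", "IB", "IC", "ID", "II", "III", "IV")

#' Load a cohort metadata table
#'
#' Reads a CSV with columns `patient_id`, `age_at_surgery`, `etiology`,
#' `histology`, `engel_outcome`, `followup_years`, validates the Engel codes
#' and derives the SF/NSF outcome label (SF = Engel IA).
#'
#' @param path CSV file path.
#' @return data.frame with an added factor column `label` (levels SF, NSF).
#' @export
load_cohort <- function(path) {
  req <- c("patient_id", "age_at_surgery", "etiology", "histology",
           "engel_outcome", "followup_years")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- !df$engel_outcome %in% .engel_codes
  if (any(bad))
    stop("unknown Engel outcome code(s): ",
         paste(unique(df$engel_outcome[bad]), collapse = ", "))
  if (any(df$followup_years < 0)) stop("negative follow-up")
  df$label <- factor(ifelse(df$engel_outcome == "IA", "SF", "NSF"),
                     levels = c("SF", "NSF"))
  df
}

#' Bundled study cohort table
#'
#' The 21-patient hemispherotomy cohort shipped with the package
#' (clinical/demographic table: age at surgery, etiology, histology, Engel
#' outcome, follow-up years).
#'
#' @param path_only if `TRUE` return the file path instead of the loaded table.
#' @return data.frame (or path).
#' @export
study_cohort <- function(path_only = FALSE) {
  p <- system.file("extdata", "table3_cohort.csv", package = "hemiconn",
                   mustWork = TRUE)
  if (path_only) p else load_cohort(p)
}

#' Summarize a cohort
#'
#' Computes cohort size, the seizure-free fraction, median and range of age
#' at surgery and follow-up (median = middle order statistic for odd n, via
#' [stats::median()]), and raw histology counts. Percentages are rounded to
#' the nearest integer.
#'
#' @param cohort data.frame from [load_cohort()].
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  n <- nrow(cohort)
  n_sf <- sum(cohort$label == "SF")
  out <- list(
    n = n,
    n_sf = n_sf,
    pct_sf = round(100 * n_sf / n),
    median_age = stats::median(cohort$age_at_surgery),
    range_age = range(cohort$age_at_surgery),
    median_followup = stats::median(cohort$followup_years),
    range_followup = range(cohort$followup_years),
    histology_counts = sort(table(cohort$histology), decreasing = TRUE))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d; seizure-free (Engel IA): %d (%d%%)\n",
              x$n, x$n_sf, x$pct_sf))
  cat(sprintf("Age at surgery: median %.1f y (range %.1f-%.1f)\n",
              x$median_age, x$range_age[1], x$range_age[2]))
  cat(sprintf("Follow-up: median %.1f y (range %.1f-%.1f)\n",
              x$median_followup, x$range_followup[1], x$range_followup[2]))
  cat("Histology:\n")
  for (h in names(x$histology_counts))
    cat(sprintf("  %-28s %d\n", h, x$histology_counts[[h]]))
  invisible(x)
}
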