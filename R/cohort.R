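# Descriptive cohort summary shaped like the standard "characteristics of
# reports" table: sex, age bins and moments, report year, reporter
# occupation, seriousness, outcome frequencies (multi-membership, so they may
# sum above 100%), time-to-onset bins and moments, and weight moments.

#' Assemble case reports from parsed packet tables
#'
#' Joins a deduplicated DEMO table with the OUTC outcome rows into one
#' case-level data.frame: demographics are decoded (age to years, weight to
#' kg, occupation codes to reporter categories) and outcomes become a
#' list-column of outcome labels. A report is serious when it carries at
#' least one outcome code.
#'
#' @param demo deduplicated DEMO data.frame (after [apply_deletions()]).
#' @param outc OUTC data.frame from [read_ascii_table()].
#' @return data.frame of class `case_reports` with columns `primaryid`,
#'   `caseid`, `fda_dt`, `sex`, `age_years`, `weight_kg`, `reporter`,
#'   `country`, `serious`, `outcomes` (list-column).
#' @export
case_reports <- function(demo, outc) {
  occp <- c(CN = "consumer", PH = "pharmacist", MD = "physician",
            OT = "other")
  outc_lab <- c(LT = "life_threatening", HO = "hospitalization",
                DS = "disability", DE = "death", CA = "congenital_anomaly",
                RI = "required_intervention", OT = "other")
  age <- suppressWarnings(as.numeric(demo$age))
  age[!is.na(age) & demo$age_cod == "MON"] <- age[!is.na(age) &
                                                    demo$age_cod == "MON"] / 12
  age[!is.na(age) & demo$age_cod == "DY"] <- age[!is.na(age) &
                                                   demo$age_cod == "DY"] / 365.25
  wt <- suppressWarnings(as.numeric(demo$wt))
  wt[!is.na(wt) & demo$wt_cod == "LBS"] <- wt[!is.na(wt) &
                                                demo$wt_cod == "LBS"] * 0.45359237
  by_pid <- split(outc_lab[outc$outc_cod], outc$primaryid)
  outcomes <- lapply(demo$primaryid, function(p) {
    o <- by_pid[[p]]
    unname(o[!is.na(o)])
  })
  out <- data.frame(primaryid = demo$primaryid, caseid = demo$caseid,
                    fda_dt = demo$fda_dt,
                    sex = ifelse(demo$sex %in% c("F", "M"), demo$sex,
                                 "unknown"),
                    age_years = age, weight_kg = wt,
                    reporter = ifelse(demo$occp_cod %in% names(occp),
                                      occp[demo$occp_cod], "unknown"),
                    country = ifelse(nzchar(demo$reporter_country),
                                     demo$reporter_country, "unknown"),
                    stringsAsFactors = FALSE)
  out$serious <- lengths(outcomes) > 0L
  out$outcomes <- outcomes
  class(out) <- c("case_reports", "data.frame")
  out
}

.outcome_levels <- c("life_threatening", "hospitalization", "disability",
                     "death", "congenital_anomaly", "required_intervention",
                     "other")

#' Descriptive summary of a deduplicated cohort
#'
#' Replicates the standard characteristics table: counts with percentages
#' rounded half-up to 2 decimals. Denominators: the full cohort for
#' demographics, outcomes and the time-to-onset bins; valid-only records for
#' the time-to-onset moments (both TTO denominators are reported).
#'
#' @param reports a `case_reports` data.frame (deduplicated).
#' @param tto optional `tto_records` from [compute_tto()] for the same cohort.
#' @return object of class `cohort_summary`: a named list of data.frames, one
#'   per table block, each with `level`, `n`, `pct` columns (moment blocks
#'   use `statistic`/`value`).
#' @export
describe_cohort <- function(reports, tto = NULL) {
  n <- nrow(reports)
  if (n == 0L) stop("empty cohort")
  pct <- function(k, denom = n) round_half_up(100 * k / denom, 2)
  block <- function(counts, denom = n) {
    data.frame(level = names(counts), n = as.integer(counts),
               pct = pct(as.integer(counts), denom),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  count_levels <- function(x, levels) {
    setNames(vapply(levels, function(l) sum(x == l), integer(1)), levels)
  }
  sex <- count_levels(reports$sex, c("F", "M", "unknown"))
  age <- reports$age_years
  age_bin <- ifelse(is.na(age), "unspecified",
                    ifelse(age < 18, "<18",
                           ifelse(age < 45, "18-44",
                                  ifelse(age < 65, "45-64", ">=65"))))
  age_bins <- count_levels(age_bin, c("<18", "18-44", "45-64", ">=65",
                                      "unspecified"))
  moments <- function(x) {
    v <- x[!is.na(x)]
    data.frame(statistic = c("n", "missing", "mean", "sd", "median", "q1",
                             "q3", "min", "max"),
               value = if (length(v) == 0L) rep(NA_real_, 9) else c(
                 length(v), sum(is.na(x)), mean(v),
                 if (length(v) > 1) sd(v) else 0,
                 quantile(v, c(0.5, 0.25, 0.75), type = 6, names = FALSE),
                 min(v), max(v)),
               stringsAsFactors = FALSE)
  }
  year <- substr(reports$fda_dt, 1, 4)
  years <- table(year[nchar(year) == 4])
  reporter <- count_levels(reports$reporter,
                           c("consumer", "pharmacist", "physician", "other",
                             "unknown"))
  serious <- c(serious = sum(reports$serious),
               non_serious = sum(!reports$serious))
  outc <- setNames(vapply(.outcome_levels, function(o) {
    sum(vapply(reports$outcomes, function(v) o %in% v, logical(1)))
  }, integer(1)), .outcome_levels)
  out <- list(
    n_reports = n,
    sex = block(sex),
    age_bins = block(age_bins),
    age = moments(age),
    report_year = block(setNames(as.integer(years), names(years))),
    reporter = block(reporter),
    seriousness = block(serious),
    outcomes = block(outc),
    weight = moments(reports$weight_kg)
  )
  if (!is.null(tto)) {
    bins <- bin_tto(tto)
    n_valid <- sum(bins[.tto_labels])
    out$tto_bins <- block(bins)            # denominator: all reports with TTO
    out$tto_bins_valid <- block(bins[.tto_labels], denom = n_valid)
    out$tto <- moments(as.numeric(tto$days))
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_reports, "deduplicated reports\n")
  for (nm in setdiff(names(x), "n_reports")) {
    cat("\n--", nm, "--\n")
    print(x[[nm]], digits = 4, row.names = FALSE)
  }
  invisible(x)
}
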