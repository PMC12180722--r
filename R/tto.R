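# Time to onset (TTO): days from therapy initiation to the adverse event.
# Records with a missing/partial date on either side are excluded as
# "missing"; a negative difference is excluded as "negative_outlier". Both
# exclusions are retained with their reason rather than dropped.

#' Compute time to onset from therapy start to event date
#'
#' Vectorized over report rows. Dates are FAERS 8-digit `YYYYMMDD` strings;
#' partial (`YYYY`/`YYYYMM`), empty, or syntactically invalid dates yield
#' status `"missing"` (invalid ones with a warning); a negative difference
#' yields `"negative_outlier"`.
#'
#' @param therapy_start,event_date character vectors of date strings.
#' @param caseid optional case identifiers carried through.
#' @return data.frame of class `tto_records` with columns `caseid`, `days`
#'   (integer, `NA` when excluded), `status`
#'   (`"valid"`/`"missing"`/`"negative_outlier"`).
#' @export
#' @examples
#' compute_tto("20240101", "20240105")$days  # 4
compute_tto <- function(therapy_start, event_date,
                        caseid = seq_along(therapy_start)) {
  stopifnot(length(therapy_start) == length(event_date))
  s_raw <- trimws(as.character(therapy_start))
  e_raw <- trimws(as.character(event_date))
  malformed <- function(x) nzchar(x) & !is.na(x) &
    !grepl("^[0-9]{8}$", x) & !is_partial_date(x)
  n_bad <- sum(malformed(s_raw) | malformed(e_raw))
  if (n_bad > 0L) {
    warning(n_bad, " record(s) with syntactically invalid date(s) set to missing")
  }
  s <- parse_faers_date(s_raw)
  e <- parse_faers_date(e_raw)
  days <- as.integer(e - s)
  status <- ifelse(is.na(days), "missing",
                   ifelse(days < 0, "negative_outlier", "valid"))
  days[status != "valid"] <- NA_integer_
  out <- data.frame(caseid = as.character(caseid), days = days,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("tto_records", "data.frame")
  out
}

.tto_breaks <- c(0, 30, 60, 90, 120, 150, 180, 360)
.tto_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150", "151-180",
                 "181-360", ">360")

# numeric vector of valid onset days from tto_records or a bare numeric vector
valid_days <- function(records) {
  if (is.data.frame(records)) {
    as.numeric(records$days[records$status == "valid"])
  } else {
    as.numeric(records[!is.na(records)])
  }
}

#' Bin time-to-onset values into the standard reporting intervals
#'
#' Closed integer bins 0-30, 31-60, ..., 181-360, >360 days, plus the count
#' of excluded (missing or negative) records. Day 30 falls in `0-30`, day 31
#' in `31-60`.
#'
#' @param records a `tto_records` data.frame from [compute_tto()], or a
#'   numeric vector of days (`NA` = excluded).
#' @return named integer vector over the eight bins plus `"excluded"`.
#' @export
bin_tto <- function(records) {
  d <- valid_days(records)
  n_excluded <- (if (is.data.frame(records)) nrow(records) else
    length(records)) - length(d)
  idx <- findInterval(d, .tto_breaks[-1] + 1)  # 30 -> bin 1, 31 -> bin 2
  counts <- tabulate(idx + 1L, nbins = length(.tto_labels))
  c(setNames(counts, .tto_labels), excluded = n_excluded)
}

#' Order statistics of valid time-to-onset values
#'
#' Quartiles use the `(n+1)p` order-statistic linear-interpolation convention
#' (R quantile `type = 6`), under which the quartiles of small samples land on
#' observed values (e.g. `[0, 4, 13]` gives Q1 = 0, Q3 = 13).
#'
#' @inheritParams bin_tto
#' @return named numeric vector: `n`, `median`, `q1`, `q3`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
summarize_tto <- function(records) {
  d <- valid_days(records)
  if (length(d) == 0L) stop("no valid time-to-onset records")
  q <- quantile(d, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  c(n = length(d), median = q[2], q1 = q[1], q3 = q[3],
    mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0,
    min = min(d), max = max(d))
}

#' Empirical cumulative incidence of onset times
#'
#' Right-continuous step function from 0 to 1 over the valid onset days.
#'
#' @inheritParams bin_tto
#' @return data.frame with columns `day` (sorted unique valid days) and
#'   `cum_frac` (fraction of valid records with onset <= day).
#' @export
#' @examples
#' cumulative_incidence(c(0, 0, 10))
cumulative_incidence <- function(records) {
  d <- valid_days(records)
  if (length(d) == 0L) stop("no valid time-to-onset records")
  day <- sort(unique(d))
  data.frame(day = day,
             cum_frac = cumsum(tabulate(match(sort(d), day),
                                        nbins = length(day))) / length(d))
}
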