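#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals, matching how
#' percentages are printed in regulatory-style characteristics tables. Base R's
#' `round()` rounds half to even, which prints 1.7766 as 1.78 either way but
#' differs on exact halves (e.g. 0.125).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(1.005, 2.675, -1.005), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse FAERS 8-digit dates
#'
#' FAERS dates are `YYYYMMDD` strings; partial dates (`YYYY` or `YYYYMM`) occur
#' and are treated as missing for arithmetic (they are retained as strings by
#' the readers and flagged here, never silently resolved).
#'
#' @param x character vector of date strings.
#' @return `Date` vector; `NA` for empty, partial, or invalid dates.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  complete <- !is.na(x) & nchar(x) == 8L & grepl("^[0-9]{8}$", x)
  out[complete] <- as.Date(x[complete], format = "%Y%m%d")
  out
}

# TRUE for syntactically partial (but non-empty) dates: YYYY or YYYYMM
is_partial_date <- function(x) {
  x <- trimws(as.character(x))
  !is.na(x) & nzchar(x) & grepl("^[0-9]+$", x) & nchar(x) %in% c(4L, 6L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a stage prefix used by run_pipeline error reporting
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
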