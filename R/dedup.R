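# Two-stage deduplication of spontaneous reports, following the FDA's
# recommended procedure: a case (CASEID) may be reported repeatedly as
# follow-up versions (each with its own PRIMARYID); only the most recent
# version is analyzed, and cases later named in quarterly deleted-report
# catalogs are removed entirely.

#' Keep one report version per case
#'
#' For reports sharing a CASEID, the version with the latest FDA receipt date
#' (`fda_dt`) is retained; when receipt dates tie, the version with the
#' highest PRIMARYID wins. The result is independent of input order.
#'
#' `fda_dt` is compared as an 8-digit `YYYYMMDD` string, which is equivalent
#' to chronological order; partial dates (`YYYY`/`YYYYMM`) sort before
#' complete dates sharing their prefix and trigger a warning. PRIMARYID is
#' compared numerically when all ids are numeric, lexicographically otherwise.
#'
#' @param reports data.frame with at least `primaryid`, `caseid`, `fda_dt`
#'   (character). Typically the DEMO table from [read_ascii_table()].
#' @return the retained rows, one per `caseid`, ordered by `caseid`.
#' @export
#' @examples
#' demo <- data.frame(primaryid = c("71", "72"), caseid = c("7", "7"),
#'                    fda_dt = c("20230101", "20230301"))
#' deduplicate_reports(demo)$primaryid  # "72"
deduplicate_reports <- function(reports) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(reports)))
  if (anyDuplicated(reports$primaryid)) {
    dup <- reports$primaryid[duplicated(reports$primaryid)][1L]
    stop("identifier collision: primaryid ", dup, " appears more than once")
  }
  if (nrow(reports) == 0L) return(reports)
  if (any(is_partial_date(reports$fda_dt))) {
    warning("partial FDA_DT value(s) present; they sort before complete dates")
  }
  pid <- reports$primaryid
  pid_num <- suppressWarnings(as.numeric(pid))
  pid_key <- if (!anyNA(pid_num)) pid_num else pid
  o <- order(reports$caseid, reports$fda_dt, pid_key)
  sorted <- reports[o, , drop = FALSE]
  keep <- !duplicated(sorted$caseid, fromLast = TRUE)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove cases named in deleted-report catalogs
#'
#' Deletion catalogs accumulate across quarters; removing an absent CASEID is
#' a no-op. The number of reports removed is reported via `message()` and as
#' the attribute `n_removed`.
#'
#' @param reports deduplicated reports (one row per `caseid`).
#' @param deleted character vector of CASEIDs to remove, e.g. the union of
#'   [read_deleted_list()] results across quarters.
#' @return surviving reports with attribute `n_removed`.
#' @export
apply_deletions <- function(reports, deleted) {
  stopifnot("caseid" %in% names(reports))
  drop <- reports$caseid %in% as.character(deleted)
  out <- reports[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  message(sum(drop), " report(s) removed by deletion catalog")
  out
}
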