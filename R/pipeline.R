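# End-to-end orchestration: read packets -> deduplicate -> apply deletions ->
# restrict to primary-suspect exposures -> disproportionality screen at PT
# and/or SOC level -> cohort descriptives -> time-to-onset analysis; all
# outputs written as CSV plus a JSON manifest with counts at each stage.

read_packet_dir <- function(input_dir) {
  tabs <- lapply(names(faers_schemas()), function(tn) {
    files <- sort(list.files(input_dir, pattern = paste0("^", tn, "_.*\\.txt$"),
                             full.names = TRUE))
    if (length(files) == 0L) return(NULL)
    do.call(rbind, lapply(files, read_ascii_table, table_name = tn))
  })
  names(tabs) <- names(faers_schemas())
  if (is.null(tabs$DEMO)) stop("no DEMO_*.txt files in ", input_dir)
  del_files <- sort(list.files(input_dir, pattern = "^deleted_cases_.*\\.txt$",
                               full.names = TRUE))
  tabs$deleted <- unique(unlist(lapply(del_files, read_deleted_list)))
  if (is.null(tabs$deleted)) tabs$deleted <- character(0)
  tabs
}

#' Run the full screening pipeline on a packet directory
#'
#' Reads all quarterly tables and deletion catalogs from `input_dir`,
#' deduplicates (one version per CASEID, deletion catalogs applied),
#' restricts to primary-suspect exposures of `target_drug`, and writes:
#'
#' * `cohort_summary.csv` -- the characteristics table;
#' * `signals_soc.csv` -- the SOC-level screen (ranked by case reports);
#' * `signals_pt_by_ror.csv` / `signals_pt_by_reports.csv` -- the PT-level
#'   screen ranked both ways (identical rows, different order);
#' * `tto_histogram.csv`, `tto_ecdf.csv`, `tto_weibull.csv` -- onset-time
#'   bins, empirical cumulative incidence, and the one-row Weibull summary
#'   (n, median/IQR, scale and shape with CIs, failure type);
#' * `manifest.json` -- package version, options, and report counts at each
#'   stage.
#'
#' Stage failures abort with the stage name; partial outputs are removed.
#'
#' @param input_dir directory of FAERS-style packets (e.g. from
#'   [generate_packets()]).
#' @param target_drug drug of interest.
#' @param out_dir output directory.
#' @param level `"pt"`, `"soc"`, or `"both"`.
#' @param criteria joint-criteria mode, `"all"` or `"any"`.
#' @param counting `"case"` or `"event"` counting.
#' @param soc_map a `meddra_map`; defaults to the shipped mapping.
#' @param prior an [mgps_prior()] or `"fit"`.
#' @param a_min case-count gate for the signal criteria.
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `signals_pt`, `signals_soc`, `tto`, `weibull`, `manifest`).
#' @export
run_pipeline <- function(input_dir, target_drug, out_dir,
                         level = c("both", "pt", "soc"),
                         criteria = c("all", "any"),
                         counting = c("case", "event"),
                         soc_map = load_meddra_map(),
                         prior = mgps_prior(), a_min = 3) {
  level <- match.arg(level)
  criteria <- match.arg(criteria)
  counting <- match.arg(counting)
  if (!nzchar(target_drug %||% "")) {
    stop_stage("validate", "target drug must be given")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write.csv(x, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  on_fail <- function(stage) {
    function(e) {
      unlink(written)
      stop_stage(stage, conditionMessage(e))
    }
  }
  run <- function(stage, expr) tryCatch(expr, error = on_fail(stage))

  tabs <- run("read", read_packet_dir(input_dir))
  n_raw <- nrow(tabs$DEMO)
  demo <- run("dedup", deduplicate_reports(tabs$DEMO))
  n_dedup <- nrow(demo)
  demo <- run("dedup", suppressMessages(apply_deletions(demo, tabs$deleted)))
  n_final <- nrow(demo)
  keep_pid <- demo$primaryid

  ps <- run("exposure", {
    d <- tabs$DRUG
    d <- d[d$role_cod == "PS" & d$primaryid %in% keep_pid, , drop = FALSE]
    r <- tabs$REAC[tabs$REAC$primaryid %in% keep_pid, , drop = FALSE]
    merge(d[c("primaryid", "caseid", "drugname")],
          r[c("primaryid", "pt")], by = "primaryid")
  })
  pairs <- data.frame(caseid = ps$caseid, drug = ps$drugname, pt = ps$pt,
                      stringsAsFactors = FALSE)

  screen_pt <- screen_soc <- NULL
  if (level %in% c("pt", "both")) {
    screen_pt <- run("signal_stats",
                     disproportionality(pairs, target_drug, level = "PT",
                                        soc_map = soc_map, prior = prior,
                                        a_min = a_min, counting = counting))
    emit(rank_signals(screen_pt, "ror"), "signals_pt_by_ror.csv")
    emit(rank_signals(screen_pt, "n_cases"), "signals_pt_by_reports.csv")
  }
  if (level %in% c("soc", "both")) {
    screen_soc <- run("signal_stats",
                      disproportionality(pairs, target_drug, level = "SOC",
                                         soc_map = soc_map, prior = prior,
                                         a_min = a_min, counting = counting))
    emit(rank_signals(screen_soc, "n_cases"), "signals_soc.csv")
  }

  cohort_tto <- run("tto", {
    tgt_pid <- unique(ps$primaryid[toupper(trimws(ps$drugname)) ==
                                     toupper(trimws(target_drug))])
    ther <- tabs$THER[tabs$THER$primaryid %in% tgt_pid, , drop = FALSE]
    # earliest primary-suspect therapy start per report
    start <- vapply(split(ther$start_dt, ther$primaryid), function(s) {
      s <- s[grepl("^[0-9]{8}$", s)]
      if (length(s)) min(s) else ""
    }, character(1))
    dtgt <- demo[demo$primaryid %in% tgt_pid, , drop = FALSE]
    compute_tto(therapy_start = start[dtgt$primaryid],
                event_date = dtgt$event_dt, caseid = dtgt$caseid)
  })

  reports <- run("cohort", {
    tgt_pid <- unique(ps$primaryid[toupper(trimws(ps$drugname)) ==
                                     toupper(trimws(target_drug))])
    case_reports(demo[demo$primaryid %in% tgt_pid, , drop = FALSE],
                 tabs$OUTC)
  })
  if (nrow(reports) == 0L) {
    unlink(written)
    stop_stage("cohort", "no deduplicated reports for target drug '",
               target_drug, "'")
  }
  cohort <- run("cohort", describe_cohort(reports, tto = cohort_tto))
  emit(cohort_summary_frame(cohort), "cohort_summary.csv")

  wfit <- run("tto", {
    d <- valid_days(cohort_tto)
    if (length(d) >= 10L && length(unique(d)) > 1L) fit_weibull(cohort_tto)
    else NULL
  })
  run("tto", {
    bins <- bin_tto(cohort_tto)
    emit(data.frame(bin = names(bins), n = as.integer(bins)),
         "tto_histogram.csv")
    emit(cumulative_incidence(cohort_tto), "tto_ecdf.csv")
    s <- summarize_tto(cohort_tto)
    emit(data.frame(
      n = s[["n"]], median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]],
      scale = if (is.null(wfit)) NA else wfit$scale,
      scale_lo = if (is.null(wfit)) NA else wfit$scale_ci[1],
      scale_hi = if (is.null(wfit)) NA else wfit$scale_ci[2],
      shape = if (is.null(wfit)) NA else wfit$shape,
      shape_lo = if (is.null(wfit)) NA else wfit$shape_ci[1],
      shape_hi = if (is.null(wfit)) NA else wfit$shape_ci[2],
      failure_type = if (is.null(wfit)) NA else wfit$failure_type),
      "tto_weibull.csv")
  })

  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    target_drug = target_drug, level = level, criteria = criteria,
    counting = counting, a_min = a_min,
    counts = list(raw_versions = n_raw, after_dedup = n_dedup,
                  after_deletions = n_final,
                  target_reports = nrow(reports),
                  tto_valid = sum(cohort_tto$status == "valid"),
                  tto_excluded = sum(cohort_tto$status != "valid")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, signals_pt = screen_pt,
                 signals_soc = screen_soc, tto = cohort_tto,
                 weibull = wfit, manifest = manifest))
}

# flatten a cohort_summary into one long CSV-friendly frame
cohort_summary_frame <- function(x) {
  blocks <- setdiff(names(x), "n_reports")
  do.call(rbind, lapply(blocks, function(b) {
    df <- x[[b]]
    if ("statistic" %in% names(df)) {
      data.frame(block = b, level = df$statistic, n = NA_integer_,
                 pct = NA_real_, value = df$value, stringsAsFactors = FALSE)
    } else {
      data.frame(block = b, level = df$level, n = df$n, pct = df$pct,
                 value = NA_real_, stringsAsFactors = FALSE)
    }
  }))
}
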