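# Drug-event 2x2 contingency tables against the database background.
#
#                 target event   other events
#   target drug        a              b
#   other drugs        c              d
#
# The counting unit is the distinct case-level (caseid, drug, event) pair:
# each deduplicated case contributes at most 1 to a given cell. Event-level
# counting (every reported occurrence counts) is available as an option.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d nonnegative integer cell counts: `a` = target drug and
#'   target event, `b` = target drug and other events, `c` = other drugs and
#'   target event, `d` = other drugs and other events.
#' @return object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(10, 90, 100, 9900)
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cells a, b, c, d must be nonnegative integers")
  }
  if (sum(cells) <= 0) stop("empty table: N = a+b+c+d must be positive")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  cat("N =", x$a + x$b + x$c + x$d, "\n")
  invisible(x)
}

# Accept a contingency_table, or a list/data.frame with fields a,b,c,d
# (vectorized over elements). Returns list of numeric vectors a,b,c,d.
as_cells <- function(t) {
  if (inherits(t, "contingency_table")) {
    return(list(a = as.numeric(t$a), b = as.numeric(t$b),
                c = as.numeric(t$c), d = as.numeric(t$d)))
  }
  if (is.list(t) && all(c("a", "b", "c", "d") %in% names(t))) {
    return(list(a = as.numeric(t$a), b = as.numeric(t$b),
                c = as.numeric(t$c), d = as.numeric(t$d)))
  }
  stop("expected a contingency_table or a list/data.frame with fields a,b,c,d")
}

#' Build the 2x2 table for one drug-event pair
#'
#' Cross-tabulates case-level (caseid, drug, event) pairs against a target
#' drug and target event. At `level = "SOC"` the target event is a system
#' organ class and PTs are mapped through `soc_map` first.
#'
#' @param event_pairs data.frame with columns `caseid`, `drug`, `pt`, already
#'   restricted upstream to primary-suspect drug roles.
#' @param target_drug drug name (matched case-insensitively after trimming).
#' @param target_event preferred term (or SOC name when `level = "SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @param soc_map a `meddra_map`, required when `level = "SOC"`.
#' @param counting `"case"` (default; distinct case-level pairs) or `"event"`
#'   (every row counts).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(event_pairs, target_drug, target_event,
                              level = c("PT", "SOC"), soc_map = NULL,
                              counting = c("case", "event")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  stopifnot(all(c("caseid", "drug", "pt") %in% names(event_pairs)))
  ep <- data.frame(caseid = as.character(event_pairs$caseid),
                   drug = toupper(trimws(event_pairs$drug)),
                   event = as.character(event_pairs$pt),
                   stringsAsFactors = FALSE)
  if (level == "SOC") {
    if (is.null(soc_map)) stop("soc_map is required at level = 'SOC'")
    ep$event <- map_pt_to_soc(ep$event, soc_map)$soc_name
  }
  ep$event_key <- normalize_pt(ep$event)
  if (counting == "case") {
    ep <- ep[!duplicated(ep[c("caseid", "drug", "event_key")]), , drop = FALSE]
  }
  is_tgt_drug <- ep$drug == toupper(trimws(target_drug))
  if (!any(is_tgt_drug)) stop("no exposure rows for target drug '",
                              target_drug, "'")
  if (all(is_tgt_drug)) {
    stop("degenerate background: dataset contains the target drug only")
  }
  is_tgt_event <- ep$event_key == normalize_pt(target_event)
  contingency_table(a = sum(is_tgt_drug & is_tgt_event),
                    b = sum(is_tgt_drug & !is_tgt_event),
                    c = sum(!is_tgt_drug & is_tgt_event),
                    d = sum(!is_tgt_drug & !is_tgt_event))
}
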