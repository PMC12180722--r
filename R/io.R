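# Readers and writers for FAERS-style quarterly ASCII packets.
#
# Real FAERS quarterly extracts are dollar-delimited text tables with a header
# row. This package uses a compact schema per table (a subset of the real
# columns) sufficient for deduplication, disproportionality and time-to-onset.
# All values are kept as character strings: identifiers are never coerced to
# numbers, so leading zeros survive a round trip.

.faers_schemas <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "wt", "wt_cod", "occp_cod", "reporter_country"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "caseid", "pt"),
  OUTC = c("primaryid", "caseid", "outc_cod"),
  THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt")
)

#' Table schemas for FAERS-style ASCII packets
#'
#' @return named list of character vectors: the ordered column names expected
#'   for each of the `DEMO`, `DRUG`, `REAC`, `OUTC`, `THER` tables.
#' @export
faers_schemas <- function() .faers_schemas

#' Read one FAERS-style ASCII table
#'
#' Parses a dollar-delimited text table with a header row, validating the
#' column set against the declared schema for `table_name`. Every field is
#' returned as a character string (empty string = missing); identifiers are
#' never coerced to numbers.
#'
#' @param path path to the table file.
#' @param table_name one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`.
#' @param delim field delimiter, `"$"` by FAERS convention.
#' @return a `data.frame` of character columns, one row per data line.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$pt", "1001$777$Myelosuppression"), f)
#' read_ascii_table(f, "REAC")
read_ascii_table <- function(path, table_name, delim = "$") {
  table_name <- match.arg(toupper(table_name), names(.faers_schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  header <- tolower(trimws(strsplit(lines[1L], delim, fixed = TRUE)[[1L]]))
  schema <- .faers_schemas[[table_name]]
  if (!setequal(header, schema) || length(header) != length(schema)) {
    stop(sprintf("header of %s does not match the %s schema (expected: %s)",
                 path, table_name, paste(schema, collapse = ", ")))
  }
  ncol <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), ncol), header),
                         stringsAsFactors = FALSE)
    return(out[schema])
  }
  parts <- strsplit(body, delim, fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad them back
  lens <- lengths(parts)
  pad <- lens < ncol & vapply(seq_along(parts), function(i) {
    n_delim <- lengths(regmatches(body[i], gregexpr(delim, body[i], fixed = TRUE)))
    n_delim == ncol - 1L
  }, logical(1))
  parts[pad] <- lapply(parts[pad], function(p) c(p, rep("", ncol - length(p))))
  lens <- lengths(parts)
  if (any(lens != ncol)) {
    bad <- which(lens != ncol)[1L]
    stop(sprintf("malformed line %d of %s: %d fields under a %d-column header",
                 bad + 1L, path, lens[bad], ncol))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out <- out[schema]
  if (any(!nzchar(out$primaryid))) {
    stop("PRIMARYID missing on line ",
         which(!nzchar(out$primaryid))[1L] + 1L, " of ", path)
  }
  out
}

#' Write one FAERS-style ASCII table
#'
#' Inverse of [read_ascii_table()]: writes the header row followed by
#' dollar-delimited data lines. `write_ascii_table()` then
#' `read_ascii_table()` reproduces identical field values.
#'
#' @param x data.frame whose columns match the schema for `table_name`.
#' @param path output path.
#' @param table_name one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_ascii_table <- function(x, path, table_name, delim = "$") {
  table_name <- match.arg(toupper(table_name), names(.faers_schemas))
  schema <- .faers_schemas[[table_name]]
  if (!all(schema %in% names(x))) {
    stop("missing columns for ", table_name, ": ",
         paste(setdiff(schema, names(x)), collapse = ", "))
  }
  x <- x[schema]
  for (j in seq_along(x)) {
    v <- as.character(x[[j]])
    v[is.na(v)] <- ""
    if (any(grepl(delim, v, fixed = TRUE))) {
      stop("field value contains the delimiter '", delim, "'")
    }
    x[[j]] <- v
  }
  lines <- c(paste(schema, collapse = delim),
             do.call(paste, c(unname(as.list(x)), sep = delim)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a deleted-case catalog
#'
#' Quarterly FAERS packets from 2019Q1 onward ship a list of CASEID values to
#' be removed from the cumulative data. The file holds one CASEID per line;
#' duplicates collapse to a set.
#'
#' @param path path to the deletion list.
#' @return character vector of unique CASEIDs (possibly empty).
#' @export
read_deleted_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
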