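# MedDRA preferred-term (PT) -> system-organ-class (SOC) mapping.
#
# The full MedDRA dictionary is licensed and out of scope; the package ships a
# small plain-text mapping covering the PTs used in the worked examples plus
# the synthetic generator's vocabulary, each PT assigned a single primary SOC.

#' Load a PT to SOC mapping table
#'
#' Reads a delimited file with columns `pt`, `soc_name`, `soc_code` and
#' returns a lookup table. PT matching downstream is case-insensitive after
#' whitespace normalization. A PT listed under two different SOCs violates the
#' single-primary-SOC invariant and is an error.
#'
#' @param path path to the mapping file; defaults to the mapping shipped with
#'   the package.
#' @param sep field separator (the shipped fixture is CSV).
#' @return data.frame of class `meddra_map` with columns `pt`, `soc_name`,
#'   `soc_code` (integer) and a normalized key column `pt_key`.
#' @export
#' @examples
#' m <- load_meddra_map()
#' map_pt_to_soc("Myelosuppression", m)
load_meddra_map <- function(path = system.file("extdata", "meddra_pt_soc.csv",
                                               package = "faersignal"),
                            sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                colClasses = "character")
  need <- c("pt", "soc_name", "soc_code")
  if (!all(need %in% names(m))) {
    stop("mapping file must have columns: ", paste(need, collapse = ", "))
  }
  m$pt_key <- normalize_pt(m$pt)
  m$soc_code <- as.integer(m$soc_code)
  dup <- split(m$soc_name, m$pt_key)
  bad <- names(dup)[vapply(dup, function(s) length(unique(s)) > 1L, logical(1))]
  if (length(bad)) {
    stop("PT mapped to more than one SOC (primary-SOC invariant): ",
         paste(bad, collapse = ", "))
  }
  m <- m[!duplicated(m$pt_key), c("pt", "pt_key", "soc_name", "soc_code")]
  class(m) <- c("meddra_map", "data.frame")
  m
}

# case-insensitive, whitespace-normalized PT key
normalize_pt <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

#' Map preferred terms to their primary system organ class
#'
#' Unmapped PTs are reported with a warning and returned with the sentinel SOC
#' `"UNMAPPED"` (code `NA`), never silently dropped.
#'
#' @param pts character vector of preferred terms.
#' @param map a `meddra_map` from [load_meddra_map()].
#' @return data.frame with columns `pt`, `soc_name`, `soc_code`; the number of
#'   unmapped lookups is attached as attribute `n_unmapped`.
#' @export
map_pt_to_soc <- function(pts, map) {
  stopifnot(inherits(map, "meddra_map"))
  i <- match(normalize_pt(pts), map$pt_key)
  out <- data.frame(pt = as.character(pts),
                    soc_name = ifelse(is.na(i), "UNMAPPED", map$soc_name[i]),
                    soc_code = map$soc_code[i],
                    stringsAsFactors = FALSE)
  n_unmapped <- sum(is.na(i))
  if (n_unmapped > 0L) {
    warning(sprintf("%d PT lookup(s) not in the mapping (SOC = UNMAPPED): %s",
                    n_unmapped,
                    paste(unique(pts[is.na(i)]), collapse = ", ")))
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}
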