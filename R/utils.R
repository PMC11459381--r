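`%||%` <- function(a, b) if (is.null(a)) b else a

#' Avogadro constant (mol^-1), 2019 SI exact value
#' @keywords internal
AVOGADRO <- 6.02214076e23

# mean molar mass of one double-stranded base pair, g/mol; not printed by most
# protocols, the conventional dsDNA average
DEFAULT_BP_MASS <- 650

abort <- function(msg, class = "spikequant_error", ...) {
  stop(errorCondition(msg, ...,
                      class = c(class, "spikequant_error", "error", "condition")))
}

config_abort <- function(msg) abort(msg, class = "spikequant_config_error")

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Parse timestamps as UTC instants
#'
#' Accepts ISO 8601 with an explicit zone designator (`Z` or `+hh:mm`/`+hhmm`).
#' Naive timestamps are rejected unless `default_tz` is supplied, because
#' time-window matchup criteria are meaningless across unlabeled zones.
#'
#' @param x character vector of timestamps
#' @param default_tz optional Olson timezone applied to zone-less timestamps
#' @return POSIXct vector in UTC; NA where unparsable
#' @keywords internal
parse_utc <- function(x, default_tz = NULL) {
  x <- trimws(as.character(x))
  x <- sub(" ", "T", x, fixed = TRUE)
  has_zone <- grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  out <- rep(as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"), length(x))
  if (any(has_zone)) {
    z <- x[has_zone]
    z <- sub("Z$", "+0000", z)
    z <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", z)
    out[has_zone] <- as.POSIXct(z, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  }
  if (any(!has_zone)) {
    if (is.null(default_tz)) {
      # leave NA; callers report the offending row
    } else {
      out[!has_zone] <- as.POSIXct(x[!has_zone],
                                   format = "%Y-%m-%dT%H:%M:%S",
                                   tz = default_tz)
    }
  }
  attr(out, "tzone") <- "UTC"
  out
}

iso_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write records as JSON lines
#' @param records list of lists (one record per line)
#' @param path output path
#' @keywords internal
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# deterministic md5 of an R object via its canonical JSON rendering
hash_config <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
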