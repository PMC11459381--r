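#' Construct a validated ASV count table
#'
#' The count table is the unit of observation for the whole pipeline: an
#' integer matrix of amplicon reads with ASVs as rows and samples as columns.
#' Both community ASVs and the ASVs belonging to the spiked genomic standards
#' live in the same table, exactly as a denoising pipeline emits them.
#'
#' @param counts integer (or whole-numeric) matrix, ASVs x samples, with
#'   rownames (ASV ids) and colnames (sample ids)
#' @return an object of class `count_table` with fields `asv_ids`,
#'   `sample_ids` and `counts`
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) abort("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort(sprintf("duplicate ASV id: %s",
                  rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    abort(sprintf("duplicate sample column: %s",
                  colnames(counts)[duplicated(colnames(counts))][1]))
  if (nrow(counts) == 0L) abort("no ASV rows")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort(sprintf("invalid count at ASV '%s', sample '%s': %s",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                  format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max at depth
  structure(list(asv_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 counts = counts),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d ASVs x %d samples, %s total reads\n",
              length(x$asv_ids), length(x$sample_ids),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read an ASV count table from TSV
#'
#' First column must hold ASV identifiers; every remaining column is one
#' sample of integer read counts. Row and column order is preserved.
#'
#' @param path path to a tab-separated file
#' @param sep field separator, tab by default
#' @return a [count_table()]
#' @export
read_count_table <- function(path, sep = "\t") {
  if (!file.exists(path)) abort(sprintf("count table not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(header) < 2L) abort("count table needs an ASV id column and at least one sample")
  samples <- header[-1]
  if (anyDuplicated(samples))
    abort(sprintf("duplicate sample column: %s", samples[duplicated(samples)][1]))
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) abort("no ASV rows")
  asv_ids <- df[[1]]
  if (anyDuplicated(asv_ids))
    abort(sprintf("duplicate ASV id: %s", asv_ids[duplicated(asv_ids)][1]))
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                dimnames = list(asv_ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L)
      abort(sprintf("invalid count at row %d (ASV '%s'), column '%s': '%s'",
                    bad[1], asv_ids[bad[1]], samples[j], df[[j + 1L]][bad[1]]))
    mat[, j] <- v
  }
  count_table(mat)
}

#' Write an ASV count table to TSV
#' @param x a [count_table()]
#' @param path output path
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(asv_id = x$asv_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a CSV with header
#' `sample_id,site_id,replicate,volume,volume_unit,lat,lon,datetime`.
#' Volumes are normalized to liters on read (`volume_unit` of "L" or "mL"),
#' timestamps are parsed as UTC instants.
#'
#' @param path path to the CSV file
#' @param default_tz optional timezone applied to timestamps lacking a zone
#'   designator; without it, naive timestamps are a hard error
#' @return a `sample_metadata` data.frame with columns `sample_id`, `site_id`,
#'   `replicate`, `volume_L`, `lat`, `lon`, `timestamp`
#' @export
read_metadata <- function(path, default_tz = NULL) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "site_id", "replicate", "volume", "volume_unit",
           "lat", "lon", "datetime")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    abort(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  sample_metadata(
    sample_id = as.character(df$sample_id),
    site_id   = as.character(df$site_id),
    replicate = df$replicate,
    volume    = df$volume,
    volume_unit = df$volume_unit,
    lat = df$lat, lon = df$lon,
    datetime = df$datetime, default_tz = default_tz)
}

#' Construct validated sample metadata
#'
#' @inheritParams read_metadata
#' @param sample_id,site_id character ids
#' @param replicate integer replicate index within site
#' @param volume filtered seawater volume
#' @param volume_unit "L" or "mL" per row
#' @param lat,lon decimal degrees WGS84
#' @param datetime ISO 8601 timestamps (character) or POSIXct
#' @export
sample_metadata <- function(sample_id, site_id, replicate, volume,
                            volume_unit = "L", lat, lon, datetime,
                            default_tz = NULL) {
  n <- length(sample_id)
  volume_unit <- rep_len(volume_unit, n)
  if (anyDuplicated(sample_id))
    abort(sprintf("duplicate sample_id: %s", sample_id[duplicated(sample_id)][1]))
  key <- paste(site_id, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort(sprintf("duplicate (site_id, replicate): (%s, %s)",
                  site_id[d], replicate[d]))
  }
  replicate <- as.integer(replicate)
  if (anyNA(replicate) || any(replicate < 1L))
    abort("replicate must be a positive integer index")
  volume <- as.numeric(volume)
  if (anyNA(volume) || any(volume <= 0)) abort("volume must be > 0")
  unit_factor <- c(L = 1, mL = 1e-3, ml = 1e-3, l = 1)[volume_unit]
  if (anyNA(unit_factor))
    abort(sprintf("unknown volume unit: %s",
                  volume_unit[is.na(unit_factor)][1]))
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (anyNA(lat) || any(lat < -90 | lat > 90))
    abort("latitude out of range [-90, 90]")
  if (anyNA(lon) || any(lon < -180 | lon >= 180))
    abort("longitude out of range [-180, 180)")
  if (inherits(datetime, "POSIXct")) {
    ts <- datetime
    attr(ts, "tzone") <- "UTC"
  } else {
    ts <- parse_utc(datetime, default_tz)
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1]
      abort(sprintf("unparsable or zone-less timestamp at row %d: '%s'",
                    bad, datetime[bad]))
    }
  }
  out <- data.frame(sample_id = sample_id, site_id = as.character(site_id),
                    replicate = replicate,
                    volume_L = volume * unname(unit_factor),
                    lat = lat, lon = lon, stringsAsFactors = FALSE)
  out$timestamp <- ts
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Write sample metadata to CSV (liters, ISO 8601 UTC)
#' @param x a `sample_metadata` data.frame
#' @param path output path
#' @export
write_metadata <- function(x, path) {
  df <- data.frame(sample_id = x$sample_id, site_id = x$site_id,
                   replicate = x$replicate, volume = fmt_num(x$volume_L),
                   volume_unit = "L", lat = fmt_num(x$lat),
                   lon = fmt_num(x$lon), datetime = iso_utc(x$timestamp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' 16S copy load of a genomic DNA spike
#'
#' Converts a mass of genomic DNA into the number of 16S rRNA gene copies it
#' carries: `mass / (genome mass) * copies_per_genome`, with the genome mass
#' taken as `genome_size_bp * bp_mass / N_A` grams. This is the a-priori known
#' copy load `C_s` of an internal standard.
#'
#' @param mass_ng genomic DNA mass in nanograms
#' @param genome_size_bp genome length in base pairs
#' @param copies_per_genome 16S rRNA operons per genome
#' @param bp_mass mean molar mass of a double-stranded base pair, g/mol
#' @return copies per sample (numeric, vectorized)
#' @examples
#' standard_copy_load(4, 3.0e6, 4)   # ~4.94e6 copies
#' @export
standard_copy_load <- function(mass_ng, genome_size_bp, copies_per_genome,
                               bp_mass = DEFAULT_BP_MASS) {
  if (any(mass_ng <= 0) || any(genome_size_bp <= 0) ||
      any(copies_per_genome < 1) || any(bp_mass <= 0))
    abort("standard_copy_load: all arguments must be positive (copies_per_genome >= 1)")
  mass_ng * 1e-9 / (genome_size_bp * bp_mass / AVOGADRO) * copies_per_genome
}

#' Define one internal genomic standard
#'
#' @param name organism label (e.g. "Blautia producta")
#' @param mass_ng genomic DNA mass spiked per sample, nanograms
#' @param genome_size_bp genome length, base pairs
#' @param copies_per_genome 16S rRNA operons per genome
#' @param asv_ids ASV identifiers assigned to this organism (one genome's
#'   operons can denoise into several ASVs; their reads are summed)
#' @param bp_mass mean base-pair molar mass used to derive the copy load
#' @return a `standard_spec` with derived field `copies_added` (C_s)
#' @export
standard_spec <- function(name, mass_ng, genome_size_bp, copies_per_genome,
                          asv_ids, bp_mass = DEFAULT_BP_MASS) {
  if (length(asv_ids) < 1L) abort(sprintf("standard '%s' has no ASV ids", name))
  if (anyDuplicated(asv_ids))
    abort(sprintf("standard '%s' lists a duplicate ASV id", name))
  copies <- standard_copy_load(mass_ng, genome_size_bp, copies_per_genome, bp_mass)
  structure(list(name = as.character(name), mass_ng = mass_ng,
                 genome_size_bp = genome_size_bp,
                 copies_per_genome = copies_per_genome,
                 asv_ids = as.character(asv_ids),
                 copies_added = copies),
            class = "standard_spec")
}

validate_standards <- function(standards) {
  if (length(standards) == 0L) abort("at least one internal standard is required")
  all_ids <- unlist(lapply(standards, `[[`, "asv_ids"))
  if (anyDuplicated(all_ids))
    abort(sprintf("configuration error: ASV '%s' assigned to multiple standards",
                  all_ids[duplicated(all_ids)][1]))
  nm <- vapply(standards, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    abort(sprintf("duplicate standard name: %s", nm[duplicated(nm)][1]))
  invisible(standards)
}

#' Read internal-standard specifications from JSON
#'
#' The file holds an array of objects with fields `name`, `mass_ng`,
#' `genome_size_bp`, `copies_per_genome`, `asv_ids`.
#'
#' @param path JSON file path
#' @param bp_mass base-pair molar mass forwarded to [standard_copy_load()]
#' @return list of `standard_spec`
#' @export
read_standards <- function(path, bp_mass = DEFAULT_BP_MASS) {
  if (!file.exists(path)) abort(sprintf("standards file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  standards <- lapply(raw, function(r) {
    standard_spec(r$name, r$mass_ng, r$genome_size_bp, r$copies_per_genome,
                  unlist(r$asv_ids), bp_mass = bp_mass)
  })
  validate_standards(standards)
  standards
}

#' Write internal-standard specifications to JSON
#' @param standards list of `standard_spec`
#' @param path output path
#' @export
write_standards <- function(standards, path) {
  recs <- lapply(standards, function(s)
    list(name = s$name, mass_ng = s$mass_ng, genome_size_bp = s$genome_size_bp,
         copies_per_genome = s$copies_per_genome, asv_ids = as.list(s$asv_ids)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ASV taxonomy table
#'
#' TSV of `asv_id<TAB>taxonomy_string` (semicolon-delimited ranks). A header
#' line starting with `asv_id` is skipped if present.
#'
#' @param path TSV path
#' @return named character vector, ASV id -> taxonomy string
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("taxonomy file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("taxonomy file needs two tab-separated columns")
  if (nrow(df) > 0L && df[1, 1] == "asv_id") df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    abort(sprintf("duplicate ASV id in taxonomy: %s",
                  df[[1]][duplicated(df[[1]])][1]))
  stats::setNames(df[[2]], df[[1]])
}

#' Write an ASV taxonomy table
#' @param taxonomy named character vector (ASV id -> taxonomy string)
#' @param path output path
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(asv_id = names(taxonomy), taxonomy = unname(taxonomy))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 16S copy-number map from JSON
#'
#' A JSON object mapping taxon name/pattern to 16S gene copies per cell,
#' e.g. `{"Prochlorococcus": 1, "Synechococcus": 2}`.
#'
#' @param path JSON path
#' @return named numeric vector
#' @export
read_copy_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("copy map not found: %s", path))
  m <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  m <- stats::setNames(as.numeric(m), names(m))
  if (anyNA(m) || any(m < 1))
    abort("copy map: every 16S copy number must be >= 1")
  m
}

#' Write a 16S copy-number map to JSON
#' @param copy_map named numeric vector
#' @param path output path
#' @export
write_copy_map <- function(copy_map, path) {
  jsonlite::write_json(as.list(copy_map), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

FCM_UNIT_FACTOR <- c(cells_per_L = 1, cells_per_mL = 1e3, cells_per_ml = 1e3,
                     cells_per_uL = 1e6, cells_per_ul = 1e6)

#' Read flow-cytometry observations
#'
#' CSV with header
#' `event_id,datetime,lat,lon,population,replicate,abundance,abundance_unit`,
#' one row per replicate measurement. Abundances are converted to cells per
#' liter at ingest and aggregated to one row per (event, population) with the
#' replicate mean and range.
#'
#' @param path CSV path
#' @param default_tz optional timezone for zone-less timestamps
#' @return an `fcm_table` data.frame: `event_id`, `timestamp`, `lat`, `lon`,
#'   `population`, `n`, `mean`, `min`, `max`, plus a `replicate_counts`
#'   list-column (cells/L)
#' @export
read_fcm <- function(path, default_tz = NULL) {
  if (!file.exists(path)) abort(sprintf("FCM file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("event_id", "datetime", "lat", "lon", "population", "replicate",
           "abundance", "abundance_unit")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    abort(sprintf("FCM file missing column(s): %s", paste(missing, collapse = ", ")))
  fac <- FCM_UNIT_FACTOR[df$abundance_unit]
  if (anyNA(fac))
    abort(sprintf("unknown FCM abundance unit: %s",
                  df$abundance_unit[is.na(fac)][1]))
  cells <- as.numeric(df$abundance) * unname(fac)
  if (anyNA(cells) || any(cells < 0)) abort("FCM abundances must be >= 0")
  ts <- parse_utc(df$datetime, default_tz)
  if (anyNA(ts))
    abort(sprintf("unparsable or zone-less FCM timestamp at row %d",
                  which(is.na(ts))[1]))
  fcm_table(event_id = as.character(df$event_id), timestamp = ts,
            lat = as.numeric(df$lat), lon = as.numeric(df$lon),
            population = as.character(df$population), cells_per_L = cells)
}

#' Aggregate replicate-level FCM measurements into an `fcm_table`
#'
#' @param event_id,timestamp,lat,lon,population,cells_per_L parallel vectors,
#'   one element per replicate measurement (cells/L)
#' @return an `fcm_table` (see [read_fcm()])
#' @export
fcm_table <- function(event_id, timestamp, lat, lon, population, cells_per_L) {
  if (any(cells_per_L < 0)) abort("FCM abundances must be >= 0")
  n <- length(cells_per_L)
  event_id <- rep_len(event_id, n); population <- rep_len(population, n)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  timestamp <- rep(timestamp, length.out = n)
  key <- paste(event_id, population, sep = "\r")
  idx <- split(seq_along(key), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]  # first-appearance order
  rows <- lapply(idx, function(i) {
    if (length(unique(lat[i])) > 1L || length(unique(lon[i])) > 1L)
      abort(sprintf("FCM event '%s' has inconsistent coordinates", event_id[i[1]]))
    v <- cells_per_L[i]
    data.frame(event_id = event_id[i[1]],
               lat = lat[i[1]], lon = lon[i[1]],
               population = population[i[1]],
               n = length(v), mean = mean(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$timestamp <- as.POSIXct(vapply(idx, function(i) as.numeric(timestamp[i[1]]),
                                     numeric(1)),
                              origin = "1970-01-01", tz = "UTC")
  out$replicate_counts <- I(lapply(idx, function(i) cells_per_L[i]))
  class(out) <- c("fcm_table", "data.frame")
  out
}

#' Write an `fcm_table` back to replicate-level CSV
#' @param x an `fcm_table`
#' @param path output path
#' @export
write_fcm <- function(x, path) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    v <- x$replicate_counts[[i]]
    data.frame(event_id = x$event_id[i], datetime = iso_utc(x$timestamp[i]),
               lat = fmt_num(x$lat[i]), lon = fmt_num(x$lon[i]),
               population = x$population[i], replicate = seq_along(v),
               abundance = fmt_num(v), abundance_unit = "cells_per_L")
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
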