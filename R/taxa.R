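split_ranks <- function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1]])

#' Assign ASVs to target taxa by rank-aware pattern matching
#'
#' Each ASV's taxonomy string is split into semicolon-delimited ranks; a
#' pattern matches when it occurs as a substring of any rank (so
#' `"Prochlorococcus"` matches the rank `"Prochlorococcus_MIT9313"`). An ASV
#' matched by patterns of two different target taxa is an ambiguity and a hard
#' error; an unmatched ASV maps to `"other"`.
#'
#' @param taxonomy named character vector, ASV id -> taxonomy string
#' @param patterns named character vector, target taxon -> substring pattern
#' @return named character vector, ASV id -> taxon label
#' @export
assign_taxa <- function(taxonomy, patterns) {
  if (is.null(names(patterns)) || any(names(patterns) == ""))
    abort("patterns must be a named vector (taxon -> pattern)")
  out <- stats::setNames(rep("other", length(taxonomy)), names(taxonomy))
  for (a in seq_along(taxonomy)) {
    ranks <- split_ranks(taxonomy[[a]])
    hit <- vapply(patterns, function(p) any(grepl(p, ranks, fixed = TRUE)),
                  logical(1))
    taxa_hit <- unique(names(patterns)[hit])
    if (length(taxa_hit) > 1L)
      abort(sprintf("ambiguous taxon assignment for ASV '%s': matches %s",
                    names(taxonomy)[a], paste(taxa_hit, collapse = ", ")))
    if (length(taxa_hit) == 1L) out[a] <- taxa_hit
  }
  out
}

#' Convert gene-copy abundance to cell abundance
#'
#' Divides a 16S gene-copy abundance by the taxon's genomic 16S copy number
#' (Prochlorococcus carries one copy per cell, Synechococcus two).
#'
#' @param copy_abundance gene copies per liter
#' @param copies_per_cell 16S gene copies per cell, >= 1
#' @return cells per liter
#' @export
cells_from_copies <- function(copy_abundance, copies_per_cell) {
  if (any(copies_per_cell < 1)) abort("copies_per_cell must be >= 1")
  copy_abundance / copies_per_cell
}

#' Default 16S copy numbers for the validated picocyanobacteria
#' @export
default_copy_map <- function() c(Prochlorococcus = 1, Synechococcus = 2)

lookup_copy_number <- function(taxon, copy_map) {
  if (taxon %in% names(copy_map)) return(copy_map[[taxon]])
  hit <- vapply(names(copy_map), function(p) grepl(p, taxon, fixed = TRUE),
                logical(1))
  if (sum(hit) > 1L)
    abort(sprintf("copy map patterns %s all match taxon '%s'",
                  paste(sQuote(names(copy_map)[hit]), collapse = ", "), taxon))
  if (sum(hit) == 1L) return(copy_map[[which(hit)]])
  NA_real_
}

#' Taxon-level absolute abundances
#'
#' For each site and taxon, member ASVs' gene-copy estimates are summed within
#' each retained (replicate, standard) slot — dropouts affect a whole sample x
#' standard slot uniformly, so sums combine like with like — then converted to
#' cells per liter via the taxon's 16S copy number, and finally summarized by
#' mean/min/max across slots. Taxa without a copy number stay in gene copies
#' per liter (`unit = "copies_per_L"`), mirroring that copy numbers are often
#' unknown outside well-characterized groups.
#'
#' @param matrix an `abundance_matrix` from [build_abundance_matrix()]
#' @param assignment named character vector from [assign_taxa()]; ASVs of the
#'   matrix absent from it are treated as `"other"`
#' @param copy_map named numeric vector, taxon (exact name or substring
#'   pattern) -> 16S copies per cell; see [default_copy_map()]
#' @return a `taxon_abundance`: list with `summary` (site_id, taxon, unit,
#'   mean, min, max, n) and `estimates` (long per-slot values)
#' @export
taxon_abundances <- function(matrix, assignment, copy_map = default_copy_map()) {
  long <- matrix$estimates
  tax <- assignment[long$asv_id]
  tax[is.na(tax)] <- "other"
  agg <- stats::aggregate(
    list(value = long$value),
    by = list(site_id = long$site_id, replicate = long$replicate,
              standard = long$standard, taxon = tax),
    FUN = sum)

  taxa_seen <- unique(agg$taxon)
  cpc <- vapply(taxa_seen, lookup_copy_number, numeric(1), copy_map = copy_map)
  no_members <- setdiff(names(copy_map), taxa_seen)
  no_members <- no_members[vapply(no_members, function(t)
    !any(vapply(taxa_seen, function(s) grepl(t, s, fixed = TRUE), logical(1))),
    logical(1))]
  if (length(no_members) > 0L) {
    warning(sprintf("taxon with no member ASVs: %s",
                    paste(no_members, collapse = ", ")), call. = FALSE)
    # emitted with all-zero estimates over every retained slot
    slot0 <- unique(long[c("site_id", "replicate", "standard")])
    zero <- do.call(rbind, lapply(no_members, function(t) {
      z <- slot0; z$taxon <- t; z$value <- 0; z
    }))
    agg <- rbind(agg, zero[names(agg)])
    cpc <- c(cpc, stats::setNames(copy_map[no_members], no_members))
  }

  k <- cpc[agg$taxon]
  agg$unit <- ifelse(is.na(k), "copies_per_L", "cells_per_L")
  agg$value <- ifelse(is.na(k), agg$value, agg$value / k)
  agg <- agg[order(agg$site_id, agg$taxon, agg$replicate, agg$standard), ,
             drop = FALSE]
  rownames(agg) <- NULL

  key <- paste(agg$site_id, agg$taxon, sep = "\r")
  idx <- split(seq_len(nrow(agg)), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]
  summary <- do.call(rbind, lapply(idx, function(i) {
    v <- agg$value[i]
    data.frame(site_id = agg$site_id[i[1]], taxon = agg$taxon[i[1]],
               unit = agg$unit[i[1]],
               mean = mean(v), min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 estimates = agg[c("site_id", "taxon", "replicate", "standard",
                                   "value", "unit")],
                 copy_map = copy_map),
            class = "taxon_abundance")
}

#' @export
print.taxon_abundance <- function(x, ...) {
  cat(sprintf("<taxon_abundance> %d sites x %d taxa (%s)\n",
              length(unique(x$summary$site_id)),
              length(unique(x$summary$taxon)),
              paste(unique(x$summary$taxon), collapse = ", ")))
  invisible(x)
}

#' Site-level ratio of two taxon abundances
#'
#' Ratio of site means (mean of slots), not mean of per-slot ratios: the
#' site-level abundance is the mean of its estimate set, and the ratio of
#' means is stable under slot dropout.
#'
#' @param tab a `taxon_abundance`
#' @param numerator,denominator taxon labels (default Prochlorococcus /
#'   Synechococcus)
#' @return data.frame `site_id`, `num_mean`, `den_mean`, `ratio`; sites with a
#'   non-positive denominator get `NA` and are listed in the `"excluded"`
#'   attribute
#' @export
abundance_ratio <- function(tab, numerator = "Prochlorococcus",
                            denominator = "Synechococcus") {
  s <- tab$summary
  num <- s[s$taxon == numerator, c("site_id", "mean")]
  den <- s[s$taxon == denominator, c("site_id", "mean")]
  m <- merge(num, den, by = "site_id", suffixes = c("_num", "_den"))
  if (nrow(m) == 0L)
    abort(sprintf("no sites carry both '%s' and '%s'", numerator, denominator))
  out <- data.frame(site_id = m$site_id, num_mean = m$mean_num,
                    den_mean = m$mean_den,
                    ratio = ifelse(m$mean_den > 0, m$mean_num / m$mean_den,
                                   NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- out$site_id[is.na(out$ratio)]
  out
}

#' Write taxon abundances to TSV
#' @param tab a `taxon_abundance`
#' @param path output path
#' @export
write_taxon_table <- function(tab, path) {
  s <- tab$summary
  cols <- lapply(s, function(col) if (is.numeric(col)) fmt_num(col) else col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(s), collapse = "\t"), con)
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read back a taxon abundance summary table
#' @param path TSV written by [write_taxon_table()]
#' @return data.frame with the summary columns
#' @export
read_taxon_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("taxon table not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(site_id = "character"))
}
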