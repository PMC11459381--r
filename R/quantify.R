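#' Total reads of one internal standard in one sample
#'
#' A single spiked genome's rRNA operons can denoise into several ASVs, so the
#' standard's read count is the sum over all ASV ids assigned to it. Assigned
#' ids absent from the table contribute zero.
#'
#' @param counts a [count_table()]
#' @param standard a [standard_spec()]
#' @param sample_id sample column to read
#' @return total standard reads (R_sj), numeric
#' @export
standard_reads <- function(counts, standard, sample_id) {
  if (!sample_id %in% counts$sample_ids)
    abort(sprintf("sample '%s' not in count table", sample_id))
  ids <- intersect(standard$asv_ids, counts$asv_ids)
  if (length(ids) == 0L) return(0)
  sum(counts$counts[ids, sample_id])
}

#' Volumetric gene-copy estimate from one internal standard
#'
#' The internal-standard correction: reads of a community ASV are converted to
#' absolute 16S gene copies per liter of filtered seawater by scaling with the
#' known copy load of a co-amplified spiked standard,
#' `R_ij * C_s / (R_sj * V_j)`.
#'
#' If the standard received zero reads in a sample (`R_sj = 0`) the estimate is
#' undefined; `NA` is returned for that element (a "standard dropout") and the
#' caller drops it from the estimate set.
#'
#' @param R_ij reads of the community ASV/taxon in sample j
#' @param C_s 16S copies of the standard added to the sample (known a priori)
#' @param R_sj reads of the standard in sample j
#' @param V_j filtered seawater volume, liters
#' @return gene copies per liter (vectorized); `NA` where `R_sj = 0`
#' @examples
#' volumetric_estimate(100, 1e6, 50, 2)  # 1e6 copies/L
#' @export
volumetric_estimate <- function(R_ij, C_s, R_sj, V_j) {
  if (any(C_s <= 0)) abort("C_s must be > 0")
  if (any(V_j <= 0)) abort("V_j must be > 0")
  if (any(R_sj < 0) || any(R_ij < 0)) abort("read counts must be >= 0")
  out <- R_ij * C_s / (R_sj * V_j)
  out[R_sj == 0] <- NA_real_
  out
}

#' Build the per-(site, ASV) absolute abundance matrix
#'
#' For every site and every community ASV, computes one volumetric gene-copy
#' estimate per (technical replicate, internal standard) pair — nine estimates
#' under the standard 3 x 3 design — then summarizes each estimate set by its
#' mean (or median), min, max and retained count `n`.
#'
#' Standard ASVs are removed from the community ASV universe; ASVs with zero
#' reads in every sample are excluded; an ASV with zero reads at one site but
#' reads elsewhere is retained there with estimate 0. A (replicate, standard)
#' slot with zero standard reads is a dropout: that single estimate is dropped
#' for all ASVs of the sample and logged, so `n < replicates * standards` for
#' that site. A site whose slots all drop out is excluded with a warning
#' record.
#'
#' @param counts a [count_table()] holding community and standard ASVs
#' @param metadata a `sample_metadata` data.frame covering every sample column
#' @param standards list of [standard_spec()]
#' @param aggregator "mean" (default, the tested path) or "median"
#' @return an `abundance_matrix`: list with `summary` (site_id, asv_id, mean,
#'   min, max, n), `estimates` (long; site_id, asv_id, replicate, standard,
#'   value), `slots` (per-(sample, standard) bookkeeping incl. dropouts),
#'   `dropouts`, `excluded_sites`, and provenance fields
#' @export
build_abundance_matrix <- function(counts, metadata, standards,
                                   aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  validate_standards(standards)
  missing <- setdiff(counts$sample_ids, metadata$sample_id)
  if (length(missing) > 0L)
    abort(sprintf("no metadata for sample(s): %s", paste(missing, collapse = ", ")))
  md <- metadata[metadata$sample_id %in% counts$sample_ids, , drop = FALSE]
  md <- md[order(md$site_id, md$replicate), , drop = FALSE]

  std_asvs <- unlist(lapply(standards, `[[`, "asv_ids"))
  comm <- setdiff(counts$asv_ids, std_asvs)
  if (length(comm) == 0L) abort("no community ASVs after removing standard ASVs")
  cm <- counts$counts[comm, , drop = FALSE]
  comm <- comm[rowSums(cm) > 0]
  cm <- cm[comm, , drop = FALSE]
  if (length(comm) == 0L) abort("all community ASVs have zero reads everywhere")

  std_names <- vapply(standards, `[[`, character(1), "name")
  n_std <- length(standards)

  # one slot per (sample, standard); R_sj and the scale factor per slot
  slots <- data.frame(
    site_id   = rep(md$site_id, each = n_std),
    sample_id = rep(md$sample_id, each = n_std),
    replicate = rep(md$replicate, each = n_std),
    standard  = rep(std_names, times = nrow(md)),
    stringsAsFactors = FALSE)
  slots$R_sj <- mapply(function(sid, std_i) {
    standard_reads(counts, standards[[std_i]], sid)
  }, slots$sample_id, match(slots$standard, std_names))
  slots$C_s <- vapply(standards, `[[`, numeric(1), "copies_added")[
    match(slots$standard, std_names)]
  slots$V_j <- md$volume_L[match(slots$sample_id, md$sample_id)]
  slots$dropped <- slots$R_sj == 0

  # estimates matrix: ASVs x slots, computed as (R_ij * C_s) / (R_sj * V_j)
  est <- matrix(NA_real_, nrow = length(comm), ncol = nrow(slots),
                dimnames = list(comm, NULL))
  for (k in seq_len(nrow(slots))) {
    if (slots$dropped[k]) next
    est[, k] <- (cm[, slots$sample_id[k]] * slots$C_s[k]) /
      (slots$R_sj[k] * slots$V_j[k])
  }

  sites <- unique(md$site_id)
  summary_rows <- vector("list", length(sites))
  excluded <- character(0)
  agg_fun <- if (aggregator == "mean") {
    function(m) rowMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 1L, stats::median, na.rm = TRUE)
  }
  for (si in seq_along(sites)) {
    cols <- which(slots$site_id == sites[si])
    keep <- cols[!slots$dropped[cols]]
    if (length(keep) == 0L) {
      excluded <- c(excluded, sites[si])
      next
    }
    m <- est[, keep, drop = FALSE]
    summary_rows[[si]] <- data.frame(
      site_id = sites[si], asv_id = comm,
      mean = agg_fun(m),
      min = apply(m, 1L, min), max = apply(m, 1L, max),
      n = length(keep), stringsAsFactors = FALSE, row.names = NULL)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  if (is.null(summary)) abort("every site lost all estimates to standard dropout")

  ok <- which(!slots$dropped & !slots$site_id %in% excluded)
  long <- data.frame(
    site_id = rep(slots$site_id[ok], each = length(comm)),
    asv_id = rep(comm, times = length(ok)),
    replicate = rep(slots$replicate[ok], each = length(comm)),
    standard = rep(slots$standard[ok], each = length(comm)),
    value = as.vector(est[, ok, drop = FALSE]),
    stringsAsFactors = FALSE)

  dropouts <- slots[slots$dropped,
                    c("site_id", "sample_id", "replicate", "standard")]
  rownames(dropouts) <- NULL
  if (length(excluded) > 0L)
    warning(sprintf("site(s) excluded (all estimates dropped out): %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)

  structure(list(summary = summary, estimates = long, slots = slots,
                 dropouts = dropouts, excluded_sites = excluded,
                 asv_ids = comm, standard_names = std_names,
                 aggregator = aggregator,
                 provenance = list(n_samples = nrow(md),
                                   n_sites = length(sites) - length(excluded))),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d sites x %d ASVs (%s of up to %d estimates/set)\n",
              length(unique(x$summary$site_id)), length(x$asv_ids),
              x$aggregator, length(x$standard_names) * max(x$slots$replicate)))
  if (nrow(x$dropouts) > 0L)
    cat(sprintf("  %d standard dropout(s)\n", nrow(x$dropouts)))
  if (length(x$excluded_sites) > 0L)
    cat(sprintf("  excluded sites: %s\n", paste(x$excluded_sites, collapse = ", ")))
  invisible(x)
}

#' Pooled technical percent-error summary
#'
#' For every estimate set (one site x one ASV, or one site x one taxon) with
#' at least two retained estimates and a positive mean, pools
#' `|estimate - set mean| / set mean * 100` over all estimates of all sets and
#' reports the pool together with its percentile (linear interpolation between
#' order statistics, R quantile type 7).
#'
#' @param x an `abundance_matrix` or `taxon_abundance`
#' @param subset optional ASV ids (or taxon names) restricting the pool
#' @param percentile probability of the reported upper percentile, default 0.95
#' @return an `error_summary`: list with `percent_errors`, `value` (the
#'   percentile of the pool), `percentile`, `n_estimates`, `n_sets`
#' @export
percent_error_summary <- function(x, subset = NULL, percentile = 0.95) {
  UseMethod("percent_error_summary")
}

pe_pool <- function(long, keycols, means, percentile) {
  pe <- abs(long$value - means) / means * 100
  if (length(pe) == 0L) abort("no estimates to summarize")
  structure(list(percent_errors = pe,
                 percentile = percentile,
                 value = unname(stats::quantile(pe, percentile, type = 7)),
                 n_estimates = length(pe),
                 n_sets = nrow(unique(long[keycols]))),
            class = "error_summary")
}

#' @export
percent_error_summary.abundance_matrix <- function(x, subset = NULL,
                                                   percentile = 0.95) {
  long <- x$estimates
  if (!is.null(subset)) long <- long[long$asv_id %in% subset, , drop = FALSE]
  s <- x$summary
  key <- paste(long$site_id, long$asv_id, sep = "\r")
  skey <- paste(s$site_id, s$asv_id, sep = "\r")
  i <- match(key, skey)
  # re-derive the arithmetic set mean: the pool is defined against it even if
  # the matrix was aggregated with the median
  mn <- stats::ave(long$value, key, FUN = mean)
  keep <- s$n[i] >= 2L & mn > 0
  pe_pool(long[keep, , drop = FALSE], c("site_id", "asv_id"), mn[keep], percentile)
}

#' @export
percent_error_summary.taxon_abundance <- function(x, subset = NULL,
                                                  percentile = 0.95) {
  long <- x$estimates
  if (!is.null(subset)) long <- long[long$taxon %in% subset, , drop = FALSE]
  key <- paste(long$site_id, long$taxon, sep = "\r")
  mn <- stats::ave(long$value, key, FUN = mean)
  nn <- stats::ave(long$value, key, FUN = length)
  keep <- nn >= 2L & mn > 0
  pe_pool(long[keep, , drop = FALSE], c("site_id", "taxon"), mn[keep], percentile)
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %d estimates in %d sets; p%g = %.4g%% (median %.4g%%)\n",
              x$n_estimates, x$n_sets, 100 * x$percentile, x$value,
              stats::median(x$percent_errors)))
  invisible(x)
}

abundance_wide <- function(x) {
  reps <- sort(unique(x$slots$replicate))
  slot_keys <- expand.grid(standard = x$standard_names, replicate = reps,
                           stringsAsFactors = FALSE)[, c("replicate", "standard")]
  slot_cols <- sprintf("est_r%d_s%d", slot_keys$replicate,
                       match(slot_keys$standard, x$standard_names))
  s <- x$summary
  wide <- data.frame(site_id = s$site_id, asv_id = s$asv_id, mean = s$mean,
                     min = s$min, max = s$max, n_estimates = s$n,
                     stringsAsFactors = FALSE)
  lk <- paste(x$estimates$site_id, x$estimates$asv_id, sep = "\r")
  wk <- paste(wide$site_id, wide$asv_id, sep = "\r")
  for (c in seq_len(nrow(slot_keys))) {
    sel <- x$estimates$replicate == slot_keys$replicate[c] &
      x$estimates$standard == slot_keys$standard[c]
    v <- rep(NA_real_, nrow(wide))
    v[match(lk[sel], wk)] <- x$estimates$value[sel]
    wide[[slot_cols[c]]] <- v
  }
  attr(wide, "standard_names") <- x$standard_names
  wide
}

#' Write an abundance matrix to TSV
#'
#' One row per (site, ASV): mean, min, max, n_estimates, then the individual
#' estimates in stable (replicate x standard) order as `est_r<i>_s<k>` columns
#' (`NA` marks a standard dropout). Values carry 12 significant digits, so a
#' read/re-write round trip is byte-identical.
#'
#' @param x an `abundance_matrix`, or a data.frame previously returned by
#'   [read_abundance_table()]
#' @param path output path
#' @export
write_abundance_table <- function(x, path) {
  wide <- if (inherits(x, "abundance_matrix")) abundance_wide(x) else x
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(sprintf("cannot write abundance table: %s", path)))
  on.exit(close(con))
  writeLines(paste(names(wide), collapse = "\t"), con)
  if (nrow(wide) > 0L) {
    cols <- lapply(wide, function(col) if (is.numeric(col)) fmt_num(col) else col)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a written abundance table
#' @param path TSV written by [write_abundance_table()]
#' @return data.frame with the same columns
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("abundance table not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(site_id = "character", asv_id = "character"))
}
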