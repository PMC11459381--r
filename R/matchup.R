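EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in kilometers
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorized)
#' @param radius_km sphere radius
#' @return distance in kilometers
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  if (any(abs(c(lat1, lat2)) > 90) ||
      any(c(lon1, lon2) < -180) || any(c(lon1, lon2) >= 360))
    abort("coordinates out of range")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Matchup criteria
#'
#' @param max_distance_km great-circle distance bound, km (default 20)
#' @param max_hours absolute time-offset bound, hours (default 6)
#' @param policy "nearest_one_to_one" (greedy by distance then |dt|; each site
#'   and each event used at most once) or "all_pairs"
#' @return a `matchup_criteria` list
#' @export
matchup_criteria <- function(max_distance_km = 20, max_hours = 6,
                             policy = c("nearest_one_to_one", "all_pairs")) {
  if (max_distance_km <= 0 || max_hours <= 0)
    abort("matchup bounds must be > 0")
  structure(list(max_distance_km = max_distance_km, max_hours = max_hours,
                 policy = match.arg(policy)),
            class = "matchup_criteria")
}

#' Collapse replicate metadata to one position/time per site
#'
#' A site's position and time are the means over its technical replicates,
#' which are drawn from the same underway stream minutes apart.
#'
#' @param metadata a `sample_metadata` data.frame
#' @return data.frame `site_id`, `lat`, `lon`, `timestamp`
#' @export
site_positions <- function(metadata) {
  idx <- split(seq_len(nrow(metadata)), metadata$site_id)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(site_id = metadata$site_id[i[1]],
               lat = mean(metadata$lat[i]), lon = mean(metadata$lon[i]),
               stringsAsFactors = FALSE)
  }))
  out$timestamp <- as.POSIXct(
    vapply(idx, function(i) mean(as.numeric(metadata$timestamp[i])), numeric(1)),
    origin = "1970-01-01", tz = "UTC")
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fcm_events <- function(fcm) {
  first <- !duplicated(fcm$event_id)
  ev <- data.frame(event_id = fcm$event_id[first], lat = fcm$lat[first],
                   lon = fcm$lon[first], stringsAsFactors = FALSE)
  ev$timestamp <- fcm$timestamp[first]
  ev
}

#' Pair amplicon sites with FCM events
#'
#' Candidate pairs are all (site, event) combinations within the distance and
#' time bounds. Under the default `nearest_one_to_one` policy candidates are
#' sorted by (distance, |dt|, site_id, event_id) and accepted greedily so each
#' site and each event appears in at most one pair; the lexicographic
#' tie-break makes the pairing deterministic under input reordering.
#'
#' @param sites `sample_metadata` (collapsed via [site_positions()]) or a
#'   data.frame with `site_id`, `lat`, `lon`, `timestamp`
#' @param fcm an `fcm_table` or a data.frame of events with `event_id`, `lat`,
#'   `lon`, `timestamp`
#' @param criteria a [matchup_criteria()]
#' @return data.frame `site_id`, `event_id`, `distance_km`, `delta_hours`
#'   (signed, event minus site); zero rows when nothing qualifies
#' @export
find_matchups <- function(sites, fcm, criteria = matchup_criteria()) {
  if (inherits(sites, "sample_metadata")) sites <- site_positions(sites)
  ev <- if ("population" %in% names(fcm)) fcm_events(fcm) else fcm
  g <- expand.grid(i = seq_len(nrow(sites)), j = seq_len(nrow(ev)))
  d <- haversine_km(sites$lat[g$i], sites$lon[g$i], ev$lat[g$j], ev$lon[g$j])
  dt <- as.numeric(difftime(ev$timestamp[g$j], sites$timestamp[g$i],
                            units = "hours"))
  keep <- d <= criteria$max_distance_km & abs(dt) <= criteria$max_hours
  cand <- data.frame(site_id = sites$site_id[g$i[keep]],
                     event_id = ev$event_id[g$j[keep]],
                     distance_km = d[keep], delta_hours = dt[keep],
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$distance_km, abs(cand$delta_hours),
                     cand$site_id, cand$event_id), , drop = FALSE]
  if (criteria$policy == "nearest_one_to_one" && nrow(cand) > 0L) {
    used_site <- character(0); used_ev <- character(0)
    take <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (cand$site_id[r] %in% used_site || cand$event_id[r] %in% used_ev) next
      take[r] <- TRUE
      used_site <- c(used_site, cand$site_id[r])
      used_ev <- c(used_ev, cand$event_id[r])
    }
    cand <- cand[take, , drop = FALSE]
  }
  cand <- cand[order(cand$site_id, cand$event_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Join matchup pairs with amplicon and FCM abundances
#'
#' @param pairs output of [find_matchups()]
#' @param taxon_tab a `taxon_abundance`
#' @param fcm an `fcm_table`
#' @param populations taxon/population labels compared across instruments
#' @return data.frame, one row per (pair, population):
#'   amplicon mean/min/max and FCM mean/min/max, cells/L
#' @export
matchup_table <- function(pairs, taxon_tab, fcm,
                          populations = c("Prochlorococcus", "Synechococcus")) {
  s <- taxon_tab$summary
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    do.call(rbind, lapply(populations, function(p) {
      a <- s[s$site_id == pairs$site_id[r] & s$taxon == p, , drop = FALSE]
      f <- fcm[fcm$event_id == pairs$event_id[r] & fcm$population == p, ,
               drop = FALSE]
      if (nrow(a) == 0L || nrow(f) == 0L) return(NULL)
      data.frame(site_id = pairs$site_id[r], event_id = pairs$event_id[r],
                 population = p,
                 distance_km = pairs$distance_km[r],
                 delta_hours = pairs$delta_hours[r],
                 lat = f$lat[1],
                 amp_mean = a$mean[1], amp_min = a$min[1], amp_max = a$max[1],
                 fcm_mean = f$mean[1], fcm_min = f$min[1], fcm_max = f$max[1],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(0), event_id = character(0),
                      population = character(0), distance_km = numeric(0),
                      delta_hours = numeric(0), lat = numeric(0),
                      amp_mean = numeric(0), amp_min = numeric(0),
                      amp_max = numeric(0), fcm_mean = numeric(0),
                      fcm_min = numeric(0), fcm_max = numeric(0))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares regression of paired instrument values
#'
#' Fits `y = intercept + slope * x` by explicit closed-form OLS and reports
#' the Pearson correlation, plus two auditing statistics: the slope with the
#' intercept forced through the origin, and the slope of the reversed
#' orientation (`x` regressed on `y`).
#'
#' @param x predictor values (FCM means, by convention)
#' @param y response values (amplicon means, by convention)
#' @return a `regression_result`: `n`, `slope`, `intercept`, `pearson_r`,
#'   `slope_origin`, `slope_reversed`
#' @export
paired_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort(sprintf("paired_regression needs >= 3 points, got %d", n))
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) abort("degenerate regression: zero variance in x")
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  structure(list(n = n, slope = slope, intercept = my - slope * mx,
                 pearson_r = r,
                 slope_origin = sum(x * y) / sum(x^2),
                 slope_reversed = if (syy == 0) NA_real_ else sxy / syy),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, slope = %.4g, intercept = %.4g, r = %.4f\n",
              x$n, x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Cross-instrument regression validation
#'
#' Builds the amplicon-vs-FCM comparisons from a matchup table: the pooled
#' cell-count regression over all populations (the headline statistic), one
#' regression per population, and the ratio regression (first taxon over
#' second), restricted to pairs where both taxa are positive in both
#' instruments. FCM means are `x`, amplicon means `y`.
#'
#' @param match_tbl output of [matchup_table()]
#' @param ratio_taxa length-2 character; numerator and denominator of the
#'   ratio comparison
#' @return list with `pooled`, `per_population` (named list), `ratio`
#'   (regression or `NULL` with `ratio_flag` saying why), `n_pairs`
#' @export
validate_matchups <- function(match_tbl,
                              ratio_taxa = c("Prochlorococcus", "Synechococcus")) {
  if (nrow(match_tbl) == 0L) abort("no matchup rows to validate")
  pooled <- paired_regression(match_tbl$fcm_mean, match_tbl$amp_mean)
  per_pop <- lapply(split(match_tbl, match_tbl$population), function(d) {
    tryCatch(paired_regression(d$fcm_mean, d$amp_mean), error = function(e) NULL)
  })
  num <- match_tbl[match_tbl$population == ratio_taxa[1], , drop = FALSE]
  den <- match_tbl[match_tbl$population == ratio_taxa[2], , drop = FALSE]
  m <- merge(num, den, by = c("site_id", "event_id"), suffixes = c("_n", "_d"))
  ok <- m$amp_mean_n > 0 & m$amp_mean_d > 0 & m$fcm_mean_n > 0 & m$fcm_mean_d > 0
  m <- m[ok, , drop = FALSE]
  ratio <- NULL; flag <- NA_character_
  if (nrow(m) >= 3L) {
    ratio <- tryCatch(paired_regression(m$fcm_mean_n / m$fcm_mean_d,
                                        m$amp_mean_n / m$amp_mean_d),
                      error = function(e) { flag <<- conditionMessage(e); NULL })
  } else flag <- sprintf("only %d ratio pairs", nrow(m))
  list(pooled = pooled, per_population = per_pop, ratio = ratio,
       ratio_flag = flag,
       n_pairs = length(unique(paste(match_tbl$site_id, match_tbl$event_id))))
}

#' Distance-threshold sensitivity analysis
#'
#' Re-runs the matchup and both regressions over a grid of distance bounds.
#' The pair count is non-decreasing in the bound (relaxing the criterion only
#' adds candidates, also under the one-to-one policy) — asserted.
#'
#' @param sites site positions (see [find_matchups()])
#' @param fcm an `fcm_table`
#' @param taxon_tab a `taxon_abundance`
#' @param distance_grid ascending km bounds, e.g. `c(10, 20, 30)`
#' @param max_hours time bound, hours
#' @param policy pairing policy
#' @param populations populations compared
#' @return data.frame, one row per bound: `max_distance_km`, `n_pairs`,
#'   `cell_slope`, `cell_intercept`, `cell_r`, `ratio_slope`, `ratio_r`,
#'   `ratio_n`, `flag` (NA, or why a regression is absent)
#' @export
sensitivity_analysis <- function(sites, fcm, taxon_tab,
                                 distance_grid = c(10, 20, 30), max_hours = 6,
                                 policy = "nearest_one_to_one",
                                 populations = c("Prochlorococcus",
                                                 "Synechococcus")) {
  if (length(distance_grid) == 0L || is.unsorted(distance_grid))
    abort("distance_grid must be non-empty and ascending")
  rows <- lapply(distance_grid, function(b) {
    pairs <- find_matchups(sites, fcm,
                           matchup_criteria(b, max_hours, policy = policy))
    row <- data.frame(max_distance_km = b, n_pairs = nrow(pairs),
                      cell_slope = NA_real_, cell_intercept = NA_real_,
                      cell_r = NA_real_, ratio_slope = NA_real_,
                      ratio_r = NA_real_, ratio_n = NA_integer_,
                      flag = NA_character_, stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L) { row$flag <- "no pairs"; return(row) }
    mt <- matchup_table(pairs, taxon_tab, fcm, populations)
    v <- tryCatch(validate_matchups(mt, populations), error = function(e) NULL)
    if (is.null(v)) { row$flag <- "regression failed"; return(row) }
    row$cell_slope <- v$pooled$slope
    row$cell_intercept <- v$pooled$intercept
    row$cell_r <- v$pooled$pearson_r
    if (!is.null(v$ratio)) {
      row$ratio_slope <- v$ratio$slope
      row$ratio_r <- v$ratio$pearson_r
      row$ratio_n <- v$ratio$n
    } else row$flag <- v$ratio_flag
    row
  })
  out <- do.call(rbind, rows)
  stopifnot(!is.unsorted(out$n_pairs))  # monotonicity in the bound
  rownames(out) <- NULL
  out
}

#' Diagnostic plots for the matchup validation
#'
#' Writes a two-panel PDF: the along-transect abundance comparison (amplicon
#' means with ranges, FCM means at matchup sites) and the amplicon-vs-FCM
#' scatter on log axes with the 1:1 line.
#'
#' @param match_tbl output of [matchup_table()]
#' @param path PDF output path
#' @export
plot_matchups <- function(match_tbl, path) {
  grDevices::pdf(path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  pops <- unique(match_tbl$population)
  cols <- stats::setNames(seq_along(pops) + 1L, pops)
  pos <- log10(pmax(match_tbl$amp_mean, 1))
  graphics::plot(match_tbl$lat, pos, col = cols[match_tbl$population],
                 pch = 19, xlab = "latitude (deg N)",
                 ylab = "log10 amplicon cells/L", main = "transect")
  graphics::segments(match_tbl$lat, log10(pmax(match_tbl$amp_min, 1)),
                     match_tbl$lat, log10(pmax(match_tbl$amp_max, 1)),
                     col = cols[match_tbl$population])
  graphics::points(match_tbl$lat, log10(pmax(match_tbl$fcm_mean, 1)),
                   col = cols[match_tbl$population], pch = 0)
  graphics::legend("bottomleft", legend = pops, col = cols, pch = 19, cex = 0.8)
  lim <- range(c(match_tbl$amp_mean, match_tbl$fcm_mean))
  graphics::plot(match_tbl$fcm_mean, match_tbl$amp_mean, log = "xy",
                 col = cols[match_tbl$population], pch = 19, xlim = lim,
                 ylim = lim, xlab = "FCM cells/L", ylab = "amplicon cells/L",
                 main = "matchups")
  graphics::abline(0, 1, lty = 2)
  invisible(path)
}
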