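KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180

#' Default simulated community
#'
#' Two focal picocyanobacteria with opposed logistic latitude profiles — a
#' Prochlorococcus-like taxon rising southward into the subtropical gyre and a
#' Synechococcus-like taxon rising northward into the transition zone — plus
#' two background heterotroph taxa whose flat baseline is calibrated to the
#' target spike fraction. Abundances are surface-ocean-realistic (cells/L).
#'
#' @return list of taxon definitions
#' @export
default_sim_taxa <- function() {
  list(
    list(name = "Prochlorococcus", copies_per_cell = 1, n_asvs = 3,
         profile = "logistic_south", hi = 2e8, lo = 1e6, lat0 = 32.5,
         width = 1.2, background = FALSE, fcm = TRUE,
         lineage = "Bacteria;Cyanobacteria;Cyanobacteriia;Synechococcales;Prochlorococcaceae;Prochlorococcus"),
    list(name = "Synechococcus", copies_per_cell = 2, n_asvs = 2,
         profile = "logistic_north", hi = 8e7, lo = 5e5, lat0 = 32.5,
         width = 1.2, background = FALSE, fcm = TRUE,
         lineage = "Bacteria;Cyanobacteria;Cyanobacteriia;Synechococcales;Synechococcaceae;Synechococcus"),
    list(name = "Pelagibacter", copies_per_cell = 1, n_asvs = 2,
         profile = "flat", hi = 4e8, lo = 4e8, lat0 = NA, width = NA,
         background = TRUE, fcm = FALSE,
         lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;Pelagibacteraceae;Pelagibacter"),
    list(name = "Roseobacter", copies_per_cell = 4, n_asvs = 1,
         profile = "flat", hi = 2e7, lo = 2e7, lat0 = NA, width = NA,
         background = TRUE, fcm = FALSE,
         lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Roseobacteraceae;Roseobacter"))
}

#' Default spiked genomic standards
#'
#' Three non-marine organisms with approximate published genome sizes and 16S
#' operon counts; each contributes its nominal mass per sample.
#'
#' @param mass_ng genomic DNA mass per standard per sample, nanograms
#' @return list of parameter lists (ASV ids are attached by [make_transect()])
#' @export
default_sim_standards <- function(mass_ng = 4) {
  list(
    list(name = "Blautia producta", genome_size_bp = 6.30e6,
         copies_per_genome = 6, mass_ng = mass_ng),
    list(name = "Deinococcus radiodurans", genome_size_bp = 3.28e6,
         copies_per_genome = 3, mass_ng = mass_ng),
    list(name = "Thermus thermophilus", genome_size_bp = 2.12e6,
         copies_per_genome = 2, mass_ng = mass_ng))
}

#' Simulation configuration
#'
#' Defaults state the emulated study: 65 sites at 46-km spacing sampled in
#' triplicate, three ~4-ng genomic standards making up ~1% of total 16S
#' copies, ~1e5 reads per sample, 2 L filtered per replicate, FCM three times
#' daily in triplicate.
#'
#' @param n_sites number of transect sites
#' @param site_spacing_km along-track spacing between sites, km
#' @param replicates_per_site technical replicates per site
#' @param standards list from [default_sim_standards()] (name, mass_ng,
#'   genome_size_bp, copies_per_genome per entry)
#' @param target_spike_fraction standard copies as a fraction of all 16S
#'   copies at the transect-mean sample, in (0, 0.5)
#' @param reads_per_sample median sequencing depth
#' @param depth_sdlog lognormal sdlog of per-sample depth (0.1 ~ +/-20%)
#' @param volume_L nominal filtered volume per replicate, liters
#' @param volume_jitter uniform relative jitter on volumes
#' @param taxa list from [default_sim_taxa()]
#' @param replicate_noise_sigma lognormal sigma of per-replicate capture
#'   efficiency (community taxa only; standards are added at lysis, after
#'   filtration, and carry no capture noise)
#' @param amplification_bias optional named vector, taxon -> multiplicative
#'   amplification efficiency (default all 1)
#' @param fcm_per_day FCM sampling events per day
#' @param fcm_noise_sigma lognormal sigma of FCM replicate counts
#' @param cruise_speed_kmh ship speed; with the default spacing this yields a
#'   ~9-day transect and ~27 FCM events
#' @param start_lat,start_lon transect origin, heading due north
#' @param start_time ISO 8601 UTC start of sampling
#' @param seed RNG seed; the three generator stages draw from seed, seed+1,
#'   seed+2
#' @return a `sim_config` list
#' @export
sim_config <- function(n_sites = 65, site_spacing_km = 46,
                       replicates_per_site = 3,
                       standards = default_sim_standards(),
                       target_spike_fraction = 0.01,
                       reads_per_sample = 1e5, depth_sdlog = 0.1,
                       volume_L = 2, volume_jitter = 0.1,
                       taxa = default_sim_taxa(),
                       replicate_noise_sigma = 0.1,
                       amplification_bias = NULL,
                       fcm_per_day = 3, fcm_noise_sigma = 0.05,
                       cruise_speed_kmh = 13.7,
                       start_lat = 23.0, start_lon = -158.0,
                       start_time = "2021-11-20T00:00:00Z", seed = 1L) {
  if (n_sites < 1 || replicates_per_site < 1 || reads_per_sample < 1 ||
      fcm_per_day < 1 || site_spacing_km <= 0 || volume_L <= 0 ||
      cruise_speed_kmh <= 0)
    abort("sim_config: counts and scales must be positive")
  if (target_spike_fraction <= 0 || target_spike_fraction >= 0.5)
    abort("target_spike_fraction must lie in (0, 0.5)")
  structure(as.list(environment()), class = "sim_config")
}

profile_cells <- function(tx, lat) {
  switch(tx$profile,
         flat = rep(tx$hi, length(lat)),
         logistic_south = tx$lo + (tx$hi - tx$lo) /
           (1 + exp((lat - tx$lat0) / tx$width)),
         logistic_north = tx$lo + (tx$hi - tx$lo) /
           (1 + exp(-(lat - tx$lat0) / tx$width)),
         abort(sprintf("unknown profile '%s'", tx$profile)))
}

slugify <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Lay out the ground-truth cruise transect
#'
#' Sites are placed due north at the configured spacing with monotone
#' timestamps derived from the ship speed; per-replicate volumes are jittered;
#' true cell abundances follow each taxon's latitude profile, with background
#' taxa scaled once so the standards' copy load is the target fraction of all
#' 16S copies at the transect-mean sample.
#'
#' @param config a [sim_config()]
#' @return a `ground_truth`: `sites`, `samples`, `taxa` (with attached ASV ids
#'   and within-taxon proportions, and the calibrated `scale`), `standards`
#'   (full [standard_spec()]s), `cells` (site x taxon matrix, cells/L),
#'   `copies` (cells x copy number), and the track parameters
#' @export
make_transect <- function(config) {
  set.seed(config$seed)
  n <- config$n_sites
  lat <- config$start_lat + (seq_len(n) - 1) * config$site_spacing_km / KM_PER_DEG_LAT
  if (any(lat > 90)) abort("transect runs off the pole; shorten it")
  t0 <- parse_utc(config$start_time)
  hours <- (seq_len(n) - 1) * config$site_spacing_km / config$cruise_speed_kmh
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                      lat = lat, lon = config$start_lon,
                      stringsAsFactors = FALSE)
  sites$timestamp <- t0 + hours * 3600

  R <- config$replicates_per_site
  samples <- data.frame(
    sample_id = sprintf("S%03d_r%d", rep(seq_len(n), each = R),
                        rep(seq_len(R), times = n)),
    site_id = rep(sites$site_id, each = R),
    replicate = rep(seq_len(R), times = n),
    volume_L = config$volume_L *
      stats::runif(n * R, 1 - config$volume_jitter, 1 + config$volume_jitter),
    lat = rep(sites$lat, each = R), lon = config$start_lon,
    stringsAsFactors = FALSE)
  samples$timestamp <- rep(sites$timestamp, each = R) +
    (samples$replicate - 1) * 120  # replicates drawn minutes apart

  taxa <- lapply(config$taxa, function(tx) {
    slug <- slugify(tx$name)
    tx$asv_ids <- sprintf("asv_%s_%02d", slug, seq_len(tx$n_asvs))
    p <- 0.5^(seq_len(tx$n_asvs) - 1)
    tx$asv_props <- p / sum(p)
    tx$scale <- 1
    tx
  })
  standards <- lapply(config$standards, function(s) {
    standard_spec(s$name, s$mass_ng, s$genome_size_bp, s$copies_per_genome,
                  asv_ids = sprintf("asv_std_%s", slugify(s$name)))
  })
  validate_standards(standards)

  cells <- vapply(taxa, function(tx) profile_cells(tx, sites$lat),
                  numeric(n))
  if (n == 1L) cells <- matrix(cells, nrow = 1L)
  colnames(cells) <- vapply(taxa, `[[`, character(1), "name")
  rownames(cells) <- sites$site_id

  # calibrate background taxa so the mean sample hits the target spike fraction
  cpc <- vapply(taxa, `[[`, numeric(1), "copies_per_cell")
  C_total <- sum(vapply(standards, `[[`, numeric(1), "copies_added"))
  load <- colMeans(cells) * cpc * config$volume_L  # copies per mean sample
  bg <- vapply(taxa, `[[`, logical(1), "background")
  f <- config$target_spike_fraction
  need <- C_total * (1 - f) / f
  if (!any(bg)) {
    if (abs(sum(load) - need) / need > 0.5)
      warning("no background taxa to calibrate; realized spike fraction will miss the target",
              call. = FALSE)
  } else {
    a <- (need - sum(load[!bg])) / sum(load[bg])
    if (a <= 0)
      abort("target spike fraction unattainable: focal taxa alone exceed the community budget")
    cells[, bg] <- cells[, bg, drop = FALSE] * a
    for (i in which(bg)) taxa[[i]]$scale <- a
  }

  copies <- sweep(cells, 2L, cpc, `*`)
  structure(list(config = config, sites = sites, samples = samples,
                 taxa = taxa, standards = standards,
                 cells = cells, copies = copies,
                 track = list(t0 = t0, lat0 = config$start_lat,
                              lon = config$start_lon,
                              speed_kmh = config$cruise_speed_kmh,
                              end = sites$timestamp[n])),
            class = "ground_truth")
}

#' True cell abundance of one taxon at an arbitrary latitude
#' @param truth a `ground_truth`
#' @param taxon taxon name
#' @param lat latitude (vectorized)
#' @return cells per liter
#' @export
true_cells_at <- function(truth, taxon, lat) {
  nm <- vapply(truth$taxa, `[[`, character(1), "name")
  tx <- truth$taxa[[match(taxon, nm)]]
  if (is.null(tx)) abort(sprintf("unknown taxon '%s'", taxon))
  profile_cells(tx, lat) * tx$scale
}

#' Simulate amplicon read counts from the ground truth
#'
#' For each sample, every community ASV's filter load is
#' `cells x within-taxon proportion x copies_per_cell x volume x capture`,
#' with one lognormal capture-efficiency draw per replicate; standard loads
#' are exactly `C_s` (standards are added to the lysis buffer after
#' filtration, so they carry no capture noise). Reads are drawn multinomially
#' with probabilities proportional to load times amplification bias, at a
#' lognormally jittered per-sample depth.
#'
#' @param truth a `ground_truth` from [make_transect()]
#' @param config a [sim_config()]; defaults to the one inside `truth`
#' @return list with `counts` ([count_table()]), `metadata`
#'   (`sample_metadata`), `standards`, `taxonomy`, `copy_map` (populations
#'   with known 16S copy number), `capture` (the per-sample draws), and
#'   `truth`
#' @export
simulate_reads <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  smp <- truth$samples
  n_samp <- nrow(smp)
  sigma <- config$replicate_noise_sigma
  capture <- if (sigma > 0) stats::rlnorm(n_samp, 0, sigma) else rep(1, n_samp)
  depth <- if (config$depth_sdlog > 0) {
    round(stats::rlnorm(n_samp, log(config$reads_per_sample), config$depth_sdlog))
  } else rep(round(config$reads_per_sample), n_samp)

  taxa <- truth$taxa
  tax_names <- vapply(taxa, `[[`, character(1), "name")
  comm_asvs <- unlist(lapply(taxa, `[[`, "asv_ids"))
  comm_taxon <- rep(tax_names, vapply(taxa, function(t) length(t$asv_ids),
                                      integer(1)))
  comm_prop <- unlist(lapply(taxa, `[[`, "asv_props"))
  cpc <- vapply(taxa, `[[`, numeric(1), "copies_per_cell")[
    match(comm_taxon, tax_names)]
  std_asvs <- unlist(lapply(truth$standards, `[[`, "asv_ids"))
  std_copies <- unlist(lapply(truth$standards, function(s)
    rep(s$copies_added / length(s$asv_ids), length(s$asv_ids))))

  bias <- rep(1, length(comm_asvs))
  if (!is.null(config$amplification_bias)) {
    b <- config$amplification_bias[comm_taxon]
    bias <- ifelse(is.na(b), 1, b)
  }

  site_i <- match(smp$site_id, truth$sites$site_id)
  counts <- matrix(0, nrow = length(comm_asvs) + length(std_asvs),
                   ncol = n_samp,
                   dimnames = list(c(comm_asvs, std_asvs), smp$sample_id))
  for (j in seq_len(n_samp)) {
    comm_load <- truth$cells[site_i[j], comm_taxon] * comm_prop * cpc *
      smp$volume_L[j] * capture[j]
    w <- c(comm_load * bias, std_copies)
    counts[, j] <- stats::rmultinom(1L, depth[j], w / sum(w))
  }

  metadata <- sample_metadata(smp$sample_id, smp$site_id, smp$replicate,
                              smp$volume_L, "L", smp$lat, smp$lon,
                              smp$timestamp)
  taxonomy <- c(
    stats::setNames(unlist(lapply(taxa, function(t)
      rep(t$lineage, length(t$asv_ids)))), comm_asvs),
    stats::setNames(vapply(truth$standards, function(s)
      sprintf("Bacteria;spike-in;%s", gsub(" ", "_", s$name)), character(1))[
        rep(seq_along(truth$standards),
            vapply(truth$standards, function(s) length(s$asv_ids), integer(1)))],
      std_asvs))
  fcm_tax <- vapply(taxa, `[[`, logical(1), "fcm")
  copy_map <- stats::setNames(
    vapply(taxa[fcm_tax], `[[`, numeric(1), "copies_per_cell"),
    tax_names[fcm_tax])

  list(counts = count_table(counts), metadata = metadata,
       standards = truth$standards, taxonomy = taxonomy, copy_map = copy_map,
       capture = stats::setNames(capture, smp$sample_id), truth = truth)
}

#' Simulate flow-cytometry observations along the track
#'
#' Events are placed at the configured daily cadence along the same track
#' (hence offset in space and time from the amplicon sites); each focal
#' population gets triplicate counts equal to the true cell abundance at the
#' event's interpolated position times lognormal noise.
#'
#' @param truth a `ground_truth`
#' @param config a [sim_config()]; defaults to the one inside `truth`
#' @return an `fcm_table` (see [read_fcm()])
#' @export
simulate_fcm <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  tr <- truth$track
  step_h <- 24 / config$fcm_per_day
  total_h <- as.numeric(difftime(tr$end, tr$t0, units = "hours"))
  ev_h <- seq(0, total_h, by = step_h)
  ev_lat <- tr$lat0 + ev_h * tr$speed_kmh / KM_PER_DEG_LAT
  ev_time <- tr$t0 + ev_h * 3600
  pops <- vapply(truth$taxa, `[[`, character(1), "name")[
    vapply(truth$taxa, `[[`, logical(1), "fcm")]
  n_rep <- 3L
  rows <- expand.grid(rep = seq_len(n_rep), pop = pops,
                      ev = seq_along(ev_h), stringsAsFactors = FALSE)
  true_cells <- mapply(function(p, e) true_cells_at(truth, p, ev_lat[e]),
                       rows$pop, rows$ev, USE.NAMES = FALSE)
  noise <- if (config$fcm_noise_sigma > 0) {
    stats::rlnorm(nrow(rows), 0, config$fcm_noise_sigma)
  } else rep(1, nrow(rows))
  fcm_table(event_id = sprintf("F%03d", rows$ev),
            timestamp = ev_time[rows$ev],
            lat = ev_lat[rows$ev], lon = tr$lon,
            population = rows$pop,
            cells_per_L = true_cells * noise)
}

#' Run the full generator and write every pipeline input format
#'
#' Produces, under `dir`: `counts.tsv`, `meta.csv`, `standards.json`,
#' `taxonomy.tsv`, `copymap.json`, `fcm.csv` — exactly the formats the
#' ingest functions read — plus `truth.tsv` with the per-site true abundances.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with `sim` (from [simulate_reads()]), `fcm`, and
#'   the file `paths`
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_transect(config)
  sim <- simulate_reads(truth, config)
  fcm <- simulate_fcm(truth, config)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "meta.csv"),
                standards = file.path(dir, "standards.json"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                copy_map = file.path(dir, "copymap.json"),
                fcm = file.path(dir, "fcm.csv"),
                truth = file.path(dir, "truth.tsv"))
  write_count_table(sim$counts, paths$counts)
  write_metadata(sim$metadata, paths$metadata)
  write_standards(sim$standards, paths$standards)
  write_taxonomy(sim$taxonomy, paths$taxonomy)
  write_copy_map(sim$copy_map, paths$copy_map)
  write_fcm(fcm, paths$fcm)
  tax_names <- colnames(truth$cells)
  tt <- data.frame(site_id = rep(truth$sites$site_id, times = length(tax_names)),
                   lat = rep(truth$sites$lat, times = length(tax_names)),
                   datetime = iso_utc(rep(truth$sites$timestamp,
                                          times = length(tax_names))),
                   taxon = rep(tax_names, each = nrow(truth$cells)),
                   true_cells_per_L = fmt_num(as.vector(truth$cells)),
                   true_copies_per_L = fmt_num(as.vector(truth$copies)))
  utils::write.table(tt, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sim = sim, fcm = fcm, paths = paths))
}
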