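# builders for small in-code fixtures; no files larger than a few lines ever
# touch disk, and only under tempdir()

# a standard whose derived copy load is (up to 1 ulp) a chosen value
std_with_copies <- function(name, copies, asv_ids, genome_size_bp = 3e6,
                            copies_per_genome = 1) {
  mass_ng <- copies * (genome_size_bp * 650 / 6.02214076e23) * 1e9 /
    copies_per_genome
  standard_spec(name, mass_ng, genome_size_bp, copies_per_genome, asv_ids)
}

mk_meta <- function(sample_id, site_id, replicate, volume_L = 2,
                    lat = 30, lon = -150) {
  n <- length(sample_id)
  sample_metadata(sample_id, site_id, replicate, rep_len(volume_L, n), "L",
                  rep_len(lat, n), rep_len(lon, n),
                  as.POSIXct("2021-11-20 00:00:00", tz = "UTC") +
                    3600 * seq_len(n))
}

# one site, 3 replicates, 3 standards, 2 community ASVs; all standard reads
# positive unless zeroed by the caller
clean_site_counts <- function(std_reads = matrix(c(50, 60, 55,
                                                   40, 45, 42,
                                                   30, 35, 33),
                                                 nrow = 3, byrow = TRUE)) {
  m <- rbind(asv_a = c(100, 110, 90),
             asv_b = c(10, 12, 8),
             std1 = std_reads[1, ], std2 = std_reads[2, ],
             std3 = std_reads[3, ])
  colnames(m) <- c("X_r1", "X_r2", "X_r3")
  count_table(m)
}

clean_site_standards <- function() {
  list(std_with_copies("stdA", 1e6, "std1"),
       std_with_copies("stdB", 2e6, "std2"),
       std_with_copies("stdC", 5e5, "std3"))
}

clean_site_meta <- function(volume_L = c(2, 1.9, 2.1)) {
  mk_meta(c("X_r1", "X_r2", "X_r3"), "X", 1:3, volume_L)
}

# a small but fully featured simulation config for fast tests
small_sim <- function(seed = 1, n_sites = 10, ...) {
  sim_config(n_sites = n_sites, seed = seed, ...)
}

# event table for matchup tests (no FCM populations needed)
mk_events <- function(event_id, lat, lon, hours,
                      t0 = as.POSIXct("2021-11-20 00:00:00", tz = "UTC")) {
  data.frame(event_id = event_id, lat = lat, lon = lon,
             timestamp = t0 + hours * 3600, stringsAsFactors = FALSE)
}

mk_sites <- function(site_id, lat, lon, hours,
                     t0 = as.POSIXct("2021-11-20 00:00:00", tz = "UTC")) {
  data.frame(site_id = site_id, lat = lat, lon = lon,
             timestamp = t0 + hours * 3600, stringsAsFactors = FALSE)
}
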