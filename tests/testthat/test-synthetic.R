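test_that("default transect matches the stated study geometry", {
  truth <- make_transect(sim_config(seed = 1))
  expect_equal(nrow(truth$sites), 65L)
  expect_equal(nrow(truth$samples), 195L)  # triplicate at 65 sites
  expect_false(is.unsorted(as.numeric(truth$sites$timestamp)))
  # adjacent sites sit one spacing apart on the sphere (0.1% tolerance)
  d <- haversine_km(truth$sites$lat[-65], truth$sites$lon[-65],
                    truth$sites$lat[-1], truth$sites$lon[-1])
  expect_equal(d, rep(46, 64), tolerance = 1e-3)
  # doubled spacing doubles the adjacent-site distance
  t2 <- make_transect(sim_config(seed = 1, site_spacing_km = 92, n_sites = 10))
  d2 <- haversine_km(t2$sites$lat[-10], t2$sites$lon[-10],
                     t2$sites$lat[-1], t2$sites$lon[-1])
  expect_equal(d2 / 92, rep(1, 9), tolerance = 1e-3)
  # degenerate single-site transect works
  t1 <- make_transect(sim_config(seed = 1, n_sites = 1))
  expect_equal(nrow(t1$sites), 1L)
  expect_equal(nrow(t1$samples), 3L)
})

test_that("true copies equal true cells times copy number exactly", {
  truth <- make_transect(small_sim(seed = 2, n_sites = 5))
  cpc <- vapply(truth$taxa, `[[`, numeric(1), "copies_per_cell")
  expect_identical(truth$copies, sweep(truth$cells, 2, cpc, `*`))
})

test_that("background calibration hits the target spike fraction in expectation", {
  cfg <- sim_config(seed = 3)
  truth <- make_transect(cfg)
  C_total <- sum(vapply(truth$standards, `[[`, numeric(1), "copies_added"))
  comm <- sum(colMeans(truth$copies)) * cfg$volume_L
  expect_equal(C_total / (C_total + comm), cfg$target_spike_fraction,
               tolerance = 1e-9)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_sim(seed = 17, n_sites = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # and a different seed changes the reads
  t3 <- simulate_reads(make_transect(small_sim(seed = 18, n_sites = 6)))
  t1 <- simulate_reads(make_transect(small_sim(seed = 17, n_sites = 6)))
  expect_false(identical(t1$counts$counts, t3$counts$counts))
})

test_that("noise knobs isolate their noise sources", {
  cfg <- small_sim(seed = 5, n_sites = 4, replicate_noise_sigma = 0,
                   depth_sdlog = 0)
  sim <- simulate_reads(make_transect(cfg))
  expect_true(all(sim$capture == 1))
  expect_true(all(colSums(sim$counts$counts) == cfg$reads_per_sample))

  # fcm_noise_sigma = 0: triplicates identical and equal to interpolated truth
  truth <- make_transect(small_sim(seed = 5, n_sites = 4, fcm_noise_sigma = 0))
  fcm <- simulate_fcm(truth)
  for (i in seq_len(nrow(fcm))) {
    v <- fcm$replicate_counts[[i]]
    expect_equal(v, rep(v[1], 3))
    expect_equal(v[1], true_cells_at(truth, fcm$population[i], fcm$lat[i]))
  }
  # the first event is colocated with the first site: values match the site truth
  f1 <- fcm[fcm$event_id == "F001" & fcm$population == "Prochlorococcus", ]
  expect_equal(f1$mean, truth$cells[1, "Prochlorococcus"])
})

test_that("default cadence over the ~9-day transect gives ~27 FCM events", {
  truth <- make_transect(sim_config(seed = 6))
  fcm <- simulate_fcm(truth)
  n_events <- length(unique(fcm$event_id))
  expect_true(n_events >= 26 && n_events <= 28)
  expect_equal(unique(fcm$n), 3L)  # triplicate
})

test_that("amplification bias inflates the biased taxon ~k-fold, others unchanged", {
  base_cfg <- small_sim(seed = 8, n_sites = 6, replicate_noise_sigma = 0,
                        depth_sdlog = 0, volume_jitter = 0,
                        reads_per_sample = 5e5)
  bias_cfg <- small_sim(seed = 8, n_sites = 6, replicate_noise_sigma = 0,
                        depth_sdlog = 0, volume_jitter = 0,
                        reads_per_sample = 5e5,
                        amplification_bias = c(Prochlorococcus = 2))
  run <- function(cfg) {
    truth <- make_transect(cfg)
    sim <- simulate_reads(truth)
    am <- build_abundance_matrix(sim$counts, sim$metadata, sim$standards)
    asn <- assign_taxa(sim$taxonomy,
                       stats::setNames(names(sim$copy_map), names(sim$copy_map)))
    taxon_abundances(am, asn, sim$copy_map)$summary
  }
  s0 <- run(base_cfg); s2 <- run(bias_cfg)
  pro0 <- s0$mean[s0$taxon == "Prochlorococcus"]
  pro2 <- s2$mean[s2$taxon == "Prochlorococcus"]
  # the estimate is a ratio of read counts, so the multinomial normalization
  # cancels: doubling a taxon's efficiency doubles its recovered abundance
  expect_equal(mean(pro2 / pro0), 2, tolerance = 0.1)
  syn0 <- s0$mean[s0$taxon == "Synechococcus"]
  syn2 <- s2$mean[s2$taxon == "Synechococcus"]
  expect_equal(mean(syn2 / syn0), 1, tolerance = 0.1)
})

test_that("written simulation files read back into equivalent objects", {
  cfg <- small_sim(seed = 10, n_sites = 4)
  dir <- withr::local_tempdir()
  ws <- write_simulation(cfg, dir)
  ct <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(ct$counts, ws$sim$counts$counts)
  md <- read_metadata(file.path(dir, "meta.csv"))
  expect_equal(md$volume_L, ws$sim$metadata$volume_L, tolerance = 1e-11)
  expect_equal(md$timestamp, ws$sim$metadata$timestamp)
  stds <- read_standards(file.path(dir, "standards.json"))
  expect_equal(vapply(stds, `[[`, numeric(1), "copies_added"),
               vapply(ws$sim$standards, `[[`, numeric(1), "copies_added"))
  fcm <- read_fcm(file.path(dir, "fcm.csv"))
  expect_equal(fcm$mean, ws$fcm$mean, tolerance = 1e-11)
  expect_equal(read_copy_map(file.path(dir, "copymap.json")), ws$sim$copy_map)
  tx <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tx, ws$sim$taxonomy)
})
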