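test_that("standard_reads sums all ASVs of a standard, absent ids count 0", {
  m <- rbind(s_a = c(40, 1), s_b = c(10, 2), comm = c(5, 5))
  colnames(m) <- c("j1", "j2")
  ct <- count_table(m)
  split_std <- std_with_copies("split", 1e6, c("s_a", "s_b"))
  expect_equal(standard_reads(ct, split_std, "j1"), 50)
  ghost <- std_with_copies("ghost", 1e6, "nope")
  expect_equal(standard_reads(ct, ghost, "j1"), 0)
  expect_error(standard_reads(ct, ghost, "zzz"), "not in count table")
})

test_that("volumetric_estimate implements R_ij*C_s/(R_sj*V_j)", {
  expect_identical(volumetric_estimate(100, 1e6, 50, 2), 1e6)
  expect_identical(volumetric_estimate(0, 1e6, 50, 2), 0)
  # frozen spreadsheet oracle: 37 * 4941243.70051282 / (121 * 1.8)
  expect_equal(volumetric_estimate(37, standard_copy_load(4, 3.0e6, 4), 121, 1.8),
               839421.565284547, tolerance = 1e-12)
  expect_true(is.na(volumetric_estimate(10, 1e6, 0, 2)))  # standard dropout
  expect_error(volumetric_estimate(10, 0, 5, 2), "C_s")
  expect_error(volumetric_estimate(10, 1e6, 5, 0), "V_j")
})

test_that("a clean 3x3 site yields nine estimates per ASV", {
  am <- build_abundance_matrix(clean_site_counts(), clean_site_meta(),
                               clean_site_standards())
  expect_true(all(am$summary$n == 9L))
  expect_equal(nrow(am$summary), 2L)  # two community ASVs
  expect_equal(sort(unique(am$estimates$standard)), c("stdA", "stdB", "stdC"))
  # mean within [min, max], all estimates finite and >= 0
  expect_true(all(am$summary$min <= am$summary$mean + 1e-12))
  expect_true(all(am$summary$mean <= am$summary$max + 1e-12))
  expect_true(all(is.finite(am$estimates$value) & am$estimates$value >= 0))
})

test_that("one standard dropout drops exactly one estimate for every ASV", {
  std0 <- matrix(c(50, 60, 55, 40, 45, 42, 30, 35, 0), nrow = 3, byrow = TRUE)
  am <- build_abundance_matrix(clean_site_counts(std0), clean_site_meta(),
                               clean_site_standards())
  expect_true(all(am$summary$n == 8L))
  expect_equal(nrow(am$dropouts), 1L)
  expect_equal(am$dropouts$standard, "stdC")
  expect_equal(am$dropouts$replicate, 3L)
})

test_that("identical replicates and standards collapse the range to a point", {
  m <- rbind(asv_a = c(100, 100, 100), std1 = c(50, 50, 50))
  colnames(m) <- c("X_r1", "X_r2", "X_r3")
  am <- build_abundance_matrix(count_table(m),
                               clean_site_meta(volume_L = c(2, 2, 2)),
                               list(std_with_copies("stdA", 1e6, "std1")))
  expect_equal(am$summary$min, am$summary$max)
  expect_equal(am$summary$mean, am$summary$min)
})

test_that("sites losing every estimate are excluded with a warning", {
  m <- rbind(asv_a = c(100, 100, 100, 90), std1 = c(0, 0, 0, 50))
  colnames(m) <- c("X_r1", "X_r2", "X_r3", "Y_r1")
  md <- mk_meta(colnames(m), c("X", "X", "X", "Y"), c(1:3, 1))
  expect_warning(
    am <- build_abundance_matrix(count_table(m), md,
                                 list(std_with_copies("stdA", 1e6, "std1"))),
    "site\\(s\\) excluded.*X")
  expect_equal(am$excluded_sites, "X")
  expect_equal(unique(am$summary$site_id), "Y")
})

test_that("missing metadata for a counted sample is a named hard error", {
  md <- clean_site_meta()[1:2, ]
  expect_error(build_abundance_matrix(clean_site_counts(), md,
                                      clean_site_standards()),
               "no metadata for sample\\(s\\): X_r3")
})

test_that("all-zero-everywhere ASVs are excluded, zero-at-one-site retained", {
  m <- rbind(asv_a = c(0, 0, 5), asv_zero = c(0, 0, 0), std1 = c(10, 10, 10))
  colnames(m) <- c("X_r1", "X_r2", "Y_r1")
  md <- mk_meta(colnames(m), c("X", "X", "Y"), c(1, 2, 1))
  am <- build_abundance_matrix(count_table(m), md,
                               list(std_with_copies("stdA", 1e6, "std1")))
  expect_false("asv_zero" %in% am$summary$asv_id)
  x_row <- am$summary[am$summary$site_id == "X" & am$summary$asv_id == "asv_a", ]
  expect_equal(x_row$mean, 0)
  expect_equal(x_row$n, 2L)
})

test_that("scale and volume equivariances hold to 1e-9 relative", {
  set.seed(42)
  stds <- clean_site_standards()
  for (i in 1:5) {
    comm <- matrix(rpois(6, 80), nrow = 2,
                   dimnames = list(c("asv_a", "asv_b"), c("X_r1", "X_r2", "X_r3")))
    stdm <- matrix(rpois(9, 40) + 1L, nrow = 3,
                   dimnames = list(c("std1", "std2", "std3"), colnames(comm)))
    vol <- runif(3, 1, 3)
    md <- mk_meta(colnames(comm), "X", 1:3, vol)
    base <- build_abundance_matrix(count_table(rbind(comm, stdm)), md, stds)
    k <- sample(2:7, 1)
    # scaling ALL reads by k leaves every estimate unchanged
    allk <- build_abundance_matrix(count_table(rbind(comm, stdm) * k), md, stds)
    expect_equal(allk$summary$mean, base$summary$mean, tolerance = 1e-9)
    expect_equal(allk$estimates$value, base$estimates$value, tolerance = 1e-9)
    # scaling only community reads multiplies estimates by k
    commk <- build_abundance_matrix(count_table(rbind(comm * k, stdm)), md, stds)
    expect_equal(commk$summary$mean, base$summary$mean * k, tolerance = 1e-9)
    # doubling volumes halves every estimate
    md2 <- mk_meta(colnames(comm), "X", 1:3, 2 * vol)
    half <- build_abundance_matrix(count_table(rbind(comm, stdm)), md2, stds)
    expect_equal(half$summary$mean, base$summary$mean / 2, tolerance = 1e-9)
  }
})

test_that("build_abundance_matrix equals a nested-loop brute force, bit-exactly", {
  # 2 sites x 4 ASVs x 2 standards, 2 replicates per site
  set.seed(7)
  samples <- c("A_r1", "A_r2", "B_r1", "B_r2")
  comm <- matrix(rpois(16, 60), nrow = 4,
                 dimnames = list(paste0("asv", 1:4), samples))
  stdm <- matrix(rpois(8, 30) + 1L, nrow = 2,
                 dimnames = list(c("std1", "std2"), samples))
  vols <- c(2, 1.8, 2.2, 2.05)
  md <- mk_meta(samples, c("A", "A", "B", "B"), c(1, 2, 1, 2), vols)
  stds <- list(std_with_copies("stdA", 1.3e6, "std1"),
               std_with_copies("stdB", 7.7e5, "std2"))
  am <- build_abundance_matrix(count_table(rbind(comm, stdm)), md, stds)

  for (site in c("A", "B")) {
    for (a in rownames(comm)) {
      vals <- c()
      for (r in 1:2) {
        j <- sprintf("%s_r%d", site, r)
        vj <- vols[match(j, samples)]
        for (s in 1:2) {
          R_sj <- stdm[s, j]
          vals <- c(vals, (comm[a, j] * stds[[s]]$copies_added) / (R_sj * vj))
        }
      }
      row <- am$summary[am$summary$site_id == site & am$summary$asv_id == a, ]
      expect_identical(row$mean, mean(vals))
      expect_identical(row$min, min(vals))
      expect_identical(row$max, max(vals))
      expect_identical(row$n, length(vals))
      got <- am$estimates[am$estimates$site_id == site &
                            am$estimates$asv_id == a, ]
      got <- got[order(got$replicate, got$standard), ]
      expect_identical(got$value, vals)
    }
  }
})

test_that("percent_error_summary matches hand computation", {
  # craft estimates 90,100,110: R_ij = 9,10,11; R_sj = 100; C_s = 1e6; V = 1
  m <- rbind(asv_a = c(9, 10, 11), std1 = c(100, 100, 100))
  colnames(m) <- c("X_r1", "X_r2", "X_r3")
  am <- build_abundance_matrix(count_table(m),
                               clean_site_meta(volume_L = c(1, 1, 1)),
                               list(std_with_copies("stdA", 1e6, "std1")))
  es <- percent_error_summary(am)
  expect_equal(sort(es$percent_errors), c(0, 10, 10), tolerance = 1e-9)
  expect_equal(es$value, 10, tolerance = 1e-9)

  # zero-spread estimates give p95 = 0
  m2 <- rbind(asv_a = c(10, 10, 10), std1 = c(100, 100, 100))
  colnames(m2) <- colnames(m)
  am2 <- build_abundance_matrix(count_table(m2),
                                clean_site_meta(volume_L = c(1, 1, 1)),
                                list(std_with_copies("stdA", 1e6, "std1")))
  expect_equal(percent_error_summary(am2)$value, 0)

  # zero-mean sets are skipped; an empty pool is a hard error
  expect_error(percent_error_summary(am, subset = "no_such_asv"),
               "no estimates to summarize")
})

test_that("mean estimates converge to truth as depth grows (noise-free draws)", {
  for (seed in 1:3) {
    cfg <- small_sim(seed = seed, n_sites = 6, replicate_noise_sigma = 0,
                     depth_sdlog = 0, reads_per_sample = 1e6,
                     volume_jitter = 0)
    truth <- make_transect(cfg)
    sim <- simulate_reads(truth)
    am <- build_abundance_matrix(sim$counts, sim$metadata, sim$standards)
    all_tax <- vapply(truth$taxa, `[[`, character(1), "name")
    asn <- assign_taxa(sim$taxonomy, stats::setNames(all_tax, all_tax))
    ta <- taxon_abundances(am, asn, sim$copy_map)
    tot <- sum(colMeans(truth$copies))
    for (tax in c("Prochlorococcus", "Pelagibacter")) {
      if (mean(truth$copies[, tax]) / tot < 0.01) next
      got <- ta$summary[ta$summary$taxon == tax, ]
      # taxa without a known copy number are reported in copies/L
      want <- if (tax %in% names(sim$copy_map)) truth$cells[got$site_id, tax]
              else truth$copies[got$site_id, tax]
      expect_lt(max(abs(got$mean - want) / want), 0.02)
    }
  }
})
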