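test_that("assign_taxa does rank-aware substring matching with 'other' default", {
  tx <- c(a1 = "Bacteria;Cyanobacteria;Synechococcales;Prochlorococcus_MIT9313",
          a2 = "Bacteria;Proteobacteria;Pelagibacterales;Pelagibacter",
          a3 = "Bacteria;Cyanobacteria;Synechococcales;Synechococcus_CC9902")
  pat <- c(Prochlorococcus = "Prochlorococcus", Synechococcus = "Synechococcus")
  asn <- assign_taxa(tx, pat)
  expect_equal(unname(asn), c("Prochlorococcus", "other", "Synechococcus"))
  expect_error(
    assign_taxa(tx, c(Synechococcus = "Synechococcus", Syn2 = "Synecho")),
    "ambiguous taxon assignment for ASV 'a3'")
})

test_that("cells_from_copies divides by copy number and validates", {
  expect_equal(cells_from_copies(2e8, 2), 1e8)
  expect_identical(cells_from_copies(5, 1), 5)
  expect_identical(cells_from_copies(0, 3), 0)
  expect_error(cells_from_copies(10, 0.5), ">= 1")
  # round trip: converting back by multiplying is the identity
  set.seed(3)
  x <- runif(50, 0, 1e9); k <- sample(1:8, 50, replace = TRUE)
  expect_equal(cells_from_copies(x, k) * k, x, tolerance = 1e-12)
})

test_that("member-ASV estimates sum per slot; copy number divides exactly", {
  # two Pro ASVs + one Syn ASV at one site
  m <- rbind(pro1 = c(60, 70, 65), pro2 = c(30, 20, 25),
             syn1 = c(10, 12, 14), std1 = c(50, 55, 45))
  colnames(m) <- c("X_r1", "X_r2", "X_r3")
  am <- build_abundance_matrix(count_table(m), clean_site_meta(),
                               list(std_with_copies("stdA", 1e6, "std1")))
  asn <- c(pro1 = "Prochlorococcus", pro2 = "Prochlorococcus",
           syn1 = "Synechococcus")
  ta <- taxon_abundances(am, asn)

  est <- am$estimates
  slot_sum <- function(asvs, r) sum(est$value[est$asv_id %in% asvs &
                                                est$replicate == r])
  pro <- ta$estimates[ta$estimates$taxon == "Prochlorococcus", ]
  pro <- pro[order(pro$replicate), ]
  for (r in 1:3)
    expect_equal(pro$value[pro$replicate == r], slot_sum(c("pro1", "pro2"), r))
  # Synechococcus (2 copies/cell): taxon cell estimates are half the copy ones
  syn <- ta$estimates[ta$estimates$taxon == "Synechococcus", ]
  syn <- syn[order(syn$replicate), ]
  copy_rows <- est[est$asv_id == "syn1", ]
  copy_rows <- copy_rows[order(copy_rows$replicate), ]
  expect_identical(syn$value, copy_rows$value / 2)
  expect_equal(unique(syn$unit), "cells_per_L")
})

test_that("taxon aggregation matches a nested-loop oracle on a 3-site toy", {
  set.seed(21)
  samples <- paste0(rep(c("A", "B", "C"), each = 2), "_r", rep(1:2, 3))
  comm <- matrix(rpois(24, 50), nrow = 4,
                 dimnames = list(c("p1", "p2", "s1", "o1"), samples))
  stdm <- matrix(rpois(12, 30) + 1L, nrow = 2,
                 dimnames = list(c("std1", "std2"), samples))
  md <- mk_meta(samples, rep(c("A", "B", "C"), each = 2), rep(1:2, 3),
                runif(6, 1.5, 2.5))
  stds <- list(std_with_copies("stdA", 1e6, "std1"),
               std_with_copies("stdB", 2e6, "std2"))
  am <- build_abundance_matrix(count_table(rbind(comm, stdm)), md, stds)
  asn <- c(p1 = "Prochlorococcus", p2 = "Prochlorococcus",
           s1 = "Synechococcus", o1 = "other")
  cpc <- c(Prochlorococcus = 1, Synechococcus = 2)
  ta <- taxon_abundances(am, asn, cpc)

  est <- am$estimates
  for (site in c("A", "B", "C")) {
    for (tax in c("Prochlorococcus", "Synechococcus", "other")) {
      members <- names(asn)[asn == tax]
      vals <- c()
      for (r in 1:2) for (sd in c("stdA", "stdB")) {
        v <- est$value[est$site_id == site & est$asv_id %in% members &
                         est$replicate == r & est$standard == sd]
        vals <- c(vals, sum(v) / (if (tax %in% names(cpc)) cpc[[tax]] else 1))
      }
      row <- ta$summary[ta$summary$site_id == site & ta$summary$taxon == tax, ]
      expect_equal(row$mean, mean(vals), tolerance = 1e-12)
      expect_equal(row$min, min(vals), tolerance = 1e-12)
      expect_equal(row$max, max(vals), tolerance = 1e-12)
    }
  }

  # conservation under partition: taxon copy means sum to ASV copy means
  k <- c(Prochlorococcus = 1, Synechococcus = 2, other = 1)
  for (site in c("A", "B", "C")) {
    tt <- ta$summary[ta$summary$site_id == site, ]
    lhs <- sum(tt$mean * k[tt$taxon])
    rhs <- sum(am$summary$mean[am$summary$site_id == site])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }

  # invariance to ASV ordering within the taxon
  perm <- c("o1", "s1", "p2", "p1", "std2", "std1")
  am2 <- build_abundance_matrix(count_table(rbind(comm, stdm)[perm, ]), md, stds)
  ta2 <- taxon_abundances(am2, asn, cpc)
  expect_equal(ta2$summary[order(ta2$summary$site_id, ta2$summary$taxon), "mean"],
               ta$summary[order(ta$summary$site_id, ta$summary$taxon), "mean"],
               tolerance = 1e-12)
})

test_that("a copy-map taxon with no member ASVs is emitted as zeros + warning", {
  m <- rbind(pro1 = c(10, 12, 9), std1 = c(50, 55, 45))
  colnames(m) <- c("X_r1", "X_r2", "X_r3")
  am <- build_abundance_matrix(count_table(m), clean_site_meta(),
                               list(std_with_copies("stdA", 1e6, "std1")))
  expect_warning(
    ta <- taxon_abundances(am, c(pro1 = "Prochlorococcus"),
                           c(Prochlorococcus = 1, Synechococcus = 2)),
    "no member ASVs: Synechococcus")
  syn <- ta$summary[ta$summary$taxon == "Synechococcus", ]
  expect_equal(syn$mean, 0)
  expect_equal(syn$n, 3L)  # one standard x three replicates of retained slots
})

test_that("abundance_ratio is the ratio of site means, degenerate sites excluded", {
  s <- data.frame(site_id = c("A", "A", "B", "B"),
                  taxon = rep(c("Prochlorococcus", "Synechococcus"), 2),
                  unit = "cells_per_L",
                  mean = c(2e8, 1e7, 5e6, 0),
                  min = 0, max = 3e8, n = 9L, stringsAsFactors = FALSE)
  ta <- structure(list(summary = s, estimates = NULL), class = "taxon_abundance")
  r <- abundance_ratio(ta)
  expect_equal(r$ratio[r$site_id == "A"], 20)
  expect_true(is.na(r$ratio[r$site_id == "B"]))
  expect_equal(attr(r, "excluded"), "B")
  expect_error(abundance_ratio(ta, "Prochlorococcus", "Nope"), "no sites carry")
})
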