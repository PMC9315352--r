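test_that("panel simulation honours composition, invariants and seeds", {
  panel <- simulate_panel(c(EUW = 19, EUD = 25, BLW = 4, NEW = 3),
                          n_sites = 300, fst = 0.15, seed = 7)
  expect_equal(nrow(panel$haplotypes), 102) # 51 diploid donors
  expect_equal(length(panel$group_labels), 102)
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(panel$sites$pos) > 0))
  # frequency conservation: group_freqs are exact per-group column means
  for (g in rownames(panel$group_freqs)) {
    expect_equal(panel$group_freqs[g, ],
                 colMeans(panel$haplotypes[panel$group_labels == g, ,
                                           drop = FALSE]),
                 tolerance = 1e-12)
  }
  # seed reproducibility, bit-identical
  again <- simulate_panel(c(EUW = 19, EUD = 25, BLW = 4, NEW = 3),
                          n_sites = 300, fst = 0.15, seed = 7)
  expect_identical(panel, again)
  expect_error(simulate_panel(c(A = 0), 100, 0.1), "empty panel")
  expect_error(simulate_panel(c(A = 2), 100, fst = 1.2), "fst")
  expect_error(simulate_panel(c(A = 2), 100, fst = 0), "fst")
})

test_that("group differentiation tracks the drift parameter", {
  # no-drift limit: the model (Beta-drawn) group frequencies converge
  tiny <- simulate_panel(c(A = 30, B = 30), n_sites = 2000, fst = 1e-6,
                         seed = 21)
  mf <- attr(tiny, "model_freqs")
  expect_lt(mean(abs(mf["A", ] - mf["B", ])), 0.005)
  # Hudson-estimator FST recovers the nominal value (independent oracle)
  panel <- simulate_panel(c(A = 50, B = 50), n_sites = 20000, fst = 0.2,
                          seed = 11)
  expect_lt(abs(hudson_fst(panel$haplotypes, panel$group_labels) - 0.2),
            0.03)
})

test_that("admixed targets are frequency-conditional ancestry mosaics", {
  panel <- simulate_panel(c(A = 5, B = 5), n_sites = 500, fst = 0.2,
                          seed = 31)
  # degenerate mixture: one group everywhere
  pure <- simulate_admixed_target(panel, c(A = 1.0), seed = 32)
  expect_true(all(pure$local_ancestry == "A"))
  # no-switch limit: exactly one ancestry segment per haploid copy
  ns <- simulate_admixed_target(panel, c(A = 0.5, B = 0.5),
                                switch_rate_per_cm = 0, seed = 33)
  expect_equal(length(unique(ns$local_ancestry[1, ])), 1L)
  expect_equal(length(unique(ns$local_ancestry[2, ])), 1L)
  # genotype = haploid allele sum is structural
  expect_true(all(pure$true_genotypes %in% 0:2))
  expect_error(simulate_admixed_target(panel, c(A = 0.5, Z = 0.5)),
               "unknown group")
  expect_error(simulate_admixed_target(panel, c(A = 0.6, B = 0.6)),
               "sum to 1")
  # determinism
  expect_identical(simulate_admixed_target(panel, c(A = .3, B = .7),
                                           seed = 5),
                   simulate_admixed_target(panel, c(A = .3, B = .7),
                                           seed = 5))
})

test_that("realized ancestry fractions recover the mixture proportions", {
  # a 46/54 mixture over 50 cM with ~1 switch/cM lands near its target
  panel <- simulate_panel(c(EU = 5, NE = 5), n_sites = 10000, fst = 0.2,
                          seed = 41, chrom_length = 50e6)
  tg <- simulate_admixed_target(panel, c(EU = 0.46, NE = 0.54),
                                switch_rate_per_cm = 1, seed = 42)
  ne_frac <- mean(tg$local_ancestry == "NE")
  expect_lt(abs(ne_frac - 0.54), 0.1)
  # tighter recovery with dense switching over many sites
  big <- simulate_panel(c(A = 3, B = 3), n_sites = 1e5, fst = 0.2,
                        seed = 43)
  mix <- simulate_admixed_target(big, c(A = 0.3, B = 0.7),
                                 switch_rate_per_cm = 50, seed = 44)
  expect_lt(abs(mean(mix$local_ancestry == "B") - 0.7), 0.02)
})

test_that("read simulation has Poisson depth, honest noise and determinism", {
  panel <- simulate_panel(c(A = 5), n_sites = 20000, fst = 0.2, seed = 51)
  tg <- simulate_admixed_target(panel, c(A = 1.0), seed = 52)
  # noise-free deep reads match truth exactly at hom sites
  clean <- simulate_reads(tg, coverage = 30, base_error = 1e-9,
                          deam_rate = 0, seed = 53)
  cnt <- tabulate(clean$pileups$site[clean$pileups$allele == 1L], 20000)
  tot <- tabulate(clean$pileups$site, 20000)
  hom0 <- tg$true_genotypes == 0L & tot > 0
  hom2 <- tg$true_genotypes == 2L & tot > 0
  expect_true(all(cnt[hom0] == 0))
  expect_true(all(cnt[hom2] == tot[hom2]))
  het <- tg$true_genotypes == 1L & tot >= 20
  expect_equal(mean(cnt[het] / tot[het]), 0.5, tolerance = 0.02)
  # Poisson zero-class at coverage 1
  lam1 <- simulate_reads(tg, coverage = 1, seed = 54)
  expect_lt(abs(mean(tabulate(lam1$pileups$site, 20000) == 0) - exp(-1)),
            0.01)
  # coverage 0 is valid and empty
  z <- simulate_reads(tg, coverage = 0, seed = 55)
  expect_equal(nrow(z$pileups), 0L)
  # determinism
  expect_identical(simulate_reads(tg, 1, seed = 56),
                   simulate_reads(tg, 1, seed = 56))
})

test_that("deamination converts the damaged strand at the nominal rate", {
  panel <- simulate_panel(c(A = 2), n_sites = 4000, fst = 0.2, seed = 61,
                          damage_frac = 1)
  tg <- simulate_admixed_target(panel, c(A = 1.0), seed = 62)
  ct <- which(panel$sites$ref %in% c("C", "T") &
              panel$sites$alt %in% c("C", "T"))
  # force hom-C truth at every C/T site so any T read is damage or error
  tg$true_genotypes[ct] <- ifelse(panel$sites$ref[ct] == "C", 0L, 2L)
  tg <- simulate_reads(tg, coverage = 10, base_error = 1e-9,
                       deam_rate = 0.2, seed = 63)
  pu <- tg$pileups[tg$pileups$site %in% ct, ]
  is_t <- ifelse(panel$sites$ref[pu$site] == "C", pu$allele == 1L,
                 pu$allele == 0L)
  expect_lt(abs(mean(is_t[pu$strand == "+"]) - 0.2), 0.02)
  expect_lt(mean(is_t[pu$strand == "-"]), 0.001) # minus strand untouched
})

test_that("damage asymmetry: non-damage-prone allele pairs are unaffected", {
  panel <- simulate_panel(c(A = 2), n_sites = 6000, fst = 0.2, seed = 71,
                          damage_frac = 0.5)
  tg <- simulate_admixed_target(panel, c(A = 1.0), seed = 72)
  dam <- simulate_reads(tg, coverage = 5, base_error = 1e-9,
                        deam_rate = 0.3, seed = 73)
  und <- simulate_reads(tg, coverage = 5, base_error = 1e-9,
                        deam_rate = 0, seed = 73)
  pair <- paste(pmin(panel$sites$ref, panel$sites$alt),
                pmax(panel$sites$ref, panel$sites$alt))
  prone <- pair %in% c("C T", "A G")
  # same seed, same reads: alleles may only differ at damage-prone sites
  changed <- dam$pileups$allele != und$pileups$allele
  expect_gt(sum(changed), 0)
  expect_true(all(prone[dam$pileups$site[changed]]))
})

test_that("downsampling hits the grid coverages and is deterministic", {
  panel <- simulate_panel(c(A = 4), n_sites = 10000, fst = 0.2, seed = 81)
  tg <- simulate_admixed_target(panel, c(A = 1.0), seed = 82)
  tg <- simulate_reads(tg, coverage = 2, seed = 83)
  for (cov in c(0.5, 1, 1.5, 2)) {
    d <- downsample_pileups(tg, target_coverage = cov, seed = 84)
    expect_equal(attr(d, "realized_coverage"), cov, tolerance = 0.05 * cov)
  }
  # identity at factor 1
  expect_identical(downsample_pileups(tg, factor = 1), tg)
  # determinism
  expect_identical(downsample_pileups(tg, factor = 0.5, seed = 85),
                   downsample_pileups(tg, factor = 0.5, seed = 85))
  expect_error(downsample_pileups(tg, target_coverage = 3),
               "above current")
})
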