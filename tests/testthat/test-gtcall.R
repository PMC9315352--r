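# helper: minimal site_calls frame from explicit parts
mk_calls <- function(ref, alt, ll, gt = NULL, pos = NULL) {
  n <- length(ref)
  if (is.null(pos)) pos <- seq_len(n) * 100
  calls <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      depth = 10L, ll_rr = ll[, 1], ll_ra = ll[, 2],
                      ll_aa = ll[, 3], gt = NA_integer_, gq = 100,
                      filter = "PASS", stringsAsFactors = FALSE)
  if (!is.null(gt)) calls$gt <- gt
  class(calls) <- c("site_calls", "data.frame")
  calls
}

test_that("genotype likelihoods follow the symmetric read-error model", {
  e <- 0.01
  ll <- genotype_likelihoods(10, 0, base_error = e)
  expect_equal(which.max(ll), 1L) # hom-ref argmax
  expect_equal(ll[1] - ll[3], 10 * (log(1 - e) - log(e)), tolerance = 1e-12)
  balanced <- genotype_likelihoods(5, 5, base_error = e)
  expect_equal(which.max(balanced), 2L) # het beats both homs
  expect_equal(balanced[2], 10 * log(0.5), tolerance = 1e-12)
  # empty pileup: all genotypes equally likely
  flat <- genotype_likelihoods(0, 0, base_error = e)
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_error(genotype_likelihoods(1, 1, base_error = 0.7), "0.5")
})

test_that("quality thresholds gate calls and set the flag vocabulary", {
  panel <- simulate_panel(c(A = 4), n_sites = 500, fst = 0.2, seed = 1)
  tg <- simulate_admixed_target(panel, c(A = 1.0), seed = 2)
  tg <- simulate_reads(tg, coverage = 30, base_error = 1e-4, deam_rate = 0,
                       seed = 3)
  calls <- call_genotypes(call_target(tg, base_error = 1e-4))
  expect_true(all(calls$filter %in% c("PASS", "LOWQUAL")))
  pass <- calls$filter == "PASS"
  expect_gt(mean(pass), 0.9)
  # deep noise-free calls equal truth
  expect_equal(calls$gt[pass], tg$true_genotypes[pass])
  # zero-depth sites are missing
  expect_true(all(is.na(calls$gt[calls$depth == 0L])))
  # threshold boundary: quality just under the filter bound is LOWQUAL
  one <- calls[which(pass)[1], ]
  one$gq <- 29.5
  gated <- call_genotypes(one, filter_quality = 30)
  expect_equal(gated$filter, "LOWQUAL")
  expect_true(is.na(gated$gt))
  # counted on a constructed fixture: exactly the low-quality sites flagged
  calls2 <- calls
  idx <- seq_len(12)
  calls2$gq[idx] <- 10
  gated2 <- call_genotypes(calls2, filter_quality = 30)
  expect_equal(sum(gated2$filter == "LOWQUAL" & calls2$depth > 0),
               sum(gated2$gq < 30 & calls2$depth > 0))
  expect_true(all(gated2$filter[idx] == "LOWQUAL"))
})

test_that("deamination filter removes exactly the damage-explicable cells", {
  # exhaustive fixture: all 6 biallelic pairs x all 3 genotypes
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"), c("C", "G"),
                c("C", "T"), c("G", "T"))
  grid <- expand.grid(pair = seq_along(pairs), gt = 0:2)
  ref <- vapply(pairs[grid$pair], `[`, "", 1)
  alt <- vapply(pairs[grid$pair], `[`, "", 2)
  ll <- matrix(-10, nrow(grid), 3)
  ll[cbind(seq_len(nrow(grid)), grid$gt + 1)] <- 0 # argmax = assigned gt
  calls <- mk_calls(ref, alt, ll, gt = grid$gt)
  res <- deamination_filter(calls, mode = "drop")
  # expected removals: {C,T} genotypes containing T, {G,A} containing A
  has_t <- (ref == "C" & alt == "T" & grid$gt >= 1) |
           (ref == "T" & alt == "C" & grid$gt <= 1)
  has_a <- (ref == "A" & alt == "G" & grid$gt <= 1) |
           (ref == "G" & alt == "A" & grid$gt >= 1)
  prone <- paste(pmin(ref, alt), pmax(ref, alt)) %in% c("C T", "A G")
  expected <- prone & (has_t | has_a)
  expect_equal(nrow(res$removed), sum(expected))
  expect_equal(sort(res$removed$pos), sort(calls$pos[expected]))
  # no other allele pair is ever touched
  expect_true(all(paste(pmin(res$removed$ref, res$removed$alt),
                        pmax(res$removed$ref, res$removed$alt))
                  %in% c("C T", "A G")))
})

test_that("deamination filter masks instead of dropping when asked", {
  calls <- mk_calls(c("C", "C"), c("T", "T"),
                    rbind(c(0, -9, -9), c(-9, -9, 0)), gt = c(0L, 2L))
  masked <- deamination_filter(calls, mode = "mask")
  expect_equal(nrow(masked$calls), 2L) # rows kept
  expect_true(is.na(masked$calls$gt[2])) # T/T masked to no-call
  expect_equal(masked$calls$filter[2], "DEAMINATION")
  expect_equal(masked$calls$gt[1], 0L) # C/C untouched
})

test_that("likelihood ties are treated as damaged (conservative removal)", {
  # equal top likelihood between C/C and C/T at a C/T SNP
  calls <- mk_calls("C", "T", rbind(c(0, 0, -9)), gt = 0L)
  expect_equal(nrow(deamination_filter(calls)$removed), 1L)
})

test_that("deamination filter is idempotent", {
  panel <- simulate_panel(c(A = 4), n_sites = 400, fst = 0.2, seed = 9)
  tg <- simulate_reads(simulate_admixed_target(panel, c(A = 1), seed = 10),
                       coverage = 5, deam_rate = 0.2, seed = 11)
  calls <- call_genotypes(call_target(tg))
  once <- deamination_filter(calls)$calls
  twice <- deamination_filter(once)$calls
  expect_identical(once, twice)
})

test_that("panel QC applies depth masking, call rate, quality and repeats", {
  set.seed(5)
  n_don <- 51; n_site <- 40
  gt <- matrix(sample(0:2, n_don * n_site, TRUE), n_don, n_site)
  depth <- matrix(10, n_don, n_site)
  qual <- rep(50, n_site)
  sites <- data.frame(chrom = "1", pos = seq_len(n_site) * 1000,
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  # site 1: 40/51 donors called (0.784 < 0.8) -> removed
  depth[41:51, 1] <- 0
  # site 2: one depth-3 genotype masked, call rate 50/51 -> kept
  depth[1, 2] <- 3
  # site 3: quality below 30 -> removed
  qual[3] <- 25
  # site 4: inside the repeat mask -> removed
  mask <- data.frame(chrom = "1", start = 3500, end = 4100)
  qc <- panel_qc(gt, sites, qual, depth, repeat_mask = mask)
  expect_false(qc$keep[1])
  expect_true(qc$keep[2])
  expect_true(is.na(qc$genotypes[1, match(2, which(qc$keep))]))
  expect_false(qc$keep[3])
  expect_false(qc$keep[4])
  expect_true(all(qc$keep[5:40]))
  # empty repeat mask changes nothing positionally
  qc2 <- panel_qc(gt, sites, qual, depth, repeat_mask = NULL)
  expect_true(qc2$keep[4])
  # QC is idempotent on its own output
  qc3 <- panel_qc(qc$genotypes, qc$sites, qual[qc$keep], NULL,
                  repeat_mask = mask)
  expect_true(all(qc3$keep))
  expect_error(panel_qc(gt, sites, rep(0, n_site), depth), "no sites")
})

test_that("MAF bins overlap by design and partition where they must", {
  expect_equal(maf_bin_labels(),
               c("<0.05", "0.05-0.1", "0.1-0.3", ">0.05", ">0.3", "No MAF"))
  m <- assign_maf_bins(c(0.04, 0.07, 0.5))
  expect_equal(colnames(m)[m[1, ]], c("<0.05", "No MAF"))
  expect_equal(colnames(m)[m[2, ]], c("0.05-0.1", ">0.05", "No MAF"))
  expect_equal(colnames(m)[m[3, ]], c(">0.05", ">0.3", "No MAF"))
  # partition consistency over random frequencies
  set.seed(3)
  m2 <- assign_maf_bins(runif(500, 0, 0.5))
  expect_true(all(m2[, "No MAF"]))
  narrow <- m2[, c("<0.05", "0.05-0.1", "0.1-0.3", ">0.3")]
  expect_true(all(rowSums(narrow) == 1))
})

test_that("the three target-site constructions nest as designed", {
  panel <- simulate_panel(c(A = 6), n_sites = 600, fst = 0.2, seed = 13)
  tg <- simulate_reads(simulate_admixed_target(panel, c(A = 1), seed = 14),
                       coverage = 1, seed = 15)
  calls <- deamination_filter(call_genotypes(call_target(tg)))$calls
  m1 <- build_target_sites(1, calls, panel)
  m2 <- build_target_sites(2, calls, panel)
  m3 <- build_target_sites(3, calls, panel)
  # method 3 always spans exactly the panel's site set
  expect_equal(nrow(m3), nrow(panel$sites))
  # method 2 contains method 1 (set inclusion, checked by brute force)
  expect_true(all(m1$panel_idx %in% m2$panel_idx))
  # method 1 holds only non-reference calls
  expect_true(all(m1$gt > 0))
  expect_error(build_target_sites(4, calls, panel), "method")
  # empty variant set refuses downstream in the pipeline
  none <- calls[0, ]
  expect_equal(nrow(build_target_sites(1, none, panel)), 0L)
})
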