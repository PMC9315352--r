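mk_truth <- function(pos, gt, ref = "A", alt = "C") {
  calls <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      depth = 30L, ll_rr = 0, ll_ra = -9, ll_aa = -9,
                      gt = gt, gq = 99, filter = "PASS",
                      stringsAsFactors = FALSE)
  class(calls) <- c("site_calls", "data.frame")
  calls
}

mk_imp <- function(pos, gt, ref = "A", alt = "C") {
  res <- data.frame(chrom = rep("1", length(pos)), pos = pos,
                    ref = rep_len(ref, length(pos)),
                    alt = rep_len(alt, length(pos)),
                    gp_rr = as.numeric(gt == 0), gp_ra = as.numeric(gt == 1),
                    gp_aa = as.numeric(gt == 2), dosage = as.numeric(gt),
                    gt = gt, score = rep(1, length(pos)),
                    observed = rep(FALSE, length(pos)),
                    stringsAsFactors = FALSE)
  class(res) <- c("imputation_result", "data.frame")
  res
}

test_that("concordance classifies the two error classes and conserves counts", {
  truth <- mk_truth(pos = (1:9) * 100, gt = rep(c(0L, 1L, 2L), 3))
  # identity
  ident <- concordance(mk_imp((1:9) * 100, rep(c(0L, 1L, 2L), 3)), truth)
  expect_equal(ident$concordance, 1)
  expect_equal(ident$information_content, 1)
  # hand-counted fixture: 8 correct, 1 wrong genotype, 1 off-position
  imp <- mk_imp(c((1:9) * 100, 9999), c(rep(c(0L, 1L, 2L), 3), 1L))
  imp$gt[2] <- 2L # wrong genotype at a truth site
  rep <- concordance(imp, truth)
  expect_equal(rep$n_imputed, 10L)
  expect_equal(rep$n_correct, 8L)
  expect_equal(rep$n_incorrect_genotype, 1L)
  expect_equal(rep$n_incorrect_position, 1L)
  expect_equal(rep$concordance, 0.8)
  expect_equal(rep$n_correct + rep$n_incorrect_position +
                 rep$n_incorrect_genotype, rep$n_imputed)
  # information content is imputed over gold-standard count
  expect_equal(rep$information_content, 10 / 9)
  # zero imputed sites: flagged undefined
  none <- concordance(mk_imp(numeric(0), integer(0)), truth)
  expect_true(none$undefined)
  expect_true(is.na(none$concordance))
})

test_that("concordance is invariant to site order and VCF round-trip", {
  panel <- simulate_panel(c(A = 5), n_sites = 300, fst = 0.2, seed = 31)
  tg <- simulate_reads(simulate_admixed_target(panel, c(A = 1), seed = 32),
                       coverage = 1, seed = 33)
  cell <- run_pipeline(panel, tg, "one-step", 3)
  truth <- truth_calls(tg)
  base <- concordance(cell$imputed, truth)
  shuf <- cell$imputed[sample(nrow(cell$imputed)), ]
  expect_equal(concordance(shuf, truth)$concordance, base$concordance)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_result_vcf(cell$imputed, f)
  back <- read_result_vcf(f)
  expect_equal(concordance(back, truth)$concordance, base$concordance)
})

test_that("strata nest and sum back to the overall report", {
  panel <- simulate_panel(c(A = 6, B = 6), n_sites = 1000, fst = 0.2,
                          seed = 41)
  tg <- simulate_reads(simulate_admixed_target(panel, c(A = .5, B = .5),
                                               seed = 42),
                       coverage = 1, seed = 43)
  cell <- run_pipeline(panel, tg, "one-step", 3)
  truth <- truth_calls(tg)
  overall <- concordance(cell$imputed, truth)
  st <- stratified_concordance(cell$imputed, truth, panel)
  expect_named(st$maf, maf_bin_labels())
  # disjoint narrow bins sum to the totals
  narrow <- st$maf[c("<0.05", "0.05-0.1", "0.1-0.3", ">0.3")]
  expect_equal(sum(vapply(narrow, function(r) r$n_correct, numeric(1))),
               overall$n_correct)
  expect_equal(sum(vapply(narrow, function(r) r$n_imputed, numeric(1))),
               overall$n_imputed)
  # "No MAF" is the whole set
  expect_equal(st$maf[["No MAF"]]$n_imputed, overall$n_imputed)
  # het stratum conditions on the gold standard being heterozygous
  expect_lte(st$het$n_hq, overall$n_hq)
  # all-het fixture: het-only equals overall
  truth_h <- truth[truth$gt == 1L, ]
  keep <- paste(cell$imputed$chrom, cell$imputed$pos) %in%
    paste(truth_h$chrom, truth_h$pos)
  imp_h <- cell$imputed[keep, ]
  st_h <- stratified_concordance(imp_h, truth_h, panel, strata = "het")
  expect_equal(st_h$het$n_imputed, concordance(imp_h, truth_h)$n_imputed)
  expect_equal(st_h$het$concordance, concordance(imp_h, truth_h)$concordance)
})

test_that("per-chromosome uniformity is the sd of chromosome concordances", {
  truth <- rbind(mk_truth((1:10) * 100, rep(0L, 10)),
                 mk_truth((1:10) * 100, rep(0L, 10)))
  truth$chrom <- rep(c("1", "2"), each = 10)
  imp <- rbind(mk_imp((1:10) * 100, c(rep(0L, 9), 1L)),
               mk_imp((1:10) * 100, rep(0L, 10)))
  imp$chrom <- rep(c("1", "2"), each = 10)
  st <- stratified_concordance(imp, truth, strata = "chrom")
  expect_equal(st$chrom$reports[["1"]]$concordance, 0.9)
  expect_equal(st$chrom$reports[["2"]]$concordance, 1.0)
  expect_equal(st$chrom$uniformity_sd, sd(c(0.9, 1.0)), tolerance = 1e-12)
  expect_equal(st$chrom$uniformity_sd, 0.0707, tolerance = 1e-3)
})

test_that("the gold standard excludes damage-explicable genotypes", {
  panel <- simulate_panel(c(A = 4), n_sites = 400, fst = 0.2, seed = 51,
                          damage_frac = 1)
  tg <- simulate_admixed_target(panel, c(A = 1), seed = 52)
  tr <- truth_calls(tg)
  pair <- paste(pmin(tr$ref, tr$alt), pmax(tr$ref, tr$alt))
  has_t <- ifelse(tr$ref == "C" | tr$ref == "T",
                  ifelse(tr$ref == "T", tr$gt <= 1L, tr$gt >= 1L), FALSE)
  expect_false(any(pair == "C T" & has_t))
  # unfiltered standard keeps everything
  expect_equal(nrow(truth_calls(tg, deam_filter = FALSE)),
               nrow(panel$sites))
})
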