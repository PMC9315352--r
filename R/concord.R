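# Genotype concordance against the high-quality gold standard, with the
# two-class error taxonomy (incorrect position / incorrect genotype),
# information content, and MAF / heterozygote / chromosome stratification.

#' Build a gold-standard call set from a simulated target
#'
#' The gold standard plays the role of the high-quality genotypes: the
#' target's true simulated genotypes, optionally with the deamination rule
#' applied (damage-prone sites whose genotype carries the damaged allele are
#' excluded, so the standard keeps only confident transitions).
#'
#' @param target An `ancient_target`.
#' @param deam_filter Apply the deamination exclusion rule (default TRUE).
#' @return A `site_calls` data frame with `gt` set to the true genotypes.
#' @export
truth_calls <- function(target, deam_filter = TRUE) {
  calls <- data.frame(
    chrom = target$sites$chrom, pos = target$sites$pos,
    ref = target$sites$ref, alt = target$sites$alt,
    depth = NA_integer_,
    ll_rr = ifelse(target$true_genotypes == 0L, 0, -Inf),
    ll_ra = ifelse(target$true_genotypes == 1L, 0, -Inf),
    ll_aa = ifelse(target$true_genotypes == 2L, 0, -Inf),
    gt = target$true_genotypes, gq = Inf, filter = "PASS",
    stringsAsFactors = FALSE)
  class(calls) <- c("site_calls", "data.frame")
  if (deam_filter) calls <- deamination_filter(calls, mode = "drop")$calls
  calls
}

#' Genotype concordance report
#'
#' Compares imputed genotypes to the gold standard. Every imputed site is
#' classified: `incorrect_position` if its position is absent from the
#' standard, `incorrect_genotype` if present with a different genotype,
#' `correct` otherwise. Concordance is the correct fraction of all imputed
#' genotypes; information content is the ratio of imputed to gold-standard
#' genotype counts.
#'
#' @param imputed An `imputation_result` (or any data frame with `chrom`,
#'   `pos`, `gt`).
#' @param truth A `site_calls` gold standard, already deamination-filtered.
#' @return A `concordance_report` list: `n_imputed`, `n_correct`,
#'   `n_incorrect_position`, `n_incorrect_genotype`, `concordance`,
#'   `information_content`, `n_hq`.
#' @export
concordance <- function(imputed, truth) {
  truth <- truth[!is.na(truth$gt), , drop = FALSE]
  n_hq <- nrow(truth)
  imp <- imputed[!is.na(imputed$gt), , drop = FALSE]
  n_imp <- nrow(imp)
  if (n_imp == 0L) {
    rep <- list(n_imputed = 0L, n_correct = 0L, n_incorrect_position = 0L,
                n_incorrect_genotype = 0L, concordance = NA_real_,
                information_content = 0, n_hq = n_hq, undefined = TRUE)
    class(rep) <- "concordance_report"
    return(rep)
  }
  idx <- match(paste(imp$chrom, imp$pos), paste(truth$chrom, truth$pos))
  off_pos <- is.na(idx)
  wrong <- !off_pos & imp$gt != truth$gt[idx]
  rep <- list(
    n_imputed = n_imp,
    n_correct = sum(!off_pos & !wrong),
    n_incorrect_position = sum(off_pos),
    n_incorrect_genotype = sum(wrong),
    concordance = sum(!off_pos & !wrong) / n_imp,
    information_content = if (n_hq > 0) n_imp / n_hq else NA_real_,
    n_hq = n_hq, undefined = FALSE)
  class(rep) <- "concordance_report"
  rep
}

#' @exportS3Method base::print
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "concordance_report: %d imputed vs %d gold-standard genotypes\n",
    "  correct %d | incorrect genotype %d | incorrect position %d\n",
    "  concordance %.4f | information content %.4f\n"),
    x$n_imputed, x$n_hq, x$n_correct, x$n_incorrect_genotype,
    x$n_incorrect_position,
    if (is.na(x$concordance)) NaN else x$concordance,
    x$information_content))
  invisible(x)
}

#' Stratified concordance
#'
#' Splits the concordance computation by panel MAF bin, by heterozygous
#' gold-standard genotype, and/or by chromosome. Heterozygote stratification
#' conditions on the gold standard being heterozygous. The per-chromosome
#' uniformity summary is the standard deviation of chromosome concordances.
#'
#' @param imputed An `imputation_result`.
#' @param truth Gold-standard `site_calls`.
#' @param panel Optional `haplotype_panel` supplying MAF (required for
#'   `"maf"` strata).
#' @param strata Character subset of `c("maf", "het", "chrom")`.
#' @return List with one element per requested stratification: `maf` (one
#'   `concordance_report` per bin label), `het` (a single report), `chrom`
#'   (per-chromosome reports plus `uniformity_sd`).
#' @export
stratified_concordance <- function(imputed, truth, panel = NULL,
                                   strata = c("maf", "het", "chrom")) {
  strata <- match.arg(strata, several.ok = TRUE)
  out <- list()
  if ("maf" %in% strata) {
    if (is.null(panel)) stop("MAF strata need the panel")
    maf <- panel_maf(panel)
    bins <- assign_maf_bins(maf)
    key_p <- paste(panel$sites$chrom, panel$sites$pos)
    imp_bin <- bins[match(paste(imputed$chrom, imputed$pos), key_p), ,
                    drop = FALSE]
    tru_bin <- bins[match(paste(truth$chrom, truth$pos), key_p), ,
                    drop = FALSE]
    out$maf <- lapply(stats::setNames(nm = colnames(bins)), function(b) {
      isel <- which(imp_bin[, b]) # NA (site not in panel) drops out
      tsel <- which(tru_bin[, b])
      concordance(imputed[isel, , drop = FALSE],
                  truth[tsel, , drop = FALSE])
    })
  }
  if ("het" %in% strata) {
    het <- truth[!is.na(truth$gt) & truth$gt == 1L, , drop = FALSE]
    key_h <- paste(het$chrom, het$pos)
    sel <- paste(imputed$chrom, imputed$pos) %in% key_h
    out$het <- concordance(imputed[sel, , drop = FALSE], het)
  }
  if ("chrom" %in% strata) {
    chroms <- unique(c(imputed$chrom, truth$chrom))
    reports <- lapply(stats::setNames(nm = chroms), function(ch) {
      concordance(imputed[imputed$chrom == ch, , drop = FALSE],
                  truth[truth$chrom == ch, , drop = FALSE])
    })
    conc <- vapply(reports, function(r) r$concordance, numeric(1))
    out$chrom <- list(reports = reports,
                      uniformity_sd = stats::sd(conc[!is.na(conc)]))
  }
  out
}

#' Apply the deamination rule to imputed best-guess genotypes
#'
#' Drops imputed sites whose best-guess genotype could have been inferred
#' from a deaminated allele: a T-containing genotype at a C/T SNP or an
#' A-containing genotype at a G/A SNP. Evaluated call sets are held to the
#' same exclusion rule as the gold standard.
#'
#' @param result An `imputation_result`.
#' @return The filtered `imputation_result`.
#' @export
result_deamination_filter <- function(result) {
  pair_ct <- (result$ref == "C" & result$alt == "T") |
             (result$ref == "T" & result$alt == "C")
  pair_ga <- (result$ref == "G" & result$alt == "A") |
             (result$ref == "A" & result$alt == "G")
  damaged <- (pair_ct & gt_contains_allele(result$gt, result$ref,
                                           result$alt, "T")) |
             (pair_ga & gt_contains_allele(result$gt, result$ref,
                                           result$alt, "A"))
  out <- result[!damaged, , drop = FALSE]
  rownames(out) <- NULL
  out
}
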