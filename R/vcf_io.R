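# Plain-text VCF 4.2 emission and vcfR-backed reading for the containers
# the framework exchanges: phased panels (GT), target calls (GT/DP/AD/PL)
# and imputation results (GT/DS/GP, imputation score as INFO).

vcf_header <- function(format_lines, samples, contigs) {
  c("##fileformat=VCFv4.2",
    "##source=paleoimpute",
    sprintf("##contig=<ID=%s>", contigs),
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

gt_string <- function(gt, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  ifelse(is.na(gt), paste0(".", sep, "."),
         c(paste0("0", sep, "0"), paste0("0", sep, "1"),
           paste0("1", sep, "1"))[gt + 1L])
}

#' Write a phased panel as VCF plus a group-label file
#'
#' Haplotype pairs become phased diploid GT entries (`|` separator); donor
#' ids are `<group>_<index>`. The companion two-column tab-separated label
#' file maps sample id to population group.
#'
#' @param panel A `haplotype_panel`.
#' @param file VCF output path.
#' @param group_file Optional label-file path (default: `file` with
#'   `.groups.tsv` appended).
#' @return Invisibly, the two paths.
#' @export
write_panel_vcf <- function(panel, file,
                            group_file = paste0(file, ".groups.tsv")) {
  don <- donor_genotypes(panel)
  n_don <- length(don$groups)
  ids <- stats::ave(seq_len(n_don), don$groups, FUN = seq_along)
  samples <- sprintf("%s_%d", don$groups, ids)
  hap <- panel$haplotypes
  gt <- matrix("", nrow = nrow(panel$sites), ncol = n_don)
  for (j in seq_len(n_don)) {
    gt[, j] <- paste(hap[2 * j - 1, ], hap[2 * j, ], sep = "|")
  }
  body <- paste(panel$sites$chrom, panel$sites$pos, ".", panel$sites$ref,
                panel$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- vcf_header(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    samples, unique(panel$sites$chrom))
  writeLines(c(hdr, body), file)
  utils::write.table(data.frame(sample = samples, group = don$groups),
                     group_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(vcf = file, groups = group_file))
}

#' Read a phased panel VCF and its group-label file
#'
#' @param file Phased VCF path.
#' @param group_file Two-column tab-separated sample/group file.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(file, group_file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE))) stop("panel VCF must be phased")
  labels <- utils::read.table(group_file, sep = "\t", header = FALSE,
                              col.names = c("sample", "group"),
                              colClasses = "character")
  labels <- labels$group[match(colnames(gt), labels$sample)]
  if (any(is.na(labels))) stop("samples missing from group-label file")
  a1 <- t(apply(gt, 2, function(x) as.integer(substr(x, 1, 1))))
  a2 <- t(apply(gt, 2, function(x) as.integer(substr(x, 3, 3))))
  K2 <- 2 * nrow(a1)
  hap <- matrix(0L, nrow = K2, ncol = ncol(a1))
  hap[seq(1, K2, 2), ] <- a1
  hap[seq(2, K2, 2), ] <- a2
  structure(list(
    sites = data.frame(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE),
    haplotypes = hap,
    group_labels = rep(labels, each = 2),
    group_freqs = group_freq_matrix(hap, rep(labels, each = 2))),
    class = "haplotype_panel")
}

phred_pl <- function(ll) {
  # natural-log likelihood triplet -> normalized Phred-scaled PL string
  pl <- round(-10 / log(10) * (ll - apply(ll, 1, max)))
  pl[pl > 9999 | is.na(pl)] <- 9999
  paste(pl[, 1], pl[, 2], pl[, 3], sep = ",")
}

#' Write target genotype calls as an unphased VCF
#'
#' FORMAT fields GT, DP, AD, PL; the per-site filter flag goes to FILTER.
#'
#' @param calls A `site_calls` data frame.
#' @param file Output path.
#' @param sample Sample id.
#' @export
write_calls_vcf <- function(calls, file, sample = "TARGET") {
  ad <- if (all(c("n_ref", "n_alt") %in% names(calls))) {
    paste(calls$n_ref, calls$n_alt, sep = ",")
  } else "."
  pl <- phred_pl(as.matrix(calls[, c("ll_rr", "ll_ra", "ll_aa")]))
  fmt <- paste(gt_string(calls$gt), calls$depth, ad, pl, sep = ":")
  filt <- ifelse(nzchar(calls$filter), calls$filter, ".")
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                sprintf("%.2f", calls$gq), filt, ".", "GT:DP:AD:PL", fmt,
                sep = "\t")
  hdr <- vcf_header(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">'),
    sample, unique(calls$chrom))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read an unphased single-sample calls VCF
#'
#' @param file VCF path.
#' @return A `site_calls` data frame (`ll_*` recovered from PL).
#' @export
read_calls_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  phased <- grepl("|", gt_raw, fixed = TRUE)
  gt <- rep(NA_integer_, length(gt_raw))
  gt[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_raw %in% c("1/1", "1|1")] <- 2L
  dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  pl <- vcfR::extract.gt(v, element = "PL")[, 1]
  plm <- t(vapply(strsplit(pl, ","),
                  function(x) as.numeric(x)[1:3], numeric(3)))
  ll <- -plm * log(10) / 10
  filt <- fix[, "FILTER"]
  calls <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    depth = dp, ll_rr = ll[, 1], ll_ra = ll[, 2], ll_aa = ll[, 3],
    gt = gt, gq = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(filt == "." | is.na(filt), "", filt),
    stringsAsFactors = FALSE)
  attr(calls, "phased") <- phased
  class(calls) <- c("site_calls", "data.frame")
  calls
}

#' Write an imputation result as VCF
#'
#' FORMAT fields GT (best guess, unphased), DS (dosage), GP (posterior
#' triplet); the per-site imputation score is written as `INFO/SCORE`.
#'
#' @param result An `imputation_result`.
#' @param file Output path.
#' @param sample Sample id.
#' @export
write_result_vcf <- function(result, file, sample = "TARGET") {
  gp <- sprintf("%.6g,%.6g,%.6g", result$gp_rr, result$gp_ra, result$gp_aa)
  fmt <- paste(gt_string(result$gt), sprintf("%.6g", result$dosage), gp,
               sep = ":")
  info <- sprintf("SCORE=%.6g;OBS=%d", result$score,
                  as.integer(result$observed))
  body <- paste(result$chrom, result$pos, ".", result$ref, result$alt, ".",
                "PASS", info, "GT:DS:GP", fmt, sep = "\t")
  hdr <- vcf_header(c(
    '##INFO=<ID=SCORE,Number=1,Type=Float,Description="Imputation score (max genotype probability)">',
    '##INFO=<ID=OBS,Number=1,Type=Integer,Description="1 if the site was observed in the target">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Best-guess genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Posterior dosage">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">'),
    sample, unique(result$chrom))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read an imputation-result VCF written by [write_result_vcf()]
#'
#' @param file VCF path.
#' @return An `imputation_result` data frame.
#' @export
read_result_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gp <- vcfR::extract.gt(v, element = "GP")[, 1]
  gpm <- t(vapply(strsplit(gp, ","),
                  function(x) as.numeric(x)[1:3], numeric(3)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  gt <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt_raw]
  info <- vcfR::getINFO(v)
  score <- as.numeric(sub(".*SCORE=([^;]+).*", "\\1", info))
  obs <- sub(".*OBS=([^;]+).*", "\\1", info) == "1"
  res <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gp_rr = gpm[, 1], gp_ra = gpm[, 2], gp_aa = gpm[, 3],
    dosage = as.numeric(vcfR::extract.gt(v, element = "DS")[, 1]),
    gt = unname(gt), score = score, observed = obs,
    stringsAsFactors = FALSE)
  class(res) <- c("imputation_result", "data.frame")
  res
}
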