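# Genotype likelihoods, calling, and the variant / deamination / panel-QC /
# MAF filters applied before imputation.

#' Biallelic diploid genotype log-likelihoods
#'
#' Standard symmetric-error model: for a read carrying allele `a`,
#' `P(obs | a) = 1 - e` if the observed base equals `a` and `e` otherwise;
#' a heterozygote emits each allele with probability 1/2, so every read
#' contributes 1/2 to the het likelihood. Likelihoods are returned in
#' natural-log space, un-normalized.
#'
#' @param n_ref,n_alt Integer vectors of reference / alternate read counts
#'   per site.
#' @param base_error Per-read error rate, in (0, 0.5); the default 1e-3
#'   corresponds to Phred-30 bases, i.e. quality-trimmed reads.
#' @return S x 3 matrix of log-likelihoods for genotypes RR, RA, AA.
#' @export
genotype_likelihoods <- function(n_ref, n_alt, base_error = 1e-3) {
  if (base_error <= 0 || base_error >= 0.5) {
    stop("base_error must lie in (0, 0.5)")
  }
  if (length(n_ref) != length(n_alt)) stop("count vectors must match")
  le <- log(base_error); l1 <- log(1 - base_error)
  cbind(rr = n_ref * l1 + n_alt * le,
        ra = (n_ref + n_alt) * log(0.5),
        aa = n_ref * le + n_alt * l1)
}

# per-site ref/alt read counts from a target's pileups
pileup_counts <- function(target) {
  S <- length(target$true_genotypes)
  if (is.null(target$pileups) || nrow(target$pileups) == 0L) {
    return(cbind(n_ref = integer(S), n_alt = integer(S)))
  }
  n_alt <- tabulate(target$pileups$site[target$pileups$allele == 1L], S)
  n_tot <- tabulate(target$pileups$site, S)
  cbind(n_ref = n_tot - n_alt, n_alt = n_alt)
}

#' Compute per-site likelihoods and depths for a simulated target
#'
#' Call quality is a site-level variant confidence (the closest internal
#' analog of a variant caller's QUAL): for sites whose likelihood argmax is
#' a variant genotype, the Phred-scaled posterior of hom-ref; for hom-ref
#' argmax sites, the Phred-scaled posterior of being variant. A single
#' alternate read of Phred-30 quality thus clears a threshold of 30, while
#' a single reference read leaves the site unconfident — the behaviour that
#' makes variant-site calling possible at 0.5-2x coverage.
#'
#' @param target An `ancient_target` with pileups.
#' @param base_error Error rate fed to [genotype_likelihoods()].
#' @return A `site_calls` data frame: `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `n_ref`, `n_alt`, `ll_rr`, `ll_ra`, `ll_aa`, `gt` (NA until
#'   [call_genotypes()]), `gq`, `filter`.
#' @export
call_target <- function(target, base_error = 1e-3) {
  cnt <- pileup_counts(target)
  ll <- genotype_likelihoods(cnt[, "n_ref"], cnt[, "n_alt"], base_error)
  norm <- exp(ll - apply(ll, 1, max))
  post <- norm / rowSums(norm)
  variant_argmax <- max.col(norm, ties.method = "first") > 1L
  p_rr <- post[, 1]
  gq <- ifelse(variant_argmax,
               -10 * log10(pmax(p_rr, 1e-12)),
               -10 * log10(pmax(1 - p_rr, 1e-12)))
  calls <- data.frame(
    chrom = target$sites$chrom, pos = target$sites$pos,
    ref = target$sites$ref, alt = target$sites$alt,
    depth = as.integer(rowSums(cnt)),
    n_ref = as.integer(cnt[, "n_ref"]), n_alt = as.integer(cnt[, "n_alt"]),
    ll_rr = ll[, 1], ll_ra = ll[, 2], ll_aa = ll[, 3],
    gt = NA_integer_, gq = gq, filter = "", stringsAsFactors = FALSE)
  class(calls) <- c("site_calls", "data.frame")
  calls
}

#' Apply quality thresholds and emit genotype calls
#'
#' Sets each genotype to the likelihood argmax (flat prior), then flags sites
#' whose Phred-scaled genotype quality falls below `filter_quality` as
#' LOWQUAL with the genotype set missing. `emit_quality` is the lower
#' emission bound; zero-depth sites are always missing. Sites whose alleles
#' are not a biallelic ACGT pair are flagged NONBIALLELIC and dropped from
#' calling.
#'
#' @param calls A `site_calls` data frame.
#' @param emit_quality Minimum quality for a site to be emitted at all.
#' @param filter_quality Minimum quality for a genotype to survive filtering.
#' @return The `site_calls` with `gt`, `gq`, `filter` filled in.
#' @export
call_genotypes <- function(calls, emit_quality = 25, filter_quality = 30) {
  if (emit_quality < 0 || filter_quality < 0) stop("thresholds must be >= 0")
  ll <- as.matrix(calls[, c("ll_rr", "ll_ra", "ll_aa")])
  gt <- max.col(ll, ties.method = "first") - 1L
  bases <- c("A", "C", "G", "T")
  nonbi <- !(calls$ref %in% bases) | !(calls$alt %in% bases) |
    calls$ref == calls$alt
  low <- calls$depth == 0L | calls$gq < max(emit_quality, filter_quality)
  calls$gt <- ifelse(nonbi | low, NA_integer_, gt)
  calls$filter <- ifelse(nonbi, "NONBIALLELIC",
                         ifelse(low, "LOWQUAL", "PASS"))
  calls
}

# does genotype gt (0/1/2) at a ref/alt site carry the given allele symbol?
gt_contains_allele <- function(gt, ref, alt, allele) {
  (ref == allele & gt <= 1L) | (alt == allele & gt >= 1L)
}

#' Deamination filter
#'
#' Removes sites where the most likely genotype could have been produced by
#' post-mortem damage: at C/T SNPs, any called genotype containing a T
#' allele; at G/A SNPs, any called genotype containing an A allele. Other
#' allele pairs are never touched. Likelihood ties are resolved
#' conservatively: if any maximal-likelihood genotype contains the damaged
#' allele the site is treated as damaged.
#'
#' @param calls A `site_calls` with genotypes called.
#' @param mode `"drop"` removes flagged sites; `"mask"` keeps them with the
#'   genotype set missing (the behaviour used when every panel site must stay
#'   in the target, where filtered genotypes are kept as no-calls `./.`).
#' @return List with `calls` (kept or masked) and `removed` (data frame of
#'   the filtered sites).
#' @export
deamination_filter <- function(calls, mode = c("drop", "mask")) {
  mode <- match.arg(mode)
  bases <- c("A", "C", "G", "T")
  if (any(!calls$ref %in% bases & calls$filter != "NONBIALLELIC") ||
      any(!calls$alt %in% bases & calls$filter != "NONBIALLELIC")) {
    stop("unknown allele symbols in calls")
  }
  pair_ct <- (calls$ref == "C" & calls$alt == "T") |
             (calls$ref == "T" & calls$alt == "C")
  pair_ga <- (calls$ref == "G" & calls$alt == "A") |
             (calls$ref == "A" & calls$alt == "G")
  ll <- as.matrix(calls[, c("ll_rr", "ll_ra", "ll_aa")])
  mx <- apply(ll, 1, max)
  tied <- ll >= mx - 1e-9 # all argmax-tied genotypes
  contains <- function(allele) {
    (tied[, 1] & gt_contains_allele(0L, calls$ref, calls$alt, allele)) |
    (tied[, 2] & gt_contains_allele(1L, calls$ref, calls$alt, allele)) |
    (tied[, 3] & gt_contains_allele(2L, calls$ref, calls$alt, allele))
  }
  damaged <- !is.na(calls$gt) &
    ((pair_ct & contains("T")) | (pair_ga & contains("A")))
  removed <- calls[damaged, c("chrom", "pos", "ref", "alt", "gt")]
  rownames(removed) <- NULL
  if (mode == "drop") {
    kept <- calls[!damaged, , drop = FALSE]
    rownames(kept) <- NULL
  } else {
    kept <- calls
    kept$gt[damaged] <- NA_integer_
    kept$filter[damaged] <- "DEAMINATION"
  }
  list(calls = kept, removed = removed)
}

#' Reference-panel quality control
#'
#' Retains autosomal biallelic SNPs with site quality >= `min_qual`; masks
#' individual genotypes below `min_depth` as missing; requires a site call
#' rate of at least `min_call_rate` after depth masking; and removes sites
#' inside a repeat-mask interval list (BED convention: 0-based, half-open).
#'
#' @param genotypes Donor x site matrix of diploid genotypes (0/1/2, NA
#'   missing).
#' @param sites Data frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param site_qual Per-site quality scores.
#' @param depth Donor x site depth matrix (or NULL to skip depth masking).
#' @param min_qual,min_depth,min_call_rate QC thresholds.
#' @param repeat_mask Optional data frame `chrom`, `start`, `end` of repeat
#'   intervals to remove.
#' @return List: `genotypes` (masked, QC-passed columns), `sites`, `keep`
#'   (logical over input sites).
#' @export
panel_qc <- function(genotypes, sites, site_qual, depth = NULL,
                     min_qual = 30, min_depth = 4, min_call_rate = 0.8,
                     repeat_mask = NULL) {
  stopifnot(nrow(sites) == ncol(genotypes))
  if (!is.null(depth)) {
    genotypes[depth < min_depth] <- NA_integer_
  }
  call_rate <- colMeans(!is.na(genotypes))
  bases <- c("A", "C", "G", "T")
  biallelic <- sites$ref %in% bases & sites$alt %in% bases &
    sites$ref != sites$alt
  keep <- biallelic & site_qual >= min_qual & call_rate >= min_call_rate
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0) {
    in_mask <- vapply(seq_len(nrow(sites)), function(i) {
      any(repeat_mask$chrom == sites$chrom[i] &
          repeat_mask$start <= sites$pos[i] - 1 &
          repeat_mask$end > sites$pos[i] - 1)
    }, logical(1))
    keep <- keep & !in_mask
  }
  if (!any(keep)) stop("no sites survive QC")
  list(genotypes = genotypes[, keep, drop = FALSE],
       sites = sites[keep, , drop = FALSE], keep = keep)
}

#' Minor-allele-frequency bin labels
#' @return Character vector of the six bin labels.
#' @export
maf_bin_labels <- function() {
  c("<0.05", "0.05-0.1", "0.1-0.3", ">0.05", ">0.3", "No MAF")
}

#' Assign sites to (overlapping) MAF bins
#'
#' Bins deliberately overlap: the four narrow bins `<0.05`, `0.05-0.1`,
#' `0.1-0.3`, `>0.3` partition `[0, 0.5]`, while `>0.05` spans the upper
#' three and `No MAF` matches every site.
#'
#' @param maf Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @return Logical S x 6 membership matrix, columns named as
#'   [maf_bin_labels()].
#' @export
assign_maf_bins <- function(maf) {
  if (any(maf < 0 | maf > 0.5 + 1e-9, na.rm = TRUE)) {
    stop("MAF must lie in [0, 0.5]")
  }
  m <- cbind("<0.05" = maf < 0.05,
             "0.05-0.1" = maf >= 0.05 & maf < 0.1,
             "0.1-0.3" = maf >= 0.1 & maf < 0.3,
             ">0.05" = maf >= 0.05,
             ">0.3" = maf >= 0.3,
             "No MAF" = rep(TRUE, length(maf)))
  m
}

#' Panel minor allele frequencies
#' @param panel A `haplotype_panel`.
#' @return Per-site MAF from the pooled haplotypes.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$haplotypes)
  pmin(f, 1 - f)
}

#' Build the target site set for imputation
#'
#' The three constructions mirror the variant-calling strategies under
#' comparison: Method 1 keeps only sites with a called non-reference
#' genotype; Method 2 keeps all confidently called sites including
#' homozygous-reference; Method 3 uses exactly the panel's sites, taking the
#' target genotype where callable and missing elsewhere.
#'
#' @param method Integer 1, 2 or 3.
#' @param calls A `site_calls` with genotypes called (and deamination-
#'   filtered as appropriate).
#' @param panel A `haplotype_panel` (QC-passed sites).
#' @return Data frame over target sites: `panel_idx` (site's column in the
#'   panel), `gt`, `ll_rr`, `ll_ra`, `ll_aa`; for Method 3 one row per panel
#'   site with `gt = NA` where uncallable.
#' @export
build_target_sites <- function(method, calls, panel) {
  if (!method %in% 1:3) stop("method must be 1, 2 or 3")
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  key_c <- paste(calls$chrom, calls$pos)
  idx <- match(key_c, key_p)
  cols <- c("gt", "ll_rr", "ll_ra", "ll_aa")
  if (method == 3L) {
    out <- data.frame(panel_idx = seq_along(key_p), gt = NA_integer_,
                      ll_rr = NA_real_, ll_ra = NA_real_, ll_aa = NA_real_)
    hit <- !is.na(idx)
    out[idx[hit], cols] <- calls[hit, cols]
    return(out)
  }
  sel <- if (method == 1L) !is.na(calls$gt) & calls$gt > 0L else
    !is.na(calls$gt)
  sel <- sel & !is.na(idx)
  out <- data.frame(panel_idx = idx[sel], calls[sel, cols])
  rownames(out) <- NULL
  out
}
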