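# Li-Stephens haplotype-copying imputation.
#
# The target diploid is modelled as an ordered pair of panel haplotypes;
# each haploid copy switches donors between sites with probability
# 1 - exp(-4 Ne d / K) (d in Morgans), choosing the new donor uniformly.
# Emissions mix a per-haplotype miscopy rate theta with the site's genotype
# likelihoods; missing sites are flat. Posteriors come from the scaled
# forward-backward recursion implemented in C++ (O(S K^2) per pass).

#' @useDynLib paleoimpute, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Restrict a panel to a subset of its sites
#'
#' @param panel A `haplotype_panel`.
#' @param idx Site (column) indices to keep, in increasing order.
#' @return A `haplotype_panel` over the selected sites.
#' @export
subset_panel <- function(panel, idx) {
  if (is.unsorted(idx, strictly = TRUE)) stop("site indices must be increasing")
  out <- panel
  out$sites <- panel$sites[idx, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$haplotypes <- panel$haplotypes[, idx, drop = FALSE]
  out$group_freqs <- panel$group_freqs[, idx, drop = FALSE]
  out
}

# per-interval haploid switch probabilities for a panel's site list
ls_switch_probs <- function(panel, map, ne, K) {
  cm <- map_cm(map, panel$sites$chrom, panel$sites$pos)
  d <- diff(cm) / 100 # Morgans
  d[diff(as.integer(factor(panel$sites$chrom,
                           levels = unique(panel$sites$chrom)))) != 0] <- Inf
  rho <- 1 - exp(-4 * ne * pmax(d, 0) / K)
  c(0, rho) # first entry unused
}

#' Impute genotypes with the haplotype-copying HMM
#'
#' @param gl S x 3 matrix of genotype log-likelihoods (RR, RA, AA) on the
#'   panel's sites; rows of all-NA are treated as missing (flat emission).
#'   `-Inf` entries encode hard calls.
#' @param panel A phased `haplotype_panel` with K >= 2 haplotypes.
#' @param map Optional `genetic_map` (default: uniform 1 cM/Mb).
#' @param ne Effective population size scaling the switch rate
#'   (default 20,000).
#' @param theta Per-haplotype miscopy/mutation rate, in (0, 0.5).
#' @return An `imputation_result` data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `gp_rr`, `gp_ra`, `gp_aa`, `dosage`, `gt` (best guess), `score`
#'   (max GP), `observed`. Attributes `loglik_forward`, `loglik_backward`.
#' @export
impute_ls <- function(gl, panel, map = NULL, ne = 20000, theta = 1e-3) {
  stopifnot(inherits(panel, "haplotype_panel"))
  K <- nrow(panel$haplotypes)
  S <- nrow(panel$sites)
  if (K < 2) stop("panel must contain at least 2 haplotypes")
  if (S < 1) stop("empty site set")
  if (!is.matrix(gl) || nrow(gl) != S || ncol(gl) != 3) {
    stop("gl must be an S x 3 matrix aligned to the panel's sites")
  }
  if (theta <= 0 || theta >= 0.5) stop("theta must lie in (0, 0.5)")
  if (ne <= 0) stop("ne must be positive")
  observed <- !apply(is.na(gl), 1, all)
  if (!any(observed)) {
    # pure panel-driven smoothing is allowed, but warn: nothing anchors it
    warning("no observed sites: posterior reflects the panel prior only")
  }
  # normalize to linear space; missing rows flat
  lin <- matrix(1 / 3, nrow = S, ncol = 3)
  if (any(observed)) {
    g <- gl[observed, , drop = FALSE]
    g <- exp(g - apply(g, 1, max))
    lin[observed, ] <- g / rowSums(g)
  }
  if (is.null(map)) {
    lens <- tapply(panel$sites$pos, panel$sites$chrom, max)
    map <- uniform_map(stats::setNames(as.numeric(lens), names(lens)))
  }
  rho <- ls_switch_probs(panel, map, ne, K)
  fb <- .ls_fb_cpp(panel$haplotypes, lin, rho, theta)
  gp <- fb$gp
  res <- data.frame(
    chrom = panel$sites$chrom, pos = panel$sites$pos,
    ref = panel$sites$ref, alt = panel$sites$alt,
    gp_rr = gp[, 1], gp_ra = gp[, 2], gp_aa = gp[, 3],
    dosage = gp[, 2] + 2 * gp[, 3],
    gt = max.col(gp, ties.method = "first") - 1L,
    score = apply(gp, 1, max),
    observed = observed, stringsAsFactors = FALSE)
  attr(res, "loglik_forward") <- fb$loglik_forward
  attr(res, "loglik_backward") <- fb$loglik_backward
  class(res) <- c("imputation_result", "data.frame")
  res
}

# genotype log-likelihood matrix over panel sites from a target-site table;
# hard = TRUE encodes called genotypes as certainty triplets
target_gl_matrix <- function(tsites, n_panel_sites, hard = TRUE) {
  gl <- matrix(NA_real_, nrow = n_panel_sites, ncol = 3)
  obs <- !is.na(tsites$gt)
  if (hard) {
    rows <- tsites$panel_idx[obs]
    gl[rows, ] <- -Inf
    gl[cbind(rows, tsites$gt[obs] + 1L)] <- 0
  } else {
    ll <- as.matrix(tsites[obs, c("ll_rr", "ll_ra", "ll_aa")])
    gl[tsites$panel_idx[obs], ] <- ll
  }
  gl
}

#' Two-step pre-imputation genotype-probability filter
#'
#' First pass: the HMM runs on the target's observed sites only, using the
#' soft genotype likelihoods, to compute refined genotype probabilities.
#' Observed genotypes whose maximum GP falls below `gp_threshold` (default
#' 0.99) are removed, leaving only confident calls to anchor the full
#' imputation pass.
#'
#' @param tsites Target site table from [build_target_sites()].
#' @param panel A `haplotype_panel`.
#' @param map,ne,theta Passed to [impute_ls()].
#' @param gp_threshold Maximum-GP cutoff in (0, 1]; 0 disables filtering.
#' @return List: `tsites` (confident subset), `removed` (row indices of
#'   `tsites` dropped), `first_pass` (the first-pass `imputation_result`).
#' @export
two_step_prefilter <- function(tsites, panel, map = NULL, ne = 20000,
                               theta = 1e-3, gp_threshold = 0.99) {
  if (gp_threshold > 1 || gp_threshold < 0) {
    stop("gp_threshold must lie in [0, 1]")
  }
  obs <- which(!is.na(tsites$gt))
  if (gp_threshold == 0 || length(obs) == 0L) {
    return(list(tsites = tsites, removed = integer(0), first_pass = NULL))
  }
  ord <- obs[order(tsites$panel_idx[obs])]
  sub <- subset_panel(panel, tsites$panel_idx[ord])
  gl <- as.matrix(tsites[ord, c("ll_rr", "ll_ra", "ll_aa")])
  first <- impute_ls(gl, sub, map = map, ne = ne, theta = theta)
  drop_rows <- ord[first$score < gp_threshold]
  if (length(drop_rows) == length(obs)) {
    stop("no confident genotypes remain after the GP prefilter")
  }
  # method-3 style tables (one row per panel site) keep the row with the
  # genotype masked; methods 1-2 drop the rows outright
  full_grid <- all(tsites$panel_idx == seq_len(nrow(tsites)))
  if (full_grid || length(drop_rows) == 0L) {
    out <- tsites
    out$gt[drop_rows] <- NA_integer_
  } else {
    out <- tsites[-drop_rows, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(tsites = out, removed = drop_rows, first_pass = first)
}

#' Imputation-score filter
#'
#' Retains sites whose imputation score reaches 1 (within 1e-6), the
#' "highest imputation accuracy" post-filter. The default score is the
#' maximum genotype probability (certainty); an INFO-style dosage-variance
#' score is available as an alternative. Scores are rounded to two decimals
#' before thresholding — the precision at which imputation tools report
#' genotype probabilities, so "score of 1" means the reported score rounds
#' to 1 (max GP of at least 0.995), not an exact-arithmetic 1 that a
#' positive miscopy rate could never produce.
#'
#' @param result An `imputation_result`.
#' @param mode `"certainty"` (max GP) or `"dosage_variance"`
#'   (1 - Var(dosage | GP), clipped to `[0, 1]`).
#' @param threshold Score cutoff (default 1).
#' @return The filtered `imputation_result` (possibly empty, with a
#'   warning).
#' @export
score_filter <- function(result, mode = c("certainty", "dosage_variance"),
                         threshold = 1) {
  mode <- match.arg(mode)
  score <- if (mode == "certainty") {
    result$score
  } else {
    v <- result$gp_ra + 4 * result$gp_aa - result$dosage^2
    pmax(0, pmin(1, 1 - v))
  }
  keep <- round(score, 2) >= threshold - 1e-6
  if (!any(keep)) warning("no sites survive the imputation-score filter")
  out <- result[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
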