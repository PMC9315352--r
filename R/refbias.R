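# Reference-panel bias diagnostics: affinity profiles (which panel groups
# carry the genotypes found in correct vs incorrect imputed calls),
# supervised ancestry-shift estimates, and PCA displacement.

# donors x sites diploid genotype matrix and per-donor group labels
donor_genotypes <- function(panel) {
  K <- nrow(panel$haplotypes)
  odd <- seq(1, K, by = 2)
  list(genotypes = panel$haplotypes[odd, , drop = FALSE] +
         panel$haplotypes[odd + 1, , drop = FALSE],
       groups = panel$group_labels[odd])
}

# per-group presence of each genotype value: list over 0/1/2 of G x S
# logical matrices
group_genotype_presence <- function(panel) {
  don <- donor_genotypes(panel)
  groups <- unique(don$groups)
  lapply(0:2, function(g) {
    m <- matrix(FALSE, nrow = length(groups), ncol = ncol(don$genotypes),
                dimnames = list(groups, NULL))
    for (grp in groups) {
      sub <- don$genotypes[don$groups == grp, , drop = FALSE]
      m[grp, ] <- colSums(sub == g) > 0
    }
    m
  })
}

#' Panel groups supporting a genotype at a site
#'
#' A group supports a genotype if at least one of its diploid panel donors
#' carries that genotype at the site.
#'
#' @param gt Genotype (0/1/2).
#' @param site Site (column) index in the panel.
#' @param panel A `haplotype_panel`.
#' @return Character vector of supporting group names (alphabetical).
#' @export
group_support <- function(gt, site, panel) {
  if (site < 1 || site > nrow(panel$sites)) stop("site absent from panel")
  if (!gt %in% 0:2) stop("genotype must be 0, 1 or 2")
  don <- donor_genotypes(panel)
  hit <- vapply(unique(don$groups), function(grp) {
    any(don$genotypes[don$groups == grp, site] == gt)
  }, logical(1))
  sort(names(hit)[hit])
}

# "EUD; EUW"-style support pattern per (genotype, site) pair, vectorized
support_patterns <- function(gts, sites, panel, presence = NULL) {
  if (is.null(presence)) presence <- group_genotype_presence(panel)
  groups <- sort(rownames(presence[[1]]))
  pat <- rep("", length(gts))
  for (grp in groups) {
    hit <- vapply(seq_along(gts), function(i) {
      presence[[gts[i] + 1L]][grp, sites[i]]
    }, logical(1))
    pat <- ifelse(hit, ifelse(nzchar(pat), paste(pat, grp, sep = "; "), grp),
                  pat)
  }
  ifelse(nzchar(pat), pat, "none")
}

# total-variation distance between two named frequency vectors
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  p <- p[keys]; q <- q[keys]
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  0.5 * sum(abs(p - q))
}

#' Reference-affinity profile
#'
#' Classifies imputed sites against the gold standard (as in
#' [concordance()]), then tabulates, per class, the distribution of
#' group-support patterns — which subsets of panel groups carry the observed
#' genotype. The divergence of the correct-class and incorrect-genotype-class
#' distributions from the gold-standard baseline is reported as
#' total-variation distance; imputation drifting toward the panel's majority
#' components shows up as excess mass on majority-group patterns in the
#' incorrect class.
#'
#' @param imputed An `imputation_result`.
#' @param truth Gold-standard `site_calls`.
#' @param panel A `haplotype_panel` (the affinity baseline).
#' @return An `affinity_profile` list: `patterns` (per-class named frequency
#'   vectors for `hq`, `correct`, `incorrect_genotype`), `counts`, `tv`
#'   (distance of each imputed class from the `hq` baseline).
#' @export
affinity_profile <- function(imputed, truth, panel) {
  truth <- truth[!is.na(truth$gt), , drop = FALSE]
  imp <- imputed[!is.na(imputed$gt), , drop = FALSE]
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  t_idx <- match(paste(truth$chrom, truth$pos), key_p)
  i_idx <- match(paste(imp$chrom, imp$pos), key_p)
  if (any(is.na(t_idx)) || any(is.na(i_idx))) {
    stop("site absent from panel")
  }
  m <- match(paste(imp$chrom, imp$pos), paste(truth$chrom, truth$pos))
  correct <- !is.na(m) & imp$gt == truth$gt[m]
  incorrect <- !is.na(m) & imp$gt != truth$gt[m]

  presence <- group_genotype_presence(panel)
  tab <- function(gts, sites) {
    if (length(gts) == 0L) return(NULL)
    p <- table(support_patterns(gts, sites, panel, presence))
    prop.table(p)
  }
  patterns <- list(
    hq = tab(truth$gt, t_idx),
    correct = tab(imp$gt[correct], i_idx[correct]),
    incorrect_genotype = tab(imp$gt[incorrect], i_idx[incorrect]))
  empty <- vapply(patterns, is.null, logical(1))
  if (any(empty)) {
    warning("empty class omitted from affinity profile: ",
            paste(names(patterns)[empty], collapse = ", "))
  }
  tv <- vapply(c("correct", "incorrect_genotype"), function(cl) {
    if (is.null(patterns[[cl]]) || is.null(patterns$hq)) return(NA_real_)
    tv_distance(c(patterns[[cl]]), c(patterns$hq))
  }, numeric(1))
  structure(list(patterns = patterns,
                 counts = c(hq = nrow(truth), correct = sum(correct),
                            incorrect_genotype = sum(incorrect)),
                 tv = tv),
            class = "affinity_profile")
}

# exact simplex-constrained least squares by active-set enumeration:
# minimizes ||d - X w||^2 subject to w >= 0, sum(w) = 1. With a handful of
# groups, enumerating support subsets is exact and deterministic.
simplex_lsq <- function(X, d) {
  G <- ncol(X)
  best <- NULL
  for (mask in seq_len(2^G - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
    Xs <- X[, sel, drop = FALSE]
    A <- crossprod(Xs)
    kkt <- rbind(cbind(2 * A, 1), c(rep(1, length(sel)), 0))
    rhs <- c(2 * crossprod(Xs, d), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_along(sel)]
    if (any(w < -1e-9)) next
    w <- pmax(w, 0); w <- w / sum(w)
    rss <- sum((d - Xs %*% w)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      full <- numeric(G)
      full[sel] <- w
      best <- list(w = full, rss = rss)
    }
  }
  if (is.null(best)) stop("simplex least squares failed")
  best
}

#' Supervised ancestry proportions from dosages
#'
#' Least-squares fit of the per-site expected dosage
#' \eqn{2 \sum_g w_g f_g} to the observed dosages, with the weights
#' constrained to the probability simplex. A supervised surrogate for model-
#' based admixture estimation, used to score ancestry shift after
#' imputation.
#'
#' @param dosages Numeric vector of observed dosages in `[0, 2]` (NA
#'   allowed, dropped).
#' @param freqs Group x site matrix of panel alternate-allele frequencies,
#'   aligned to `dosages`.
#' @return An `ancestry_estimate`: `props` (named, on the simplex),
#'   `residual` (root mean squared error), `ill_conditioned` flag.
#' @export
ancestry_props <- function(dosages, freqs) {
  if (nrow(freqs) < 2) stop("need at least 2 groups")
  ok <- !is.na(dosages)
  if (sum(ok) < 100) stop("need at least 100 overlapping sites")
  F <- freqs[, ok, drop = FALSE]
  d <- dosages[ok]
  ill <- FALSE
  for (i in seq_len(nrow(F) - 1)) {
    for (j in seq(i + 1, nrow(F))) {
      if (max(abs(F[i, ] - F[j, ])) < 1e-9) ill <- TRUE
    }
  }
  if (ill) warning("ill-conditioned: some groups have identical frequencies")
  fit <- simplex_lsq(2 * t(F), d)
  structure(list(props = stats::setNames(fit$w, rownames(freqs)),
                 residual = sqrt(fit$rss / length(d)),
                 ill_conditioned = ill),
            class = "ancestry_estimate")
}

#' @exportS3Method base::print
print.ancestry_estimate <- function(x, ...) {
  cat("ancestry_estimate:",
      paste(sprintf("%s=%.3f", names(x$props), x$props), collapse = ", "),
      sprintf("(rmse %.3f%s)\n", x$residual,
              if (x$ill_conditioned) ", ill-conditioned" else ""))
  invisible(x)
}

#' Ancestry shift and PCA displacement after imputation
#'
#' Quantifies drift of the imputed genotypes toward the panel's majority
#' component: per-group ancestry deltas (imputed minus gold standard, from
#' [ancestry_props()]), and the displacement of the sample in the panel's
#' principal-component space. The PCA is computed on the panel donors'
#' frequency-standardized genotypes; the gold-standard and imputed samples
#' are projected onto it, not included in the decomposition.
#'
#' @param truth Gold-standard `site_calls` (genotypes used as dosages).
#' @param imputed An `imputation_result` (posterior dosages used).
#' @param panel A `haplotype_panel`.
#' @param majority_group Group whose direction is scored; default the group
#'   with the most donors.
#' @return List: `delta` (named per-group ancestry shift),
#'   `delta_majority`, `displacement` (Euclidean, PC1-2),
#'   `toward_majority` (signed component of the displacement toward the
#'   majority-group centroid), `coords` (donor, truth and imputed PC1-2
#'   coordinates), plus the two `ancestry_estimate`s.
#' @export
bias_shift <- function(truth, imputed, panel, majority_group = NULL) {
  don <- donor_genotypes(panel)
  if (is.null(majority_group)) {
    majority_group <- names(which.max(table(don$groups)))
  }
  key_p <- paste(panel$sites$chrom, panel$sites$pos)

  t_idx <- match(paste(truth$chrom, truth$pos), key_p)
  i_idx <- match(paste(imputed$chrom, imputed$pos), key_p)
  if (any(is.na(t_idx)) || any(is.na(i_idx))) stop("site absent from panel")
  S <- nrow(panel$sites)
  d_truth <- rep(NA_real_, S); d_truth[t_idx] <- truth$gt
  d_imp <- rep(NA_real_, S); d_imp[i_idx] <- imputed$dosage

  est_t <- ancestry_props(d_truth, panel$group_freqs)
  est_i <- ancestry_props(d_imp, panel$group_freqs)
  delta <- est_i$props - est_t$props

  # PCA on frequency-standardized donor genotypes; samples projected
  f <- colMeans(panel$haplotypes)
  poly <- f > 0 & f < 1
  n_donors <- nrow(don$genotypes)
  if (sum(poly) < n_donors) stop("fewer polymorphic sites than samples")
  std <- function(v) (v - 2 * f[poly]) / sqrt(2 * f[poly] * (1 - f[poly]))
  D <- t(apply(don$genotypes[, poly, drop = FALSE], 1, std))
  pca <- stats::prcomp(D, center = FALSE, scale. = FALSE)
  project <- function(dos) {
    v <- dos[poly]
    v[is.na(v)] <- 2 * f[poly][is.na(v)] # mean imputation
    std(v) %*% pca$rotation[, 1:2]
  }
  co_t <- drop(project(d_truth))
  co_i <- drop(project(d_imp))
  disp <- sqrt(sum((co_i - co_t)^2))
  centroid <- colMeans(pca$x[don$groups == majority_group, 1:2, drop = FALSE])
  dir <- centroid - co_t
  nrm <- sqrt(sum(dir^2))
  toward <- if (nrm > 0) sum((co_i - co_t) * dir) / nrm else 0
  list(delta = delta, delta_majority = unname(delta[majority_group]),
       displacement = disp, toward_majority = toward,
       majority_group = majority_group,
       coords = list(donors = pca$x[, 1:2], groups = don$groups,
                     truth = co_t, imputed = co_i),
       ancestry_truth = est_t, ancestry_imputed = est_i)
}
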