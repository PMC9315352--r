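# Synthetic structured panels and admixed damaged targets.
#
# The generator stands in for the real study system: a small wild-boar/pig
# reference panel dominated by European groups, and Neolithic targets of
# mixed European / Near Eastern ancestry sequenced to ~0.5-2x with
# post-mortem deamination. Population structure follows the Balding-Nichols
# drift model; targets are frequency-conditional mosaics over the panel's
# groups.

# run code under a temporary RNG seed, restoring global RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

DAMAGE_PAIRS <- list(c("C", "T"), c("G", "A"))
OTHER_PAIRS <- list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))

#' Simulate a structured phased reference panel
#'
#' Draws an ancestral allele frequency per site (uniform on `freq_range`),
#' per-group frequencies from the Balding-Nichols model
#' (Beta with mean equal to the ancestral frequency and variance scaled by
#' the group's drift parameter `fst`), and haplotype alleles as Bernoulli
#' draws from the group frequency. Each diploid donor contributes two
#' independent haplotypes.
#'
#' The default composition mirrors the main wild-boar/domestic-pig panel the
#' framework emulates: 19 European wild boar (EUW), 25 European domestic
#' (EUD), 4 Balkan/Greek wild boar (BLW) and 3 Near Eastern wild boar (NEW)
#' diploid donors — 51 donors, 102 haplotypes — a panel heavily skewed toward
#' European components.
#'
#' @param group_sizes Named integer vector: diploid donors per population
#'   group.
#' @param n_sites Number of biallelic SNPs.
#' @param fst Per-group drift (Balding-Nichols), in (0,1); recycled.
#' @param seed Optional integer seed; identical inputs + seed give identical
#'   panels.
#' @param chrom Chromosome id for the simulated region.
#' @param chrom_length Region length in bp (default: 1 site per 500 bp,
#'   matching the marker density of a dense whole-genome call set).
#' @param damage_frac Fraction of sites assigned a deamination-prone allele
#'   pair (C/T or G/A).
#' @param freq_range Range of the ancestral allele frequency.
#' @return A `haplotype_panel`: list with `sites` (chrom, pos, ref, alt),
#'   `haplotypes` (K x S 0/1 matrix), `group_labels` (length K),
#'   `group_freqs` (group x S matrix of empirical alternate-allele
#'   frequencies).
#' @export
simulate_panel <- function(group_sizes = c(EUW = 19, EUD = 25, BLW = 4,
                                           NEW = 3),
                           n_sites = 5000, fst = 0.15, seed = NULL,
                           chrom = "1", chrom_length = NULL,
                           damage_frac = 0.5, freq_range = c(0.05, 0.95)) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be named")
  }
  if (any(group_sizes < 0)) stop("group counts must be >= 0")
  group_sizes <- group_sizes[group_sizes > 0]
  if (length(group_sizes) == 0L || sum(group_sizes) == 0L) stop("empty panel")
  if (n_sites < 1) stop("n_sites must be >= 1")
  fst <- rep_len(fst, length(group_sizes))
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (is.null(chrom_length)) chrom_length <- n_sites * 500
  if (chrom_length < n_sites) stop("chrom_length must be >= n_sites")

  local_seed(seed, {
    pos <- sort(sample.int(chrom_length, n_sites))
    # allele pairs: damage-prone C/T or G/A at damage_frac of sites
    prone <- stats::runif(n_sites) < damage_frac
    pair_idx <- ifelse(prone, sample.int(2L, n_sites, replace = TRUE),
                       sample.int(4L, n_sites, replace = TRUE))
    flip <- stats::runif(n_sites) < 0.5
    ref <- alt <- character(n_sites)
    for (i in seq_len(n_sites)) {
      pair <- if (prone[i]) DAMAGE_PAIRS[[pair_idx[i]]] else
        OTHER_PAIRS[[pair_idx[i]]]
      if (flip[i]) pair <- rev(pair)
      ref[i] <- pair[1]; alt[i] <- pair[2]
    }

    anc <- stats::runif(n_sites, freq_range[1], freq_range[2])
    groups <- names(group_sizes)
    K <- 2L * sum(group_sizes)
    hap <- matrix(0L, nrow = K, ncol = n_sites)
    labels <- rep(groups, times = 2L * group_sizes)
    model_freqs <- matrix(NA_real_, nrow = length(groups), ncol = n_sites,
                          dimnames = list(groups, NULL))
    for (gi in seq_along(groups)) {
      f <- fst[gi]
      gf <- stats::rbeta(n_sites, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
      model_freqs[gi, ] <- gf
      rows <- which(labels == groups[gi])
      hap[rows, ] <- matrix(
        stats::rbinom(length(rows) * n_sites, 1L,
                      rep(gf, each = length(rows))),
        nrow = length(rows))
    }
    gfreq <- group_freq_matrix(hap, labels)
    structure(list(
      sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
      haplotypes = hap,
      group_labels = labels,
      group_freqs = gfreq),
      chrom_length = chrom_length,
      model_freqs = model_freqs, # Beta-drawn group frequencies (pre-sampling)
      class = "haplotype_panel")
  })
}

# empirical per-group alternate-allele frequency matrix (groups x sites)
group_freq_matrix <- function(hap, labels) {
  groups <- unique(labels)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(hap),
                dimnames = list(groups, NULL))
  for (g in groups) out[g, ] <- colMeans(hap[labels == g, , drop = FALSE])
  out
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d donors), %d sites\n",
              nrow(x$haplotypes), nrow(x$haplotypes) / 2, nrow(x$sites)))
  comp <- table(x$group_labels) / 2
  cat("  donors per group:",
      paste(sprintf("%s=%d", names(comp), comp), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an admixed diploid target
#'
#' Each haploid copy of the target is an ancestry mosaic over the panel's
#' population groups: segment lengths are exponential on the genetic map
#' (rate `switch_rate_per_cm`), each segment's group is drawn from
#' `ancestry_props`, and within a segment alleles are Bernoulli draws from
#' the group's panel frequency (frequency-conditional copying). True diploid
#' genotypes are the haploid allele sums.
#'
#' The default admixture, ~46% European / ~54% Near Eastern, is the kind of
#' mixed-ancestry individual for which reference-panel bias matters most.
#'
#' @param panel A `haplotype_panel`.
#' @param ancestry_props Named proportions over panel groups, summing to 1.
#' @param switch_rate_per_cm Ancestry switch rate per cM (default 0.01, i.e.
#'   1 per Morgan).
#' @param map Optional `genetic_map`; default: uniform 1 cM/Mb over the
#'   panel's region.
#' @param seed Optional integer seed.
#' @return An `ancient_target`: list with `sites`, `true_genotypes` (0/1/2),
#'   `ancestry_props`, `local_ancestry` (2 x S group matrix), `pileups`
#'   (NULL until [simulate_reads()]).
#' @export
simulate_admixed_target <- function(panel,
                                    ancestry_props = c(EUW = 0.46,
                                                       NEW = 0.54),
                                    switch_rate_per_cm = 0.01, map = NULL,
                                    seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  groups <- rownames(panel$group_freqs)
  if (!all(names(ancestry_props) %in% groups)) {
    stop("unknown group name in ancestry_props: ",
         paste(setdiff(names(ancestry_props), groups), collapse = ", "))
  }
  if (abs(sum(ancestry_props) - 1) > 1e-6) {
    stop("ancestry_props must sum to 1")
  }
  if (switch_rate_per_cm < 0) stop("switch rate must be >= 0")
  if (is.null(map)) {
    lens <- tapply(panel$sites$pos, panel$sites$chrom, max)
    map <- uniform_map(stats::setNames(as.numeric(lens), names(lens)))
  }
  S <- nrow(panel$sites)
  cm <- map_cm(map, panel$sites$chrom, panel$sites$pos)

  local_seed(seed, {
    la <- matrix(NA_character_, nrow = 2, ncol = S)
    alleles <- matrix(0L, nrow = 2, ncol = S)
    for (ch in unique(panel$sites$chrom)) {
      sel <- which(panel$sites$chrom == ch)
      span <- max(cm[sel])
      for (copy in 1:2) {
        brk <- numeric(0)
        if (switch_rate_per_cm > 0) {
          # draw breakpoints until past the end of the chromosome
          at <- 0
          repeat {
            at <- at + stats::rexp(1, rate = switch_rate_per_cm)
            if (at >= span) break
            brk <- c(brk, at)
          }
        }
        seg_groups <- sample(names(ancestry_props), length(brk) + 1L,
                             replace = TRUE, prob = ancestry_props)
        seg <- findInterval(cm[sel], brk) + 1L
        grp <- seg_groups[seg]
        la[copy, sel] <- grp
        gi <- match(grp, rownames(panel$group_freqs))
        f <- panel$group_freqs[cbind(gi, sel)]
        alleles[copy, sel] <- stats::rbinom(length(sel), 1L, f)
      }
    }
    structure(list(
      sites = panel$sites,
      true_genotypes = as.integer(alleles[1, ] + alleles[2, ]),
      ancestry_props = ancestry_props,
      local_ancestry = la,
      pileups = NULL),
      class = "ancient_target")
  })
}

#' @exportS3Method base::print
print.ancient_target <- function(x, ...) {
  cat(sprintf("ancient_target: %d sites, het fraction %.3f\n",
              length(x$true_genotypes), mean(x$true_genotypes == 1L)))
  cat("  ancestry:",
      paste(sprintf("%s=%.2f", names(x$ancestry_props), x$ancestry_props),
            collapse = ", "), "\n")
  if (!is.null(x$pileups)) {
    cat(sprintf("  pileups: %d reads, realized coverage %.3fx\n",
                nrow(x$pileups), attr(x, "realized_coverage")))
  }
  invisible(x)
}

#' Simulate damaged low-coverage read pileups
#'
#' Per-site read counts are Poisson(`coverage`); each read copies one of the
#' two true alleles uniformly and flips to the other allele with probability
#' `base_error`. Post-mortem deamination is strand-specific: at C/T sites a
#' read carrying C on the + strand is converted to T with probability
#' `deam_rate`; at G/A sites a read carrying G on the - strand is converted
#' to A. Other allele pairs are unaffected.
#'
#' @param target An `ancient_target`.
#' @param coverage Mean reads per site (Poisson lambda), `>= 0`.
#' @param base_error Per-read sequencing error rate.
#' @param deam_rate Deamination conversion probability.
#' @param seed Optional integer seed.
#' @return The target with a `pileups` data frame (`site`, `allele` 0=ref /
#'   1=alt, `strand`, `qual`) and attribute `realized_coverage`.
#' @export
simulate_reads <- function(target, coverage = 1, base_error = 1e-3,
                           deam_rate = 0.1, seed = NULL) {
  stopifnot(inherits(target, "ancient_target"))
  if (coverage < 0) stop("coverage must be >= 0")
  if (base_error < 0 || base_error >= 0.5) stop("base_error must be in [0, 0.5)")
  if (deam_rate < 0 || deam_rate >= 0.5) stop("deam_rate must be in [0, 0.5)")
  S <- length(target$true_genotypes)

  local_seed(seed, {
    n <- stats::rpois(S, coverage)
    site <- rep.int(seq_len(S), n)
    N <- length(site)
    g <- target$true_genotypes[site]
    allele <- ifelse(g == 1L, stats::rbinom(N, 1L, 0.5), as.integer(g / 2L))
    err <- stats::rbinom(N, 1L, base_error) == 1L
    allele <- ifelse(err, 1L - allele, allele)
    strand <- ifelse(stats::rbinom(N, 1L, 0.5) == 1L, "+", "-")

    if (deam_rate > 0 && N > 0) {
      ref <- target$sites$ref[site]
      alt <- target$sites$alt[site]
      base <- ifelse(allele == 0L, ref, alt)
      pair_ct <- (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
      pair_ga <- (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
      hit <- (pair_ct & base == "C" & strand == "+") |
             (pair_ga & base == "G" & strand == "-")
      conv <- hit & stats::rbinom(N, 1L, deam_rate) == 1L
      allele <- ifelse(conv, 1L - allele, allele)
    }
    qual <- sample(20:40, N, replace = TRUE)
    target$pileups <- data.frame(site = site, allele = allele,
                                 strand = strand, qual = qual,
                                 stringsAsFactors = FALSE)
    attr(target, "realized_coverage") <- N / S
    target
  })
}

#' Downsample read pileups to a lower coverage
#'
#' Thins reads independently, the standard way of downsampling
#' high-coverage genomes onto a 0.5x-2x evaluation grid.
#'
#' @param target An `ancient_target` with pileups.
#' @param target_coverage Desired mean coverage (mutually exclusive with
#'   `factor`).
#' @param factor Retention probability per read, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The target with thinned pileups and updated
#'   `realized_coverage`.
#' @export
downsample_pileups <- function(target, target_coverage = NULL, factor = NULL,
                               seed = NULL) {
  stopifnot(inherits(target, "ancient_target"))
  if (is.null(target$pileups)) stop("target has no pileups")
  cur <- attr(target, "realized_coverage")
  if (is.null(factor)) {
    if (is.null(target_coverage)) stop("give target_coverage or factor")
    factor <- target_coverage / cur
  }
  if (factor > 1 + 1e-9) {
    stop("requested coverage above current realized coverage")
  }
  if (factor >= 1) return(target)
  local_seed(seed, {
    keep <- stats::runif(nrow(target$pileups)) < factor
    target$pileups <- target$pileups[keep, , drop = FALSE]
    rownames(target$pileups) <- NULL
    attr(target, "realized_coverage") <-
      nrow(target$pileups) / length(target$true_genotypes)
    target
  })
}

#' Build a target directly from two panel haplotypes
#'
#' The perfect-information construction: the target's haploid copies are two
#' existing panel haplotypes, so with deep error-free sequencing the imputer
#' has everything it needs. Used to verify the pipeline's upper bound.
#'
#' @param panel A `haplotype_panel`.
#' @param hap_idx Two haplotype row indices.
#' @return An `ancient_target` (no pileups yet).
#' @export
target_from_panel <- function(panel, hap_idx = c(1L, 2L)) {
  stopifnot(inherits(panel, "haplotype_panel"), length(hap_idx) == 2)
  if (any(hap_idx < 1 | hap_idx > nrow(panel$haplotypes))) {
    stop("haplotype index out of range")
  }
  a <- panel$haplotypes[hap_idx, , drop = FALSE]
  grp <- panel$group_labels[hap_idx]
  props <- table(grp) / 2
  structure(list(
    sites = panel$sites,
    true_genotypes = as.integer(a[1, ] + a[2, ]),
    ancestry_props = stats::setNames(as.numeric(props), names(props)),
    local_ancestry = matrix(rep(grp, ncol(a)), nrow = 2),
    pileups = NULL),
    class = "ancient_target")
}
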