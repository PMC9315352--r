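# Independent oracles, written naively on purpose: they share no code with
# the package internals they check.

# --- naive diploid copying-HMM forward-backward over the explicit K^2 x K^2
#     transition matrix (no factorization tricks) -----------------------------
naive_fb <- function(alleles, gl_log, rho, theta) {
  K <- nrow(alleles); S <- ncol(alleles)
  # normalized linear emissions per genotype
  gl <- matrix(1 / 3, S, 3)
  obs <- !apply(is.na(gl_log), 1, all)
  if (any(obs)) {
    g <- gl_log[obs, , drop = FALSE]
    g <- exp(g - apply(g, 1, max))
    gl[obs, ] <- g / rowSums(g)
  }
  mis <- rbind(c((1 - theta)^2, 2 * theta * (1 - theta), theta^2),
               c(theta * (1 - theta), (1 - theta)^2 + theta^2,
                 theta * (1 - theta)),
               c(theta^2, 2 * theta * (1 - theta), (1 - theta)^2))
  n_states <- K * K
  state_h1 <- rep(seq_len(K), times = K)
  state_h2 <- rep(seq_len(K), each = K)
  emis <- function(s) {
    d <- alleles[state_h1, s] + alleles[state_h2, s]
    rowSums(mis[d + 1, , drop = FALSE] * matrix(gl[s, ], n_states, 3,
                                                byrow = TRUE))
  }
  trans <- function(r) {
    t1 <- matrix(r / K, K, K) + diag(1 - r, K)
    T2 <- matrix(0, n_states, n_states)
    for (a in seq_len(n_states)) {
      for (b in seq_len(n_states)) {
        T2[a, b] <- t1[state_h1[a], state_h1[b]] * t1[state_h2[a], state_h2[b]]
      }
    }
    T2
  }
  f <- matrix(0, S, n_states)
  scl <- numeric(S)
  f[1, ] <- emis(1) / n_states
  scl[1] <- sum(f[1, ]); f[1, ] <- f[1, ] / scl[1]
  for (s in seq_len(S)[-1]) {
    f[s, ] <- as.vector(t(trans(rho[s])) %*% f[s - 1, ]) * emis(s)
    scl[s] <- sum(f[s, ]); f[s, ] <- f[s, ] / scl[s]
  }
  b <- matrix(0, S, n_states)
  b[S, ] <- 1
  for (s in rev(seq_len(S - 1))) {
    b[s, ] <- as.vector(trans(rho[s + 1]) %*% (emis(s + 1) * b[s + 1, ]))
    b[s, ] <- b[s, ] / max(b[s, ])
  }
  gp <- matrix(0, S, 3)
  for (s in seq_len(S)) {
    d <- alleles[state_h1, s] + alleles[state_h2, s]
    e_state <- as.vector(mis[d + 1, , drop = FALSE] %*% gl[s, ])
    post_ex <- f[s, ] * b[s, ] / e_state # forward without site-s emission
    for (g in 0:2) {
      gp[s, g + 1] <- sum(post_ex * mis[d + 1, g + 1]) * gl[s, g + 1]
    }
    gp[s, ] <- gp[s, ] / sum(gp[s, ])
  }
  list(gp = gp, loglik = sum(log(scl)))
}

# --- exhaustive path enumeration (tiny instances only) -----------------------
enum_paths_gp <- function(alleles, gl_log, rho, theta) {
  K <- nrow(alleles); S <- ncol(alleles)
  gl <- matrix(1 / 3, S, 3)
  obs <- !apply(is.na(gl_log), 1, all)
  if (any(obs)) {
    g <- gl_log[obs, , drop = FALSE]
    g <- exp(g - apply(g, 1, max))
    gl[obs, ] <- g / rowSums(g)
  }
  mis <- rbind(c((1 - theta)^2, 2 * theta * (1 - theta), theta^2),
               c(theta * (1 - theta), (1 - theta)^2 + theta^2,
                 theta * (1 - theta)),
               c(theta^2, 2 * theta * (1 - theta), (1 - theta)^2))
  t1 <- function(r) matrix(r / K, K, K) + diag(1 - r, K)
  states <- expand.grid(h1 = seq_len(K), h2 = seq_len(K))
  n_states <- nrow(states)
  paths <- do.call(expand.grid, rep(list(seq_len(n_states)), S))
  gp_num <- matrix(0, S, 3)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- as.integer(paths[p, ])
    pr <- 1 / n_states
    for (s in seq_len(S)) {
      h1 <- states$h1[path[s]]; h2 <- states$h2[path[s]]
      if (s > 1) {
        m1 <- t1(rho[s]);
        pr <- pr * m1[states$h1[path[s - 1]], h1] *
          m1[states$h2[path[s - 1]], h2]
      }
      d <- alleles[h1, s] + alleles[h2, s]
      pr <- pr * sum(mis[d + 1, ] * gl[s, ])
    }
    total <- total + pr
    for (s in seq_len(S)) {
      h1 <- states$h1[path[s]]; h2 <- states$h2[path[s]]
      d <- alleles[h1, s] + alleles[h2, s]
      # weight genotype posterior by this path's probability and the
      # per-site genotype emission split
      es <- mis[d + 1, ] * gl[s, ]
      gp_num[s, ] <- gp_num[s, ] + pr * es / sum(es)
    }
  }
  gp_num / total
}

# --- brute-force ROH scan: direct loops, no cumulative sums ------------------
brute_roh <- function(pos, gt, window_snp = 100, window_het = 2,
                      window_miss = 1, hit_frac = 0.05, min_snp = 100,
                      min_kb = 10, max_gap_kb = 10) {
  S <- length(pos)
  if (S < window_snp) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snp = integer(0)))
  }
  n_win <- S - window_snp + 1
  win_hom <- logical(n_win)
  for (wst in seq_len(n_win)) {
    idx <- wst:(wst + window_snp - 1)
    n_het <- 0; n_mis <- 0
    for (i in idx) {
      if (is.na(gt[i])) n_mis <- n_mis + 1
      else if (gt[i] == 1) n_het <- n_het + 1
    }
    win_hom[wst] <- n_het <= window_het && n_mis <= window_miss
  }
  in_run <- logical(S)
  for (i in seq_len(S)) {
    n_cov <- 0; n_hom <- 0
    for (wst in seq_len(n_win)) {
      if (wst <= i && i <= wst + window_snp - 1) {
        n_cov <- n_cov + 1
        if (win_hom[wst]) n_hom <- n_hom + 1
      }
    }
    in_run[i] <- n_cov > 0 && n_hom / n_cov >= hit_frac
  }
  segs <- NULL
  i <- 1
  while (i <= S) {
    if (!in_run[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= S && in_run[j + 1] &&
           (pos[j + 1] - pos[j]) <= max_gap_kb * 1000) j <- j + 1
    n <- j - i + 1
    kb <- (pos[j] - pos[i] + 1) / 1000
    if (n >= min_snp && kb >= min_kb) {
      segs <- rbind(segs, data.frame(start = pos[i], end = pos[j],
                                     n_snp = n))
    }
    i <- j + 1
  }
  if (is.null(segs)) {
    segs <- data.frame(start = numeric(0), end = numeric(0),
                       n_snp = integer(0))
  }
  segs
}

# --- Hudson FST estimator (ratio of averages) on a 0/1 haplotype matrix -----
hudson_fst <- function(hap, labels) {
  gs <- unique(labels)
  stopifnot(length(gs) == 2)
  h1 <- hap[labels == gs[1], , drop = FALSE]
  h2 <- hap[labels == gs[2], , drop = FALSE]
  n1 <- nrow(h1); n2 <- nrow(h2)
  p1 <- colMeans(h1); p2 <- colMeans(h2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# random log-GL matrix with some missing rows, for HMM tests
random_gl <- function(S, missing_frac = 0.2) {
  gl <- matrix(log(stats::runif(S * 3, 0.05, 1)), S, 3)
  mis <- stats::runif(S) < missing_frac
  gl[mis, ] <- NA_real_
  gl
}

# small ad-hoc panel around an explicit haplotype matrix
hap_panel <- function(alleles, chrom_length = NULL) {
  K <- nrow(alleles); S <- ncol(alleles)
  if (is.null(chrom_length)) chrom_length <- S * 100
  pos <- round(seq(100, chrom_length, length.out = S))
  structure(list(
    sites = data.frame(chrom = "1", pos = pos, ref = "A", alt = "C",
                       stringsAsFactors = FALSE),
    haplotypes = alleles,
    group_labels = rep("X", K),
    group_freqs = matrix(colMeans(alleles), 1, S,
                         dimnames = list("X", NULL))),
    class = "haplotype_panel")
}

# the switch probabilities impute_ls derives from a uniform 1 cM/Mb map
ls_rho <- function(panel, ne) {
  K <- nrow(panel$haplotypes)
  cm <- map_cm(uniform_map(c("1" = max(panel$sites$pos))),
               panel$sites$chrom, panel$sites$pos)
  c(0, 1 - exp(-4 * ne * diff(cm) / 100 / K))
}
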