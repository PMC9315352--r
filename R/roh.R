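# Runs of homozygosity: sliding-window detector with the plink-style
# parameterization (window SNP count, het/missing allowances, per-SNP hit
# fraction, minimum SNPs/kb, gap splitting) and Table-style class
# statistics per length class.

#' Detect runs of homozygosity
#'
#' Sliding windows of `window_snp` consecutive SNPs are scored homozygous if
#' they contain at most `window_het` heterozygous and `window_miss` missing
#' calls. Each SNP's homozygosity proportion is the fraction of covering
#' windows scored homozygous; SNPs at or above `hit_frac` form candidate
#' runs, which are split where the inter-SNP gap exceeds `max_gap_kb` and
#' retained if they span at least `min_snp` SNPs and `min_kb` kilobases.
#'
#' @param chrom Chromosome id per SNP.
#' @param pos 1-based positions, sorted increasing within chromosome.
#' @param gt Genotypes 0/1/2 (NA missing).
#' @param window_snp Window size in SNPs (default 100).
#' @param window_het Max heterozygous calls per homozygous window (default
#'   2).
#' @param window_miss Max missing calls per homozygous window (default 1).
#' @param hit_frac Per-SNP homozygous-window proportion threshold (default
#'   0.05).
#' @param min_snp Minimum SNPs per run (default 100).
#' @param min_kb Minimum run length in kb (default 10).
#' @param max_gap_kb Split runs at inter-SNP gaps above this (default 10).
#' @return Data frame of `roh_segments`: `chrom`, `start`, `end`, `n_snp`,
#'   `kb`.
#' @export
detect_roh <- function(chrom, pos, gt, window_snp = 100, window_het = 2,
                       window_miss = 1, hit_frac = 0.05, min_snp = 100,
                       min_kb = 10, max_gap_kb = 10) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(gt))
  if (any(window_snp < 1, min_snp < 1, min_kb <= 0, max_gap_kb <= 0)) {
    stop("ROH parameters must be positive")
  }
  segs <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    p <- pos[sel]; g <- gt[sel]
    if (is.unsorted(p, strictly = TRUE)) {
      stop(sprintf("positions not strictly increasing on chromosome %s", ch))
    }
    detect_roh_chrom(ch, p, g, window_snp, window_het, window_miss,
                     hit_frac, min_snp, min_kb, max_gap_kb)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snp = integer(0), kb = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

detect_roh_chrom <- function(ch, pos, gt, w, max_het, max_miss, hit_frac,
                             min_snp, min_kb, max_gap_kb) {
  S <- length(pos)
  if (S < w) return(NULL)
  het <- !is.na(gt) & gt == 1L
  mis <- is.na(gt)
  ch_cum <- c(0, cumsum(het))
  mi_cum <- c(0, cumsum(mis))
  W <- S - w + 1L
  win_ok <- (ch_cum[(1:W) + w] - ch_cum[1:W]) <= max_het &
            (mi_cum[(1:W) + w] - mi_cum[1:W]) <= max_miss
  ok_cum <- c(0, cumsum(win_ok))
  i <- seq_len(S)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(W, i)
  n_cover <- hi - lo + 1L
  n_hom <- ok_cum[hi + 1L] - ok_cum[lo]
  in_run <- n_cover > 0 & n_hom / pmax(n_cover, 1L) >= hit_frac

  # candidate stretches, split at large physical gaps
  brk <- c(0, which(diff(pos) > max_gap_kb * 1000), S)
  out <- NULL
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    # split this stretch at gap breakpoints
    cuts <- brk[brk >= starts[k] & brk < ends[k]]
    bounds <- unique(c(starts[k] - 1L, cuts, ends[k]))
    for (b in seq_len(length(bounds) - 1L)) {
      a <- bounds[b] + 1L; z <- bounds[b + 1L]
      n <- z - a + 1L
      kb <- (pos[z] - pos[a] + 1) / 1000
      if (n >= min_snp && kb >= min_kb) {
        out <- rbind(out, data.frame(chrom = ch, start = pos[a],
                                     end = pos[z], n_snp = n, kb = kb,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' ROH length-class statistics
#'
#' Per length class — 0-0.5 Mb, 0.5-1 Mb, and >1 Mb (boundaries left-closed
#' at 500 and 1,000 kb) — the count of runs, their total length in kb, and
#' Froh, the fraction of the assayed genome covered by runs of that class.
#'
#' @param segments `roh_segments` from [detect_roh()].
#' @param genome_length Total assayed genome length in bp.
#' @return An `roh_report` data frame: `class`, `count`, `sum_kb`, `froh`,
#'   with a `total` attribute row-summing all classes.
#' @export
roh_stats <- function(segments, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  cls <- cut(segments$kb, breaks = c(0, 500, 1000, Inf),
             labels = c("0-0.5", "0.5-1", ">1"), right = FALSE)
  gl_kb <- genome_length / 1000
  out <- data.frame(
    class = c("0-0.5", "0.5-1", ">1"),
    count = as.integer(table(cls)),
    sum_kb = as.numeric(tapply(segments$kb, cls, sum, default = 0)),
    stringsAsFactors = FALSE)
  out$sum_kb[is.na(out$sum_kb)] <- 0
  out$froh <- out$sum_kb / gl_kb
  attr(out, "total") <- c(count = sum(out$count), sum_kb = sum(out$sum_kb),
                          froh = sum(out$froh))
  class(out) <- c("roh_report", "data.frame")
  out
}
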