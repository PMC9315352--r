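#' Haldane mapping function
#'
#' Converts a recombination frequency into a genetic distance under the
#' Haldane (no-interference, Poisson crossover) model:
#' \eqn{d = -50 \ln(1 - 2r)} centimorgans.
#'
#' @param r Numeric vector of recombination frequencies, each in `[0, 0.5)`.
#' @return Genetic distance(s) in centimorgans.
#' @examples
#' haldane_cm(0.1) # 11.157 cM
#' @export
haldane_cm <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("recombination frequency must be finite numeric")
  }
  if (any(r < 0) || any(r >= 0.5)) {
    stop("recombination frequency must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping
#'
#' @param cm Genetic distance(s) in centimorgans, `>= 0`.
#' @return Recombination frequency in `[0, 0.5)`.
#' @export
haldane_r <- function(cm) {
  if (any(cm < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-cm / 50)) / 2
}

#' Build a binned genetic map
#'
#' Builds per-chromosome genetic maps from recombination frequencies estimated
#' in fixed-width physical bins (1 Mb by default). Each bin's frequency is
#' converted to centimorgans with the Haldane formula and accumulated along
#' the chromosome; positions interpolate linearly within a bin.
#'
#' @param bin_r Named list, one numeric vector per chromosome giving the
#'   recombination frequency of each consecutive bin (the final bin may be
#'   partial).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names must match `bin_r`.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return A `genetic_map`: data frame with columns `chrom`, `bin_start`,
#'   `bin_end` (1-based, inclusive), `r`, `cm_len`, `cm_end`.
#' @export
build_map <- function(bin_r, chrom_lengths, bin_size = 1e6) {
  if (!all(names(bin_r) %in% names(chrom_lengths))) {
    stop("every chromosome in bin_r needs a length in chrom_lengths")
  }
  rows <- lapply(names(bin_r), function(ch) {
    len <- chrom_lengths[[ch]]
    n_bins <- ceiling(len / bin_size)
    r <- bin_r[[ch]]
    if (length(r) != n_bins) {
      stop(sprintf("chromosome %s: expected %d bin r values, got %d",
                   ch, n_bins, length(r)))
    }
    start <- (seq_len(n_bins) - 1) * bin_size + 1
    end <- pmin(seq_len(n_bins) * bin_size, len)
    # partial terminal bin contributes length-proportional cM
    cm_full <- haldane_cm(r)
    cm_len <- cm_full * (end - start + 1) / bin_size
    data.frame(chrom = ch, bin_start = start, bin_end = end, r = r,
               cm_len = cm_len, cm_end = cumsum(cm_len),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Uniform-rate genetic map
#'
#' Convenience constructor for a constant cM/Mb map, the default used by the
#' simulators when no pedigree-derived map is supplied.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param cm_per_mb Constant recombination rate (default 1 cM/Mb).
#' @param bin_size Bin width in bp.
#' @return A `genetic_map`.
#' @export
uniform_map <- function(chrom_lengths, cm_per_mb = 1, bin_size = 1e6) {
  r <- haldane_r(cm_per_mb * bin_size / 1e6)
  bin_r <- lapply(chrom_lengths, function(len) {
    rep(r, ceiling(len / bin_size))
  })
  names(bin_r) <- names(chrom_lengths)
  build_map(bin_r, chrom_lengths, bin_size = bin_size)
}

#' Interpolate genetic positions
#'
#' Maps physical positions to cumulative centimorgans, linear within bins.
#' Position 0 (or the first base of the chromosome) maps to 0 cM.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome id (scalar or vector recycled against `pos`).
#' @param pos 1-based physical positions (bp).
#' @return Numeric vector of cM positions.
#' @export
map_cm <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) stop(sprintf("chromosome %s not in map", ch))
    p <- pos[sel]
    if (any(p < 0 | p > max(m$bin_end))) {
      stop(sprintf("position outside chromosome %s", ch))
    }
    idx <- findInterval(pmax(p, 1), m$bin_start)
    frac <- (p - (m$bin_start[idx] - 1)) / (m$bin_end[idx] - m$bin_start[idx] + 1)
    out[sel] <- c(0, m$cm_end)[idx] + frac * m$cm_len[idx]
  }
  out
}

#' Write a genetic map in plink .map dialect
#'
#' One row per bin end: chromosome, marker id, cumulative cM, bp.
#'
#' @param map A `genetic_map`.
#' @param file Output path.
#' @export
write_plink_map <- function(map, file) {
  id <- sprintf("%s_bin%d", map$chrom,
                stats::ave(seq_len(nrow(map)), map$chrom, FUN = seq_along))
  lines <- sprintf("%s\t%s\t%.10g\t%d", map$chrom, id, map$cm_end, map$bin_end)
  writeLines(lines, file)
  invisible(file)
}

#' Read a plink-dialect genetic map written by [write_plink_map()]
#'
#' @param file Path to a four-column plink .map file (chrom, id, cM, bp).
#' @param bin_size Bin width used when the map was built.
#' @return A `genetic_map`.
#' @export
read_plink_map <- function(file, bin_size = 1e6) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "id", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  rows <- lapply(split(tab, tab$chrom), function(x) {
    x <- x[order(x$bp), , drop = FALSE]
    cm_len <- diff(c(0, x$cm))
    start <- c(1, utils::head(x$bp, -1) + 1)
    width <- x$bp - start + 1
    # undo the partial-bin proration before inverting Haldane
    r <- haldane_r(cm_len * bin_size / width)
    data.frame(chrom = x$chrom, bin_start = start, bin_end = x$bp, r = r,
               cm_len = cm_len, cm_end = x$cm, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}
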