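#' Derived-allele frequencies for a four-taxon quartet
#'
#' Builds the per-site frequency table (p1, p2, p3, p4) for taxa ordered
#' (P1, P2, P3, Outgroup). Frequencies are alternate-allele sample
#' frequencies; the outgroup frequency p4 is used directly (sites where the
#' outgroup is polymorphic contribute with weight 1 - p4). Sites need at
#' least \code{min_alleles} called allele copies in every taxon.
#'
#' @param matrix a \code{geno_matrix}.
#' @param pops character vector of four population labels (P1, P2, P3, O).
#' @param popmap a \code{pop_map}.
#' @param idx optional site indices (default all sites).
#' @param min_alleles minimum called allele copies per taxon (default 2).
#' @return data.frame with chrom, pos, p1, p2, p3, p4.
#' @export
quartet_frequencies <- function(matrix, pops, popmap, idx = NULL,
                                min_alleles = 2L) {
  stopifnot(length(pops) == 4L)
  if (is.null(idx)) idx <- seq_len(n_sites(matrix))
  cts <- lapply(pops, function(p) .pop_counts(matrix, idx, p, popmap))
  use <- Reduce(`&`, lapply(cts, function(ct) ct$n >= min_alleles))
  p <- lapply(cts, function(ct) (ct$k / ct$n)[use])
  data.frame(chrom = matrix$chrom[idx][use], pos = matrix$pos[idx][use],
             p1 = p[[1]], p2 = p[[2]], p3 = p[[3]], p4 = p[[4]],
             stringsAsFactors = FALSE)
}

#' Frequency-weighted ABBA and BABA site-pattern sums
#'
#' abba = sum (1-p1) p2 p3 (1-p4); baba = sum p1 (1-p2) p3 (1-p4). On
#' binary (0/1) frequencies these reduce to literal pattern counts.
#'
#' @param qf data.frame with columns p1..p4 (as from
#'   \code{\link{quartet_frequencies}}).
#' @return numeric vector \code{c(abba, baba)}; \code{c(0, 0)} for empty
#'   input.
#' @export
site_pattern_sums <- function(qf) {
  if (nrow(qf) == 0L) return(c(abba = 0, baba = 0))
  c(abba = sum((1 - qf$p1) * qf$p2 * qf$p3 * (1 - qf$p4)),
    baba = sum(qf$p1 * (1 - qf$p2) * qf$p3 * (1 - qf$p4)))
}

#' Patterson's D from ABBA/BABA sums
#'
#' @param abba_sum,baba_sum non-negative pattern sums.
#' @return D = (abba - baba) / (abba + baba), or \code{NA} when the sums
#'   are both zero.
#' @export
patterson_d <- function(abba_sum, baba_sum) {
  tot <- abba_sum + baba_sum
  if (tot == 0) return(NA_real_)
  (abba_sum - baba_sum) / tot
}

#' Window-scale admixture-fraction estimator f_d
#'
#' The ABBA-BABA numerator normalised by its value under complete sharing:
#' in the denominator both P2 and P3 are replaced per site by the donor
#' proxy, whichever of the two has the larger derived frequency at that
#' site. Negative values are clamped to 0 (excess sharing with P1 carries
#' no admixture interpretation here); \code{NA} when the denominator is 0.
#'
#' @param qf data.frame of quartet frequencies for the window's sites.
#' @return f_d in [0, 1] (up to sampling noise above 1), or \code{NA}.
#' @export
fd_window <- function(qf) {
  if (nrow(qf) == 0L) return(NA_real_)
  num <- sum((1 - qf$p1) * qf$p2 * qf$p3 * (1 - qf$p4) -
               qf$p1 * (1 - qf$p2) * qf$p3 * (1 - qf$p4))
  pd <- pmax(qf$p2, qf$p3)
  den <- sum((1 - qf$p1) * pd * pd * (1 - qf$p4) -
               qf$p1 * (1 - pd) * pd * (1 - qf$p4))
  if (den == 0) return(NA_real_)
  max(0, num / den)
}

#' Windowed ABBA-BABA scan
#'
#' Per-window ABBA/BABA sums, Patterson's D and f_d for a quartet
#' (P1, P2, P3, O) over tiling windows.
#'
#' @inheritParams quartet_frequencies
#' @param size window size in bp.
#' @param step optional step in bp.
#' @return data.frame: chrom, start, end, n_sites, abba, baba, D, fd.
#' @export
introgression_scan <- function(matrix, pops, popmap, size, step = NULL,
                               min_alleles = 2L) {
  wins <- iter_windows(matrix, size, step)
  rows <- lapply(wins, function(w) {
    qf <- quartet_frequencies(matrix, pops, popmap, idx = w$idx,
                              min_alleles = min_alleles)
    ss <- site_pattern_sums(qf)
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               n_sites = nrow(qf), abba = ss[["abba"]],
               baba = ss[["baba"]],
               D = patterson_d(ss[["abba"]], ss[["baba"]]),
               fd = fd_window(qf), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Block-jackknife mean and standard deviation of a ratio statistic
#'
#' Partitions the per-unit paired sums (e.g. per-window ABBA and BABA) into
#' \code{n_blocks} contiguous, equal-count blocks; each pseudo-estimate
#' drops one block (with 20 blocks each pseudo-replicate keeps 95\% of the
#' data). The point estimate is the statistic on the full sums; the
#' jackknife standard deviation is
#' sqrt(((m-1)/m) * sum_j (theta_(-j) - mean(theta_(-.)))^2).
#'
#' @param x,y numeric vectors of per-unit numerator-component and
#'   denominator-component sums (for Patterson's D: abba and baba per
#'   window).
#' @param n_blocks number of blocks (default 20; must be >= 2 and <=
#'   length(x)).
#' @param statistic function of (sum_x, sum_y) returning the scalar
#'   statistic; default Patterson's D.
#' @return list: mean, sd, n_blocks, z (mean/sd, \code{NA} when sd = 0).
#' @export
block_jackknife <- function(x, y, n_blocks = 20L,
                            statistic = patterson_d) {
  m <- as.integer(n_blocks)
  if (m < 2L) stop("need at least 2 jackknife blocks")
  if (length(x) != length(y)) stop("x and y must be the same length")
  if (length(x) < m) stop("fewer units than blocks")
  blk <- sort(rep_len(seq_len(m), length(x)))
  sx <- sum(x); sy <- sum(y)
  full <- statistic(sx, sy)
  bx <- tapply(x, blk, sum); by <- tapply(y, blk, sum)
  loo <- vapply(seq_len(m), function(j)
    statistic(sx - bx[[j]], sy - by[[j]]), 0)
  sd_j <- sqrt(((m - 1) / m) * sum((loo - mean(loo))^2))
  list(mean = full, sd = sd_j, n_blocks = m,
       z = if (sd_j > 0) full / sd_j else NA_real_)
}

#' Date introgression from the divergence ratio
#'
#' The divergence of the introgressed haplotypes from the donor, relative
#' to the genome-wide donor divergence, approximates the fraction of the
#' total divergence time at which the haplotypes last shared an ancestor.
#'
#' @param d_focal per-site divergence in the focal (introgressed) region.
#' @param d_genomewide per-site genome-wide divergence (> 0).
#' @param t_div optional total divergence time (e.g. in Myr).
#' @return list: \code{ratio} = d_focal / d_genomewide, and \code{t_intro}
#'   = ratio * t_div when \code{t_div} is supplied (otherwise \code{NA}).
#' @export
divergence_ratio_timing <- function(d_focal, d_genomewide, t_div = NULL) {
  if (d_genomewide <= 0) stop("genome-wide divergence must be positive")
  ratio <- d_focal / d_genomewide
  list(ratio = ratio,
       t_intro = if (is.null(t_div)) NA_real_ else ratio * t_div)
}

#' Detect outlier peaks in a windowed statistic
#'
#' Windows whose robust z-score (median/MAD-based; falls back to mean/SD
#' with a warning when the MAD is zero) reaches \code{z_threshold} are
#' flagged; flagged windows separated by at most \code{merge_gap}
#' unflagged windows are merged into intervals.
#'
#' @param values numeric vector of per-window statistic values (\code{NA}
#'   allowed; never flagged).
#' @param z_threshold robust z-score threshold (default 4).
#' @param merge_gap maximum unflagged windows bridged when merging
#'   (default 0).
#' @return data.frame of intervals: start_idx, end_idx, peak_idx (window
#'   with the maximum statistic), peak_value, n_windows.
#' @export
scan_peaks <- function(values, z_threshold = 4, merge_gap = 0L) {
  if (sum(!is.na(values)) < 2L) stop("need at least 2 defined values")
  med <- stats::median(values, na.rm = TRUE)
  madv <- stats::mad(values, na.rm = TRUE)
  if (madv == 0) {
    warning("MAD is zero; falling back to mean/SD z-scores")
    mu <- mean(values, na.rm = TRUE)
    sdv <- stats::sd(values, na.rm = TRUE)
    if (sdv == 0) return(data.frame(start_idx = integer(0),
                                    end_idx = integer(0),
                                    peak_idx = integer(0),
                                    peak_value = numeric(0),
                                    n_windows = integer(0)))
    z <- (values - mu) / sdv
  } else {
    z <- (values - med) / madv
  }
  flagged <- which(!is.na(z) & z >= z_threshold)
  if (length(flagged) == 0L)
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      peak_idx = integer(0), peak_value = numeric(0),
                      n_windows = integer(0)))
  grp <- cumsum(c(1L, diff(flagged) > merge_gap + 1L))
  out <- lapply(split(flagged, grp), function(ix) {
    span <- seq.int(min(ix), max(ix))
    pk <- span[which.max(values[span])]
    data.frame(start_idx = min(ix), end_idx = max(ix), peak_idx = pk,
               peak_value = values[pk], n_windows = length(span))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
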