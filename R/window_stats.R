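#' Per-population called/alt allele counts for a set of sites
#'
#' Internal workhorse: returns, for each site row, the number of called
#' allele copies and the alternate (or derived) allele count within one
#' population.
#' @noRd
.pop_counts <- function(matrix, idx, population, popmap) {
  samp <- intersect(pop_samples(popmap, population), matrix$samples)
  if (length(samp) == 0L)
    stop("population has no samples in the matrix: ", population)
  g <- matrix$geno[idx, samp, drop = FALSE]
  list(n = 2L * rowSums(!is.na(g)),
       k = rowSums(g, na.rm = TRUE),
       n_ind = rowSums(!is.na(g)),
       het = rowSums(g == 1L, na.rm = TRUE))
}

#' Nucleotide diversity in a window
#'
#' Per-site heterozygosity summed over sites and divided by a fixed
#' denominator (by default the window length in bp, so monomorphic and
#' uncalled positions count as zero difference). Each site contributes
#' 2k(n-k)/(n(n-1)) where n is the number of called allele copies and k the
#' alternate-allele count in the population; sites with n < 4 are skipped.
#'
#' @param matrix a \code{geno_matrix}.
#' @param idx integer site indices (the window's sites).
#' @param population population label.
#' @param popmap a \code{pop_map}.
#' @param denominator_bp positive integer divisor, normally the window
#'   length.
#' @param min_alleles minimum called allele copies for a site to count
#'   (default 4).
#' @return per-site nucleotide diversity (dimensionless, per bp).
#' @export
pi_window <- function(matrix, idx, population, popmap, denominator_bp,
                      min_alleles = 4L) {
  stopifnot(denominator_bp >= 1)
  if (length(idx) == 0L) return(0)
  ct <- .pop_counts(matrix, idx, population, popmap)
  use <- ct$n >= min_alleles
  n <- ct$n[use]; k <- ct$k[use]
  sum(2 * k * (n - k) / (n * (n - 1))) / denominator_bp
}

#' Tajima's D denominator constants
#'
#' The classical constants for a sample of \code{n} allele copies:
#' a1, a2, b1, b2, c1, c2, e1, e2.
#'
#' @param n number of sampled allele copies (>= 4 for a usable variance).
#' @return named list of the eight constants plus \code{n}.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D for a window
#'
#' Uses only sites at which every genotype in the focal population is
#' called (the classical statistic assumes a constant sample size), with
#' n = 2 x population samples. Returns \code{NA} when there are no
#' segregating sites or n < 4.
#'
#' @inheritParams pi_window
#' @return Tajima's D, or \code{NA} when undefined.
#' @export
tajimas_d <- function(matrix, idx, population, popmap) {
  samp <- intersect(pop_samples(popmap, population), matrix$samples)
  n <- 2L * length(samp)
  if (n < 4L) {
    warning("fewer than 4 allele copies in population; D undefined")
    return(NA_real_)
  }
  if (length(idx) == 0L) return(NA_real_)
  g <- matrix$geno[idx, samp, drop = FALSE]
  full <- rowSums(is.na(g)) == 0L
  k <- rowSums(g[full, , drop = FALSE])
  seg <- k > 0L & k < n
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  kk <- k[seg]
  pi_sum <- sum(2 * kk * (n - kk) / (n * (n - 1)))
  cst <- tajima_constants(n)
  theta_w <- S / cst$a1
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  (pi_sum - theta_w) / denom
}

#' Weir-Cockerham variance components and weighted F_ST for a window
#'
#' Two-population (r = 2) variance-components estimator. Per site, with
#' per-population sample sizes n_i (called individuals), allele frequencies
#' p_i and observed heterozygote proportions h_i, the among-population (a),
#' among-individual (b) and within-individual (c) components are computed
#' and the weighted window estimate is sum(a) / sum(a + b + c). Sites
#' require at least \code{min_ind} called individuals in each population.
#'
#' @param matrix a \code{geno_matrix}.
#' @param idx site indices in the window.
#' @param popA,popB distinct population labels.
#' @param popmap a \code{pop_map}.
#' @param min_ind minimum called diploid individuals per population per
#'   site (default 2).
#' @return list with per-site component vectors \code{a}, \code{b},
#'   \code{c}, the weighted estimate \code{fst} (\code{NA} when the
#'   component sum is zero) and \code{n_sites_used}.
#' @export
weir_cockerham_fst <- function(matrix, idx, popA, popB, popmap,
                               min_ind = 2L) {
  if (identical(popA, popB)) stop("population labels must differ")
  if (length(idx) == 0L)
    return(list(a = numeric(0), b = numeric(0), c = numeric(0),
                fst = NA_real_, n_sites_used = 0L))
  cA <- .pop_counts(matrix, idx, popA, popmap)
  cB <- .pop_counts(matrix, idx, popB, popmap)
  use <- cA$n_ind >= min_ind & cB$n_ind >= min_ind
  if (!any(use))
    return(list(a = numeric(0), b = numeric(0), c = numeric(0),
                fst = NA_real_, n_sites_used = 0L))
  n1 <- cA$n_ind[use]; n2 <- cB$n_ind[use]
  p1 <- cA$k[use] / (2 * n1); p2 <- cB$k[use] / (2 * n2)
  h1 <- cA$het[use] / n1; h2 <- cB$het[use] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- sum(a + b + cc)
  fst <- if (tot == 0) NA_real_ else sum(a) / tot
  list(a = a, b = b, c = cc, fst = fst, n_sites_used = sum(use))
}

#' Absolute divergence d_xy in a window
#'
#' d_xy = sum over sites of pA(1-pB) + pB(1-pA), divided by a fixed
#' denominator (normally window length). Sites need at least
#' \code{min_alleles} called allele copies in each population.
#'
#' @inheritParams weir_cockerham_fst
#' @param denominator_bp positive divisor in bp.
#' @param min_alleles minimum called allele copies per population (default
#'   4).
#' @return per-site absolute divergence.
#' @export
dxy_window <- function(matrix, idx, popA, popB, popmap, denominator_bp,
                       min_alleles = 4L) {
  if (identical(popA, popB)) stop("population labels must differ")
  stopifnot(denominator_bp >= 1)
  if (length(idx) == 0L) return(0)
  cA <- .pop_counts(matrix, idx, popA, popmap)
  cB <- .pop_counts(matrix, idx, popB, popmap)
  use <- cA$n >= min_alleles & cB$n >= min_alleles
  pA <- cA$k[use] / cA$n[use]
  pB <- cB$k[use] / cB$n[use]
  sum(pA * (1 - pB) + pB * (1 - pA)) / denominator_bp
}

#' Windowed scan of diversity and differentiation statistics
#'
#' Computes per-window nucleotide diversity and Tajima's D for each
#' requested population, and Weir-Cockerham F_ST and d_xy for each
#' requested population pair, over tiling (or sliding) windows.
#'
#' @param matrix a \code{geno_matrix}.
#' @param popmap a \code{pop_map}.
#' @param size window size in bp.
#' @param step optional step in bp (absent = non-overlapping).
#' @param populations character vector of population labels for pi / D.
#' @param pairs optional list of 2-vectors of labels for F_ST / d_xy.
#' @return a data.frame with one row per window: chrom, start, end,
#'   n_sites, S (segregating sites over all samples), then
#'   \code{pi_<pop>}, \code{tajD_<pop>}, \code{fst_<A>_<B>},
#'   \code{dxy_<A>_<B>} columns; missing values are \code{NA}. Rows are
#'   ordered by (chrom, start).
#' @export
windowed_scan <- function(matrix, popmap, size, step = NULL,
                          populations = character(0), pairs = list()) {
  wins <- iter_windows(matrix, size, step)
  nw <- length(wins)
  res <- data.frame(chrom = vapply(wins, `[[`, "", "chrom"),
                    start = vapply(wins, `[[`, 0L, "start"),
                    end = vapply(wins, `[[`, 0L, "end"),
                    n_sites = vapply(wins, function(w) length(w$idx), 0L),
                    stringsAsFactors = FALSE)
  res$S <- vapply(wins, function(w) {
    if (length(w$idx) == 0L) return(0L)
    k <- rowSums(matrix$geno[w$idx, , drop = FALSE], na.rm = TRUE)
    n <- 2L * rowSums(!is.na(matrix$geno[w$idx, , drop = FALSE]))
    sum(k > 0L & k < n)
  }, 0L)
  for (p in populations) {
    res[[paste0("pi_", p)]] <- vapply(wins, function(w)
      pi_window(matrix, w$idx, p, popmap, size), 0)
    res[[paste0("tajD_", p)]] <- vapply(wins, function(w)
      suppressWarnings(tajimas_d(matrix, w$idx, p, popmap)), 0)
  }
  for (pr in pairs) {
    tagf <- paste0("fst_", pr[1], "_", pr[2])
    tagd <- paste0("dxy_", pr[1], "_", pr[2])
    res[[tagf]] <- vapply(wins, function(w)
      weir_cockerham_fst(matrix, w$idx, pr[1], pr[2], popmap)$fst, 0)
    res[[tagd]] <- vapply(wins, function(w)
      dxy_window(matrix, w$idx, pr[1], pr[2], popmap, size), 0)
  }
  res[order(res$chrom, res$start), , drop = FALSE]
}
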