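# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive enumeration, never the package's own formulas.

# mean pairwise difference over all allele pairs at each site, summed;
# alleles expanded explicitly from dosages
oracle_pi_sum <- function(geno_rows) {
  tot <- 0
  for (r in seq_len(nrow(geno_rows))) {
    g <- geno_rows[r, ]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 4) next
    diff <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      diff <- diff + (alleles[i] != alleles[j])
    tot <- tot + diff / choose(n, 2)
  }
  unname(tot)
}

# literal ABBA/BABA pattern counting on haploid binary data
oracle_pattern_counts <- function(b1, b2, b3, b4) {
  abba <- sum(b1 == 0 & b2 == 1 & b3 == 1 & b4 == 0)
  baba <- sum(b1 == 1 & b2 == 0 & b3 == 1 & b4 == 0)
  c(abba = abba, baba = baba)
}

# direct scalar evaluation of the two-population Weir-Cockerham
# variance components at one site
oracle_wc_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                           hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# independent Tajima's D evaluation from first principles
oracle_tajimas_d <- function(k, n) {
  k <- k[k > 0 & k < n]
  S <- length(k)
  if (S == 0) return(NA_real_)
  pi_sum <- sum(2 * k * (n - k) / (n * (n - 1)))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# a small two-population toy matrix with reproducible random dosages
toy_matrix <- function(n_sites = 12, n_per_pop = 3, seed = 42,
                       miss_prob = 0) {
  set.seed(seed)
  ns <- 2 * n_per_pop
  geno <- matrix(sample(0:2, n_sites * ns, replace = TRUE), n_sites, ns)
  if (miss_prob > 0)
    geno[runif(length(geno)) < miss_prob] <- NA_integer_
  samples <- c(paste0("a", seq_len(n_per_pop)),
               paste0("b", seq_len(n_per_pop)))
  list(matrix = geno_matrix(rep("chr1", n_sites),
                            seq(100, by = 100, length.out = n_sites),
                            rep("A", n_sites), rep("T", n_sites),
                            geno, samples),
       popmap = pop_map(samples, rep(c("popA", "popB"),
                                     each = n_per_pop)))
}

# write a small VCF from raw text lines
write_vcf_fixture <- function(body_lines, samples = c("s1", "s2"),
                              format = "GT") {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}
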