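#' Construct a genotype matrix object
#'
#' The central data container: diploid biallelic genotypes encoded as
#' alternate-allele dosages (0, 1, 2 or \code{NA} for missing) for a set of
#' sites (rows) by samples (columns), together with site coordinates and
#' alleles. Sites must be unique on (chrom, pos) and are stored sorted by
#' chromosome then position.
#'
#' @param chrom character vector of sequence identifiers, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference / alternate alleles per site.
#' @param geno integer matrix, sites x samples, entries in \{0,1,2,NA\}.
#' @param samples character vector of sample identifiers (column names).
#' @param gq optional numeric matrix of genotype qualities, same shape as
#'   \code{geno}.
#' @param annotation optional character vector of per-site effect labels.
#' @return an object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(chrom, pos, ref, alt, geno, samples,
                        gq = NULL, annotation = NULL) {
  n_sites <- length(chrom)
  stopifnot(length(pos) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites)
  geno <- as.matrix(geno)
  if (n_sites == 0L) geno <- matrix(integer(0), 0L, length(samples))
  if (nrow(geno) != n_sites)
    stop("genotype matrix must have one row per site")
  if (ncol(geno) != length(samples))
    stop("genotype vector length must equal sample count at every site")
  if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(paste(chrom, pos))) stop("(chrom, pos) must be unique")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    stopifnot(all(dim(gq) == dim(geno)))
  }
  if (!is.null(annotation)) stopifnot(length(annotation) == n_sites)
  ord <- order(chrom, pos)
  storage.mode(geno) <- "integer"
  colnames(geno) <- samples
  obj <- structure(list(
    chrom = as.character(chrom)[ord],
    pos = as.integer(pos)[ord],
    ref = as.character(ref)[ord],
    alt = as.character(alt)[ord],
    geno = geno[ord, , drop = FALSE],
    gq = if (is.null(gq)) NULL else gq[ord, , drop = FALSE],
    annotation = if (is.null(annotation)) NULL else
      as.character(annotation)[ord],
    samples = as.character(samples)
  ), class = "geno_matrix")
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples (%d chromosome(s))\n",
              n_sites(x), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param matrix a \code{geno_matrix}.
#' @return integer site count.
#' @export
n_sites <- function(matrix) length(matrix$pos)

#' Subset a genotype matrix by site index
#' @param matrix a \code{geno_matrix}.
#' @param idx integer indices of sites to keep.
#' @return a \code{geno_matrix} with the selected sites, order preserved.
#' @export
subset_sites <- function(matrix, idx) {
  geno_matrix(matrix$chrom[idx], matrix$pos[idx], matrix$ref[idx],
              matrix$alt[idx], matrix$geno[idx, , drop = FALSE],
              matrix$samples,
              gq = if (is.null(matrix$gq)) NULL else
                matrix$gq[idx, , drop = FALSE],
              annotation = if (is.null(matrix$annotation)) NULL else
                matrix$annotation[idx])
}

.valid_snp_allele <- function(x) x %in% c("A", "C", "G", "T")

#' Read a multi-sample VCF into a genotype matrix
#'
#' Retains only biallelic SNP records: one single-nucleotide REF, one
#' single-nucleotide ALT (multi-allelic, indel and symbolic records are
#' dropped and counted). Dosages are decoded from GT; phased (\code{|}) and
#' unphased (\code{/}) separators are treated identically, and half-calls
#' such as \code{./1} become missing. GQ is read when present.
#'
#' @param path VCF file (plain or gzip/bgzip compressed), v4.x with GT.
#' @param sample_subset optional character vector of samples to keep;
#'   samples absent from the header are an error.
#' @return a \code{geno_matrix}; the number of non-SNP/multi-allelic records
#'   dropped is attached as attribute \code{"n_dropped"}.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L || !startsWith(first, "##fileformat"))
    stop("not a VCF: first line must be a ##fileformat header")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  all_samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, all_samples)
    if (length(missing_s) > 0)
      stop("sample(s) not in VCF header: ",
           paste(missing_s, collapse = ", "))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & .valid_snp_allele(ref) & .valid_snp_allele(alt)
  n_dropped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  # dosage = number of "1" allele calls; any missing allele -> NA
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
  gq <- NULL
  if (any(grepl("GQ", v@gt[, "FORMAT"]))) {
    gq <- suppressWarnings(
      vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    if (is.null(dim(gq))) gq <- matrix(gq, nrow = nrow(fix))
  }
  cols <- if (is.null(sample_subset)) all_samples else sample_subset
  ci <- match(cols, all_samples)
  m <- geno_matrix(chrom = fix[keep, "CHROM"],
                   pos = as.integer(fix[keep, "POS"]),
                   ref = ref[keep], alt = alt[keep],
                   geno = dos[keep, ci, drop = FALSE],
                   samples = cols,
                   gq = if (is.null(gq)) NULL else
                     gq[keep, ci, drop = FALSE])
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal biallelic-SNP VCF (GT only, or GT:GQ when qualities are
#' present) that round-trips through \code{\link{read_vcf}}.
#'
#' @param matrix a \code{geno_matrix}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_vcf <- function(matrix, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popgenscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_gq <- !is.null(matrix$gq)
  if (has_gq)
    hdr <- c(hdr, paste0('##FORMAT=<ID=GQ,Number=1,Type=Integer,',
                         'Description="Genotype quality">'))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", matrix$samples),
                      collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[matrix$geno + 1L],
                   nrow = n_sites(matrix))
  gt_str[is.na(matrix$geno)] <- "./."
  if (has_gq) {
    gqv <- ifelse(is.na(matrix$gq), ".",
                  format(matrix$gq, trim = TRUE, scientific = FALSE))
    gt_str <- matrix(paste(gt_str, gqv, sep = ":"),
                     nrow = n_sites(matrix))
  }
  body <- character(0)
  if (n_sites(matrix) > 0) {
    body <- paste(matrix$chrom, matrix$pos, ".", matrix$ref, matrix$alt,
                  ".", "PASS", ".", if (has_gq) "GT:GQ" else "GT",
                  apply(gt_str, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter sites by genotype quality, missingness and minor allele frequency
#'
#' Genotype-level quality masking is applied first (calls with GQ below
#' \code{min_gq} become missing), then site-level filters: sites whose
#' missing-call fraction exceeds \code{max_missing_fraction}, or whose minor
#' allele frequency (computed on called alleles) is below \code{min_maf},
#' are removed. Site order is preserved. An empty result is permitted (with
#' a warning), not an error.
#'
#' @param matrix a \code{geno_matrix}.
#' @param min_gq optional genotype-quality threshold (calls below it are
#'   set to missing).
#' @param max_missing_fraction maximum fraction of missing genotypes per
#'   site, in [0, 1].
#' @param min_maf minimum minor allele frequency, in [0, 0.5].
#' @return a filtered \code{geno_matrix}.
#' @export
filter_sites <- function(matrix, min_gq = NULL, max_missing_fraction = 1,
                         min_maf = 0) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 0.5)
  geno <- matrix$geno
  if (!is.null(min_gq)) {
    if (is.null(matrix$gq))
      stop("min_gq given but the matrix carries no genotype qualities")
    geno[!is.na(matrix$gq) & matrix$gq < min_gq] <- NA_integer_
    geno[is.na(matrix$gq)] <- NA_integer_
  }
  ns <- n_sites(matrix)
  if (ns == 0L) return(matrix)
  miss_frac <- rowMeans(is.na(geno))
  called <- 2L * rowSums(!is.na(geno))
  altc <- rowSums(geno, na.rm = TRUE)
  af <- ifelse(called > 0, altc / called, NA_real_)
  maf <- pmin(af, 1 - af)
  keep <- miss_frac <= max_missing_fraction &
    (min_maf == 0 | (!is.na(maf) & maf >= min_maf))
  keep[is.na(keep)] <- FALSE
  out <- geno_matrix(matrix$chrom[keep], matrix$pos[keep],
                     matrix$ref[keep], matrix$alt[keep],
                     geno[keep, , drop = FALSE], matrix$samples,
                     gq = if (is.null(matrix$gq)) NULL else
                       matrix$gq[keep, , drop = FALSE],
                     annotation = if (is.null(matrix$annotation)) NULL else
                       matrix$annotation[keep])
  if (n_sites(out) == 0L) warning("all sites removed by filters")
  out
}

#' Called-allele and alternate-allele counts in one population at one site
#'
#' @param matrix a \code{geno_matrix}.
#' @param site_idx site row index.
#' @param population population label.
#' @param popmap a \code{pop_map}.
#' @return integer vector \code{c(called_alleles, alt_count)}:
#'   2 x non-missing genotypes, and the sum of dosages.
#' @export
allele_counts <- function(matrix, site_idx, population, popmap) {
  samp <- pop_samples(popmap, population)
  samp <- intersect(samp, matrix$samples)
  if (length(samp) == 0L)
    stop("population has no samples in the matrix: ", population)
  g <- matrix$geno[site_idx, samp]
  c(called_alleles = 2L * sum(!is.na(g)),
    alt_count = as.integer(sum(g, na.rm = TRUE)))
}

#' Tile a genotype matrix into genomic windows
#'
#' Windows tile each chromosome from position 1; 1-based inclusive
#' coordinates. With no \code{step} (or \code{step == size}) windows are
#' non-overlapping \code{[k*size+1, (k+1)*size]}; with a smaller step they
#' slide with starts \code{1, step+1, 2*step+1, ...}. Empty windows are
#' yielded (required for length-normalised diversity). A site at position p
#' belongs to every window whose span covers p.
#'
#' @param matrix a \code{geno_matrix}.
#' @param size window length in bp (>= 1).
#' @param step optional step in bp; must satisfy 1 <= step <= size.
#' @return a list of windows, each a list with \code{chrom}, \code{start},
#'   \code{end}, \code{length}, and \code{idx} (site row indices).
#' @export
iter_windows <- function(matrix, size, step = NULL) {
  stopifnot(size >= 1)
  if (is.null(step)) step <- size
  if (step == 0) stop("step must be >= 1")
  if (step > size) stop("step must be <= size")
  out <- list()
  for (chr in unique(matrix$chrom)) {
    in_chr <- which(matrix$chrom == chr)
    maxp <- if (length(in_chr)) max(matrix$pos[in_chr]) else size
    starts <- seq.int(1L, maxp, by = step)
    # drop sliding starts whose window begins past the last site
    for (s in starts) {
      e <- s + size - 1L
      idx <- in_chr[matrix$pos[in_chr] >= s & matrix$pos[in_chr] <= e]
      out[[length(out) + 1L]] <- list(chrom = chr, start = as.integer(s),
                                      end = as.integer(e),
                                      length = as.integer(size), idx = idx)
    }
  }
  out
}

#' Construct a population map
#'
#' @param sample character vector of sample identifiers.
#' @param population parallel vector of population labels.
#' @param lat,lon optional parallel numeric coordinate vectors (degrees).
#' @return an object of class \code{pop_map}.
#' @export
pop_map <- function(sample, population, lat = NULL, lon = NULL) {
  stopifnot(length(sample) == length(population))
  if (anyDuplicated(sample)) stop("duplicate sample identifiers")
  if (!is.null(lat)) {
    stopifnot(length(lat) == length(sample), length(lon) == length(sample))
    if (any(!is.na(lat) & (lat < -90 | lat > 90)))
      stop("latitude outside [-90, 90]")
    if (any(!is.na(lon) & (lon < -180 | lon > 180)))
      stop("longitude outside [-180, 180]")
  }
  structure(list(sample = as.character(sample),
                 population = as.character(population),
                 lat = lat, lon = lon),
            class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  cat(sprintf("pop_map: %d samples, %d populations%s\n",
              length(x$sample), length(unique(x$population)),
              if (is.null(x$lat)) "" else ", with coordinates"))
  invisible(x)
}

#' Samples belonging to a population
#' @param popmap a \code{pop_map}.
#' @param population population label.
#' @return character vector of sample identifiers.
#' @export
pop_samples <- function(popmap, population) {
  s <- popmap$sample[popmap$population == population]
  if (length(s) == 0L) stop("unknown or empty population: ", population)
  s
}

#' Read a population map TSV
#'
#' Expects a header line \code{sample<TAB>population[<TAB>lat<TAB>lon]}.
#'
#' @param path tab-separated file path.
#' @return a \code{pop_map}.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(df)))
    stop("popmap must have 'sample' and 'population' columns")
  has_coord <- all(c("lat", "lon") %in% names(df))
  pop_map(df$sample, df$population,
          lat = if (has_coord) as.numeric(df$lat) else NULL,
          lon = if (has_coord) as.numeric(df$lon) else NULL)
}

#' Write a population map TSV
#' @param popmap a \code{pop_map}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_popmap <- function(popmap, path) {
  df <- data.frame(sample = popmap$sample, population = popmap$population)
  if (!is.null(popmap$lat)) { df$lat <- popmap$lat; df$lon <- popmap$lon }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
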