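#' Effect-label vocabulary
#'
#' Annotation labels counted as neutral or deleterious when classifying
#' derived variants; anything else is excluded from the load analysis.
#' @name effect_classes
#' @keywords internal
NULL

.NEUTRAL_LABELS <- c("synonymous_variant", "intron_variant", "NONE")
.DELETERIOUS_LABELS <- c("missense_variant", "start_lost", "stop_gained")

#' Classify a functional-effect annotation
#'
#' Exact, case-sensitive membership: synonymous_variant, intron_variant and
#' NONE are neutral; missense_variant, start_lost and stop_gained are
#' deleterious; every other label is excluded.
#'
#' @param annotation character vector of effect labels.
#' @return character vector over \{"neutral", "deleterious", "excluded"\}.
#' @export
classify_effect <- function(annotation) {
  out <- rep("excluded", length(annotation))
  out[annotation %in% .NEUTRAL_LABELS] <- "neutral"
  out[annotation %in% .DELETERIOUS_LABELS] <- "deleterious"
  out
}

#' Polarize sites by outgroup majority
#'
#' A site's ancestral allele is assigned only when every outgroup sample is
#' called there AND a strict majority of the outgroup allele copies agree;
#' exact ties and sites with any missing outgroup genotype stay
#' unassigned.
#'
#' @param matrix a \code{geno_matrix}.
#' @param outgroup_samples sample identifiers used for polarization.
#' @return character vector, one per site: \code{"ref"}, \code{"alt"} or
#'   \code{NA} (unassigned).
#' @export
polarize <- function(matrix, outgroup_samples) {
  missing_s <- setdiff(outgroup_samples, matrix$samples)
  if (length(missing_s) > 0)
    stop("outgroup sample(s) not in matrix: ",
         paste(missing_s, collapse = ", "))
  g <- matrix$geno[, outgroup_samples, drop = FALSE]
  all_called <- rowSums(is.na(g)) == 0L
  n_copies <- 2L * length(outgroup_samples)
  alt_copies <- rowSums(g)
  anc <- rep(NA_character_, n_sites(matrix))
  anc[all_called & alt_copies > n_copies / 2] <- "alt"
  anc[all_called & alt_copies < n_copies / 2] <- "ref"
  anc
}

#' Per-population derived-allele counts at polarized sites
#'
#' For each polarizable site, the number of called allele copies and the
#' derived-allele count in the focal population. Where the ancestral allele
#' is the alternate, the derived count is the reference count.
#'
#' @param matrix a \code{geno_matrix}.
#' @param ancestral character vector from \code{\link{polarize}}.
#' @param population population label.
#' @param popmap a \code{pop_map}.
#' @return data.frame with one row per site: \code{n} (called allele
#'   copies), \code{k} (derived count) and \code{polarized} (logical).
#' @export
derived_counts <- function(matrix, ancestral, population, popmap) {
  ct <- .pop_counts(matrix, seq_len(n_sites(matrix)), population, popmap)
  k <- ifelse(ancestral == "ref", ct$k, ct$n - ct$k)
  data.frame(n = ct$n, k = as.integer(k), polarized = !is.na(ancestral))
}

#' Unfolded site-frequency spectrum by effect class
#'
#' Tallies derived-allele counts 1..n over sites with EXACTLY
#' \code{n_chromosomes} called allele copies in the population (no
#' projection or downsampling); sites fixed for the ancestral allele
#' (derived count 0) are excluded. Class n counts fixed derived sites.
#'
#' @param matrix a \code{geno_matrix}.
#' @param ancestral vector from \code{\link{polarize}}.
#' @param population population label.
#' @param popmap a \code{pop_map}.
#' @param n_chromosomes required called allele copies (>= 2).
#' @param effect_class optional: restrict to \code{"neutral"} or
#'   \code{"deleterious"} sites (requires annotations on the matrix).
#' @return list of class \code{sfs}: \code{n_chromosomes}, \code{counts}
#'   (named vector xi_1..xi_n), \code{effect_class}.
#' @export
derived_sfs <- function(matrix, ancestral, population, popmap,
                        n_chromosomes, effect_class = NULL) {
  if (n_chromosomes < 2L) stop("n_chromosomes must be >= 2")
  dc <- derived_counts(matrix, ancestral, population, popmap)
  use <- dc$polarized & dc$n == n_chromosomes & dc$k >= 1L
  if (!is.null(effect_class)) {
    if (is.null(matrix$annotation))
      stop("matrix carries no annotations")
    use <- use & classify_effect(matrix$annotation) == effect_class
  }
  counts <- tabulate(dc$k[use], nbins = n_chromosomes)
  names(counts) <- paste0("xi_", seq_len(n_chromosomes))
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 counts = counts,
                 effect_class = if (is.null(effect_class)) "all" else
                   effect_class),
            class = "sfs")
}

#' Neutral equilibrium SFS expectation
#'
#' Expected proportions of the polymorphic classes 1..(n-1) under the
#' standard neutral constant-size coalescent: proportional to 1/i.
#'
#' @param n_chromosomes sample size in allele copies.
#' @return numeric vector of length n-1 summing to 1.
#' @export
neutral_sfs_expectation <- function(n_chromosomes) {
  i <- seq_len(n_chromosomes - 1L)
  (1 / i) / sum(1 / i)
}

#' Is the derived allele fixed in a population at a site?
#'
#' Default reading: derived frequency 1 among called allele copies (the
#' standard substitution definition). The alternative literal reading —
#' every called individual carries at least one derived copy — is available
#' via \code{per_individual = TRUE}. Sites with zero called alleles return
#' \code{NA}.
#'
#' @param matrix a \code{geno_matrix}.
#' @param ancestral vector from \code{\link{polarize}}.
#' @param population population label.
#' @param popmap a \code{pop_map}.
#' @param per_individual use the per-individual-presence reading.
#' @return logical vector, one per site (\code{NA} where unpolarized or
#'   uncalled).
#' @export
fixed_in_population <- function(matrix, ancestral, population, popmap,
                                per_individual = FALSE) {
  samp <- intersect(pop_samples(popmap, population), matrix$samples)
  g <- matrix$geno[, samp, drop = FALSE]
  der <- g
  flip <- which(ancestral == "alt")
  der[flip, ] <- 2L - g[flip, , drop = FALSE]
  n_called <- rowSums(!is.na(der))
  out <- rep(NA, n_sites(matrix))
  if (per_individual) {
    ok <- n_called > 0L & !is.na(ancestral)
    out[ok] <- (rowSums(der >= 1L, na.rm = TRUE) == n_called)[ok]
  } else {
    ok <- n_called > 0L & !is.na(ancestral)
    out[ok] <- (rowSums(der, na.rm = TRUE) == 2L * n_called)[ok]
  }
  out
}

#' Fixed-substitution table by effect class
#'
#' Per population: counts of fixed derived alleles in the neutral and
#' deleterious classes and the deleterious fraction
#' deleterious / (deleterious + neutral).
#'
#' @param matrix an annotated \code{geno_matrix}.
#' @param ancestral vector from \code{\link{polarize}}.
#' @param populations character vector of population labels.
#' @param popmap a \code{pop_map}.
#' @param per_individual passed to \code{\link{fixed_in_population}}.
#' @return data.frame: population, neutral_fixed, deleterious_fixed,
#'   deleterious_fraction (\code{NA} when no fixed sites).
#' @export
substitution_table <- function(matrix, ancestral, populations, popmap,
                               per_individual = FALSE) {
  if (is.null(matrix$annotation)) stop("matrix carries no annotations")
  cls <- classify_effect(matrix$annotation)
  rows <- lapply(populations, function(p) {
    fx <- fixed_in_population(matrix, ancestral, p, popmap,
                              per_individual = per_individual)
    fx[is.na(fx)] <- FALSE
    neu <- sum(fx & cls == "neutral")
    del <- sum(fx & cls == "deleterious")
    data.frame(population = p, neutral_fixed = neu,
               deleterious_fixed = del,
               deleterious_fraction =
                 if (neu + del == 0) NA_real_ else del / (neu + del),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test of a contingency table
#'
#' Classical test with expectations from the row/column margins:
#' chi2 = sum (O-E)^2 / E, df = (r-1)(c-1), upper-tail p-value. No
#' continuity correction, no multiple-testing adjustment.
#'
#' @param table numeric matrix of counts (r x c), all margins positive.
#' @return list: statistic, df, p_value.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Read a per-site annotation table and attach it to a matrix
#'
#' The table is a TSV with header \code{chrom<TAB>pos<TAB>effect}. Sites
#' absent from the table get the label \code{"NONE"}.
#'
#' @param matrix a \code{geno_matrix}.
#' @param path annotation TSV path.
#' @return the matrix with its \code{annotation} field populated.
#' @export
attach_annotations <- function(matrix, path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "effect") %in% names(df)))
    stop("annotation table must have chrom, pos, effect columns")
  key <- paste(matrix$chrom, matrix$pos)
  idx <- match(key, paste(df$chrom, df$pos))
  ann <- ifelse(is.na(idx), "NONE", df$effect[idx])
  matrix$annotation <- ann
  matrix
}
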