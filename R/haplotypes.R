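#' Read an aligned FASTA into a character alignment
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector of upper-case sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(out))) > 1L)
    stop("sequences are not aligned (unequal lengths)")
  if (anyDuplicated(names(out))) stop("duplicate sequence identifiers")
  out
}

.alignment_matrix <- function(sequences) {
  if (length(unique(nchar(sequences))) > 1L)
    stop("sequences must be equal length")
  do.call(rbind, strsplit(sequences, ""))
}

#' Columns free of gaps and ambiguity across all sequences
#' @noRd
.retained_columns <- function(mat) {
  which(colSums(mat == "-" | mat == "N") == 0L)
}

#' Collapse aligned sequences into haplotypes
#'
#' Complete deletion first: columns containing a gap or N in ANY sequence
#' are removed; sequences identical over the remaining columns share a
#' haplotype. Haplotypes are numbered by first occurrence.
#'
#' @param sequences named character vector of equal-length sequences over
#'   \{A,C,G,T,N,-\}.
#' @return list: \code{haplotypes} (character vector of distinct retained
#'   sequences, names H1, H2, ...), \code{membership} (haplotype name per
#'   input sequence), \code{counts}, \code{retained_columns} (indices into
#'   the original alignment).
#' @export
collapse_haplotypes <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  mat <- .alignment_matrix(sequences)
  keep <- .retained_columns(mat)
  if (length(keep) == 0L)
    stop("no columns remain after removing gap/N columns")
  red <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  uniq <- red[!duplicated(red)]
  hap_names <- paste0("H", seq_along(uniq))
  membership <- hap_names[match(red, uniq)]
  names(membership) <- names(sequences)
  names(uniq) <- hap_names
  list(haplotypes = uniq, membership = membership,
       counts = table(factor(membership, levels = hap_names)),
       retained_columns = keep)
}

#' Pairwise Hamming differences between haplotypes
#'
#' @param haplotypes character vector of equal-length sequences (e.g. the
#'   \code{haplotypes} element of \code{\link{collapse_haplotypes}}).
#' @return symmetric integer matrix of mutation counts, zero diagonal.
#' @export
pairwise_differences <- function(haplotypes) {
  stopifnot(length(haplotypes) >= 2L)
  mat <- .alignment_matrix(haplotypes)
  n <- nrow(mat)
  d <- matrix(0L, n, n, dimnames = list(names(haplotypes),
                                        names(haplotypes)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

#' Minimum-spanning haplotype network
#'
#' The union of ALL minimum spanning trees of the haplotype distance
#' matrix: distances are processed in increasing order, and within each
#' distance rank every edge joining two components that are still separate
#' under strictly smaller distances is retained (tie union), then the
#' components are merged. This is the epsilon = 0 backbone of a
#' median-joining network (median vertices are not added).
#'
#' @param distances symmetric numeric distance matrix with haplotype
#'   names.
#' @return data.frame of edges: from, to, weight (mutation count), ordered
#'   by weight then labels; errors if the haplotypes cannot all be
#'   connected.
#' @export
minimum_spanning_network <- function(distances) {
  n <- nrow(distances)
  labs <- rownames(distances)
  if (is.null(labs)) labs <- paste0("H", seq_len(n))
  ut <- which(upper.tri(distances), arr.ind = TRUE)
  ed <- data.frame(i = ut[, 1], j = ut[, 2],
                   w = distances[upper.tri(distances)])
  if (any(!is.finite(ed$w))) stop("distance matrix has non-finite entries")
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  keep <- logical(nrow(ed))
  for (w in sort(unique(ed$w))) {
    grp <- which(ed$w == w)
    roots_i <- vapply(ed$i[grp], find, 0L)
    roots_j <- vapply(ed$j[grp], find, 0L)
    sel <- roots_i != roots_j
    keep[grp[sel]] <- TRUE
    for (g in grp[sel]) comp[find(ed$i[g])] <- find(ed$j[g])
  }
  root1 <- find(1L)
  if (!all(vapply(seq_len(n), find, 0L) == root1))
    stop("distance matrix is disconnected; network cannot span it")
  res <- ed[keep, , drop = FALSE]
  res <- data.frame(from = labs[res$i], to = labs[res$j],
                    weight = res$w, stringsAsFactors = FALSE)
  res[order(res$weight, res$from, res$to), , drop = FALSE]
}

#' Nucleotide diversity from an alignment
#'
#' Mean pairwise Hamming difference over all sequence pairs, divided by
#' the number of retained (gap/N-free) columns; optionally per population.
#'
#' @param sequences named character vector of aligned sequences.
#' @param populations optional named character vector (or vector parallel
#'   to \code{sequences}) of population labels.
#' @return list: \code{overall} per-site diversity, \code{n_columns}
#'   retained columns, and \code{per_population} (named vector, \code{NA}
#'   for groups of one) when labels are given.
#' @export
alignment_pi <- function(sequences, populations = NULL) {
  stopifnot(length(sequences) >= 2L)
  mat <- .alignment_matrix(sequences)
  keep <- .retained_columns(mat)
  if (length(keep) == 0L) stop("no columns remain after filtering")
  mat <- mat[, keep, drop = FALSE]
  mean_pd <- function(rows) {
    m <- length(rows)
    if (m < 2L) return(NA_real_)
    tot <- 0
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m))
      tot <- tot + sum(mat[rows[i], ] != mat[rows[j], ])
    tot / choose(m, 2) / length(keep)
  }
  out <- list(overall = mean_pd(seq_len(nrow(mat))),
              n_columns = length(keep))
  if (!is.null(populations)) {
    if (!is.null(names(populations)))
      populations <- populations[names(sequences)]
    out$per_population <- vapply(split(seq_len(nrow(mat)), populations),
                                 mean_pd, 0)
  }
  out
}

#' Write a haplotype network as GraphML
#'
#' @param edges edge data.frame from
#'   \code{\link{minimum_spanning_network}}.
#' @param counts optional named haplotype counts (node sizes).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_graphml <- function(edges, path, counts = NULL) {
  nodes <- unique(c(edges$from, edges$to))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="w" for="edge" attr.name="weight" attr.type="int"/>',
             '<key id="n" for="node" attr.name="count" attr.type="int"/>',
             '<graph edgedefault="undirected">')
  for (nd in nodes) {
    cnt <- if (!is.null(counts) && nd %in% names(counts))
      sprintf('<data key="n">%d</data>', as.integer(counts[[nd]])) else ""
    lines <- c(lines, sprintf('<node id="%s">%s</node>', nd, cnt))
  }
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf(
      '<edge source="%s" target="%s"><data key="w">%d</data></edge>',
      edges$from[i], edges$to[i], as.integer(edges$weight[i])))
  }
  lines <- c(lines, "</graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
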