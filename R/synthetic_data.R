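#' Define a demographic model for the structured-coalescent simulator
#'
#' Time is measured in generations backward from sampling. Populations
#' have piecewise-constant diploid sizes; backward in time, lineages in a
#' derived population move to its ancestral population at the split time,
#' migrate between extant populations at per-generation rates, and jump
#' from a pulse's recipient to its source with probability f at the pulse
#' time (an instantaneous admixture pulse of fraction f, forward in time,
#' from source into recipient).
#'
#' @param populations character vector of population labels.
#' @param sizes named numeric vector of diploid sizes N (individuals).
#' @param splits optional data.frame(time, derived, ancestral): backward
#'   in time, at \code{time} all lineages of \code{derived} join
#'   \code{ancestral} and \code{derived} ceases to exist.
#' @param migration optional square matrix of backward per-lineage
#'   migration rates per generation; \code{migration[i, j]} is the rate at
#'   which a lineage currently in population i jumps to population j.
#' @param pulses optional data.frame(time, source, recipient, fraction).
#' @param size_changes optional data.frame(time, population, size):
#'   backward in time the population takes the new size from \code{time}
#'   on (so a recent bottleneck is a small present size with a larger
#'   ancestral size at the bottleneck onset time).
#' @return an object of class \code{demography_model}.
#' @export
demography_model <- function(populations, sizes, splits = NULL,
                             migration = NULL, pulses = NULL,
                             size_changes = NULL) {
  stopifnot(length(populations) >= 1L,
            all(populations %in% names(sizes)), all(sizes > 0))
  if (!is.null(splits)) {
    stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)),
              all(splits$time > 0),
              all(splits$derived %in% populations),
              all(splits$ancestral %in% populations))
  }
  if (!is.null(migration)) {
    migration <- as.matrix(migration)
    stopifnot(nrow(migration) == length(populations),
              ncol(migration) == length(populations),
              all(migration >= 0))
    dimnames(migration) <- list(populations, populations)
    diag(migration) <- 0
  }
  if (!is.null(pulses)) {
    stopifnot(all(c("time", "source", "recipient", "fraction") %in%
                    names(pulses)),
              all(pulses$time > 0),
              all(pulses$fraction >= 0), all(pulses$fraction <= 1),
              all(pulses$source %in% populations),
              all(pulses$recipient %in% populations))
  }
  if (!is.null(size_changes)) {
    stopifnot(all(c("time", "population", "size") %in%
                    names(size_changes)),
              all(size_changes$time > 0), all(size_changes$size > 0),
              all(size_changes$population %in% populations))
  }
  model <- structure(list(populations = populations,
                          sizes = sizes[populations],
                          splits = splits, migration = migration,
                          pulses = pulses, size_changes = size_changes),
                     class = "demography_model")
  .validate_connectivity(model)
  model
}

# all populations must be joinable (via splits, migration or pulses) so
# that the coalescent terminates at a single grand MRCA
.validate_connectivity <- function(model) {
  pops <- model$populations
  np <- length(pops)
  if (np == 1L) return(invisible(TRUE))
  comp <- seq_len(np)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  join <- function(a, b) comp[find(match(a, pops))] <<-
    find(match(b, pops))
  if (!is.null(model$splits))
    for (i in seq_len(nrow(model$splits)))
      join(model$splits$derived[i], model$splits$ancestral[i])
  if (!is.null(model$migration)) {
    nz <- which(model$migration > 0, arr.ind = TRUE)
    for (i in seq_len(nrow(nz))) join(pops[nz[i, 1]], pops[nz[i, 2]])
  }
  if (!is.null(model$pulses))
    for (i in seq_len(nrow(model$pulses)))
      if (model$pulses$fraction[i] > 0)
        join(model$pulses$source[i], model$pulses$recipient[i])
  roots <- vapply(seq_len(np), find, 0L)
  if (length(unique(roots)) > 1L)
    stop("model has isolated populations with no joining event; ",
         "the coalescent would not terminate")
  invisible(TRUE)
}

#' Simulate one genealogy under the structured coalescent
#'
#' Continuous-time simulation backward from sampling: within each
#' population of current diploid size N, each pair of lineages coalesces
#' at rate 1/(2N) per generation; each lineage migrates at the model's
#' backward rates; scheduled events (splits, pulses, size changes) are
#' applied at their times. Runs until the grand MRCA.
#'
#' @param model a \code{demography_model}.
#' @param samples named integer vector: haploid lineages sampled per
#'   population (zero entries allowed).
#' @return a \code{genealogy} object: \code{n_tips}, \code{parent}
#'   (integer, NA at the root), \code{time} (generations, 0 at tips),
#'   \code{tip_population}, \code{tmrca} and \code{event_log} (pulse
#'   applications with lineage counts moved).
#' @export
simulate_genealogy <- function(model, samples) {
  pops <- model$populations
  np <- length(pops)
  samples <- samples[names(samples) %in% pops]
  n <- sum(samples)
  stopifnot(n >= 1L)
  tip_pop <- rep(match(names(samples), pops), samples)
  nn <- 2L * n - 1L
  parent <- rep(NA_integer_, nn)
  node_time <- numeric(nn)
  active <- seq_len(n)
  pop_of <- tip_pop
  next_node <- n + 1L
  sizes <- model$sizes
  M <- if (is.null(model$migration))
    matrix(0, np, np, dimnames = list(pops, pops)) else model$migration
  ev <- .event_schedule(model)
  ev_i <- 1L
  t <- 0
  log_rows <- list()
  if (n == 1L)
    return(structure(list(n_tips = 1L, parent = parent,
                          time = node_time, tip_population = pops[tip_pop],
                          tmrca = 0, event_log = data.frame()),
                     class = "genealogy"))
  repeat {
    if (length(active) == 1L) break
    ks <- tabulate(pop_of, np)
    coal_rate <- ks * (ks - 1) / 2 / (2 * sizes)
    mig_rate <- ks * rowSums(M)
    tot <- sum(coal_rate) + sum(mig_rate)
    t_ev <- if (ev_i <= nrow(ev)) ev$time[ev_i] else Inf
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (t + dt >= t_ev) {
      if (is.infinite(t_ev))
        stop("simulation cannot proceed: no rates and no events left")
      t <- t_ev
      e <- ev[ev_i, ]
      ev_i <- ev_i + 1L
      if (e$type == "split") {
        d <- match(e$a, pops); an <- match(e$b, pops)
        pop_of[pop_of == d] <- an
        M[d, ] <- 0; M[, d] <- 0
      } else if (e$type == "pulse") {
        src <- match(e$a, pops); rec <- match(e$b, pops)
        in_rec <- which(pop_of == rec)
        mv <- in_rec[stats::runif(length(in_rec)) < e$value]
        pop_of[mv] <- src
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(time = t, type = "pulse", source = e$a,
                     recipient = e$b, n_candidates = length(in_rec),
                     n_moved = length(mv))
      } else if (e$type == "size") {
        sizes[e$a] <- e$value
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1) * tot
    acc <- 0
    done <- FALSE
    for (i in seq_len(np)) {
      acc <- acc + coal_rate[i]
      if (u < acc) {  # coalescence in population i
        pair <- sample(which(pop_of == i), 2L)
        parent[active[pair]] <- next_node
        node_time[next_node] <- t
        active <- c(active[-pair], next_node)
        pop_of <- c(pop_of[-pair], i)
        next_node <- next_node + 1L
        done <- TRUE
        break
      }
    }
    if (!done) {
      for (i in seq_len(np)) {
        for (j in seq_len(np)) {
          acc <- acc + ks[i] * M[i, j]
          if (u < acc) {  # one lineage migrates i -> j
            mv <- sample(which(pop_of == i), 1L)
            pop_of[mv] <- j
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
  }
  structure(list(n_tips = n, parent = parent, time = node_time,
                 tip_population = pops[tip_pop], tmrca = t,
                 event_log = if (length(log_rows))
                   do.call(rbind, log_rows) else data.frame()),
            class = "genealogy")
}

.event_schedule <- function(model) {
  rows <- list()
  if (!is.null(model$splits))
    rows[[length(rows) + 1L]] <- data.frame(
      time = model$splits$time, type = "split",
      a = model$splits$derived, b = model$splits$ancestral, value = NA)
  if (!is.null(model$pulses))
    rows[[length(rows) + 1L]] <- data.frame(
      time = model$pulses$time, type = "pulse",
      a = model$pulses$source, b = model$pulses$recipient,
      value = model$pulses$fraction)
  if (!is.null(model$size_changes))
    rows[[length(rows) + 1L]] <- data.frame(
      time = model$size_changes$time, type = "size",
      a = model$size_changes$population, b = NA,
      value = model$size_changes$size)
  if (length(rows) == 0L)
    return(data.frame(time = numeric(0), type = character(0),
                      a = character(0), b = character(0),
                      value = numeric(0)))
  ev <- do.call(rbind, rows)
  ev[order(ev$time), , drop = FALSE]
}

#' Tip sets descending from each node of a genealogy
#' @noRd
.descendant_tips <- function(tree) {
  nn <- length(tree$parent)
  desc <- vector("list", nn)
  for (i in seq_len(tree$n_tips)) desc[[i]] <- i
  if (nn > tree$n_tips)
    for (i in seq.int(tree$n_tips + 1L, nn)) desc[[i]] <- integer(0)
  for (i in seq_len(nn))  # parents always have larger ids than children
    if (!is.na(tree$parent[i]))
      desc[[tree$parent[i]]] <- c(desc[[tree$parent[i]]], desc[[i]])
  desc
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutation count is Poisson(total branch length x mu x length); each
#' mutation lands uniformly on the branches (probability proportional to
#' branch length) and receives a unique position in 1..length. Carriers
#' are the tips below the mutated branch.
#'
#' @param tree a \code{genealogy}.
#' @param mu_per_site mutation rate per site per generation (>= 0).
#' @param length locus length in bp.
#' @return list: \code{pos} (sorted unique positions) and
#'   \code{carriers} (list of tip-index vectors, parallel to \code{pos}).
#' @export
drop_mutations <- function(tree, mu_per_site, length) {
  stopifnot(mu_per_site >= 0, length >= 1)
  nn <- length(tree$parent)
  bl <- rep(0, nn)
  has_par <- !is.na(tree$parent)
  bl[has_par] <- tree$time[tree$parent[has_par]] - tree$time[has_par]
  total <- sum(bl)
  n_mut <- if (total > 0) stats::rpois(1, total * mu_per_site * length)
           else 0L
  if (n_mut > length) n_mut <- as.integer(length)  # infinite-sites cap
  if (n_mut == 0L) return(list(pos = integer(0), carriers = list()))
  branch <- sample.int(nn, n_mut, replace = TRUE, prob = bl)
  pos <- sort(sample.int(length, n_mut))
  desc <- .descendant_tips(tree)
  list(pos = pos, carriers = desc[branch])
}

#' Simulation parameters
#'
#' @param samples_per_population named integer vector of DIPLOID sample
#'   counts per population.
#' @param mu mutation rate per site per generation.
#' @param n_windows number of independent windows (one genealogy each; no
#'   intra-window recombination).
#' @param window_length window length in bp.
#' @param seed integer seed fixing all randomness.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(samples_per_population, mu, n_windows,
                       window_length, seed = 1L) {
  stopifnot(all(samples_per_population >= 1L), mu > 0, n_windows >= 1,
            window_length >= 1)
  structure(list(samples_per_population = samples_per_population,
                 mu = mu, n_windows = as.integer(n_windows),
                 window_length = as.integer(window_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a multi-window genotype dataset
#'
#' One genealogy per window, infinite-sites mutations, haploid carriers
#' paired into diploids within each population. An optional set of focal
#' windows restricts the model's admixture pulses to those windows,
#' emulating a locus-specific introgression signal against a pulse-free
#' genome-wide background. Identical seeds give bit-identical output.
#'
#' @param model a \code{demography_model}.
#' @param params a \code{sim_params}.
#' @param pulse_windows optional integer window indices where the model's
#'   pulses apply (default: all windows when the model has pulses).
#' @param chrom chromosome name for the emitted coordinates.
#' @return list: \code{matrix} (a \code{geno_matrix}), \code{popmap}
#'   (a \code{pop_map}), \code{truth} (per-window data.frame: window,
#'   start, end, tmrca, n_mutations, pulse).
#' @export
simulate_dataset <- function(model, params, pulse_windows = NULL,
                             chrom = "sim_1") {
  stopifnot(inherits(model, "demography_model"),
            inherits(params, "sim_params"))
  set.seed(params$seed)
  dip <- params$samples_per_population
  hap <- 2L * dip
  L <- params$window_length
  model_nopulse <- model
  model_nopulse$pulses <- NULL
  if (is.null(pulse_windows))
    pulse_windows <- if (is.null(model$pulses)) integer(0) else
      seq_len(params$n_windows)
  sample_ids <- unlist(lapply(names(dip), function(p)
    paste0(p, "_", seq_len(dip[[p]]))))
  pop_labels <- rep(names(dip), dip)
  chroms <- character(0); poss <- integer(0)
  geno_rows <- list()
  truth <- vector("list", params$n_windows)
  for (w in seq_len(params$n_windows)) {
    m_w <- if (w %in% pulse_windows) model else model_nopulse
    tree <- simulate_genealogy(m_w, hap)
    mut <- drop_mutations(tree, params$mu, L)
    nmut <- length(mut$pos)
    if (nmut > 0) {
      hapmat <- matrix(0L, nmut, sum(hap))
      for (i in seq_len(nmut)) hapmat[i, mut$carriers[[i]]] <- 1L
      # consecutive haplotypes pair into diploids (tips are ordered by
      # population, matching sample_ids)
      dosage <- hapmat[, seq(1, sum(hap), by = 2), drop = FALSE] +
        hapmat[, seq(2, sum(hap), by = 2), drop = FALSE]
      geno_rows[[w]] <- dosage
      chroms <- c(chroms, rep(chrom, nmut))
      poss <- c(poss, (w - 1L) * L + mut$pos)
    }
    truth[[w]] <- data.frame(window = w, start = (w - 1L) * L + 1L,
                             end = w * L, tmrca = tree$tmrca,
                             n_mutations = nmut,
                             pulse = w %in% pulse_windows)
  }
  geno <- if (length(geno_rows)) do.call(rbind, geno_rows) else
    matrix(integer(0), 0, sum(dip))
  ref_alt <- .random_ref_alt(length(poss))
  list(matrix = geno_matrix(chroms, poss, ref_alt$ref, ref_alt$alt,
                            geno, sample_ids),
       popmap = pop_map(sample_ids, pop_labels),
       truth = do.call(rbind, truth))
}

.random_ref_alt <- function(n) {
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Draw derived-allele counts from an arbitrary frequency-class
#' distribution
#'
#' Fabricates site-frequency data directly: derived counts in 1..n are
#' drawn from the normalised class weights. Neutral sites use weights
#' proportional to 1/i; deleterious sites use a user-distorted profile.
#'
#' @param n_chromosomes sample size in allele copies.
#' @param class_weights non-negative weights for classes 1..n (not all
#'   zero); shorter vectors are zero-padded.
#' @param n_sites number of sites to draw.
#' @return integer vector of derived counts (length \code{n_sites}).
#' @export
sample_sfs_sites <- function(n_chromosomes, class_weights, n_sites) {
  stopifnot(n_chromosomes >= 2, all(class_weights >= 0))
  if (sum(class_weights) == 0) stop("all class weights are zero")
  w <- rep(0, n_chromosomes)
  w[seq_along(class_weights)] <- class_weights
  if (n_sites == 0L) return(integer(0))
  sample.int(n_chromosomes, n_sites, replace = TRUE, prob = w)
}

#' Fabricate a functional-annotation table for simulated sites
#'
#' Each site is labelled deleterious with the given probability
#' (label drawn uniformly from the deleterious vocabulary:
#' missense_variant, start_lost, stop_gained), otherwise neutral
#' (synonymous_variant, intron_variant, NONE).
#'
#' @param matrix a \code{geno_matrix} (sites to annotate).
#' @param deleterious_fraction probability a site is deleterious, in
#'   [0, 1].
#' @return data.frame: chrom, pos, effect (suitable for
#'   \code{\link{attach_annotations}} after writing to TSV, or attach the
#'   \code{effect} column directly).
#' @export
annotate_sites <- function(matrix, deleterious_fraction) {
  stopifnot(deleterious_fraction >= 0, deleterious_fraction <= 1)
  ns <- n_sites(matrix)
  del <- stats::runif(ns) < deleterious_fraction
  eff <- character(ns)
  eff[del] <- sample(.DELETERIOUS_LABELS, sum(del), replace = TRUE)
  eff[!del] <- sample(.NEUTRAL_LABELS, sum(!del), replace = TRUE)
  data.frame(chrom = matrix$chrom, pos = matrix$pos, effect = eff,
             stringsAsFactors = FALSE)
}

#' Convenience demography: one constant-size population
#' @param N diploid size.
#' @param label population label.
#' @return a \code{demography_model}.
#' @export
demography_constant <- function(N, label = "pop1") {
  demography_model(label, stats::setNames(N, label))
}

#' Convenience demography: recent bottleneck
#'
#' Present size \code{N_small}; at \code{t_change} generations ago the
#' size was \code{N_large} (so forward in time the population crashed
#' from N_large to N_small at that point).
#'
#' @param N_small,N_large diploid sizes.
#' @param t_change generations before present.
#' @param label population label.
#' @return a \code{demography_model}.
#' @export
demography_bottleneck <- function(N_small, N_large, t_change,
                                  label = "pop1") {
  demography_model(label, stats::setNames(N_small, label),
                   size_changes = data.frame(time = t_change,
                                             population = label,
                                             size = N_large))
}

#' Convenience demography: four-taxon quartet with an optional pulse
#'
#' Topology (((P1, P2), P3), O): P1 and P2 split at \code{t12}, their
#' ancestor and P3 at \code{t123}, and the outgroup at \code{t_root}. An
#' optional admixture pulse moves a fraction \code{pulse_fraction} of P2
#' from P3 (forward in time: P3 into P2) at \code{pulse_time}.
#'
#' @param N diploid size of every population.
#' @param t12,t123,t_root split times in generations (increasing).
#' @param pulse_fraction admixture fraction f in [0, 1] (0 = no pulse).
#' @param pulse_time pulse time in generations (< t12).
#' @return a \code{demography_model} with populations P1, P2, P3, O.
#' @export
demography_quartet <- function(N, t12, t123, t_root,
                               pulse_fraction = 0,
                               pulse_time = t12 / 10) {
  stopifnot(t12 < t123, t123 < t_root)
  pops <- c("P1", "P2", "P3", "O")
  pulses <- NULL
  if (pulse_fraction > 0) {
    stopifnot(pulse_time < t12)
    pulses <- data.frame(time = pulse_time, source = "P3",
                         recipient = "P2", fraction = pulse_fraction)
  }
  demography_model(
    pops, stats::setNames(rep(N, 4), pops),
    splits = data.frame(time = c(t12, t123, t_root),
                        derived = c("P2", "P3", "O"),
                        ancestral = c("P1", "P1", "P1")),
    pulses = pulses)
}
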