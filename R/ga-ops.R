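# Operators of the immunogenetic global-search phase. A chromosome is a
# row of integer community labels, one per node; a population is a matrix
# with one chromosome per row. All operators draw from the current RNG
# stream; mfmicd() seeds it once so whole fits are reproducible.

#' Identifier-passing population initialisation
#'
#' Every chromosome starts from the identity labelling (each node its own
#' community, label = node id) and then every node's label is replaced, in
#' a single synchronous pass, by the id of one of its graph neighbours
#' drawn uniformly at random. Isolated nodes keep their own id. This seeds
#' the population with locally coherent label patches: labels can never
#' cross connected components.
#'
#' @param net a [binary_network()].
#' @param pop_size number of chromosomes (>= 2).
#' @return integer matrix `pop_size x n_nodes`.
#' @export
initialize_population <- function(net, pop_size) {
  if (pop_size < 2) stop("population size must be at least 2", call. = FALSE)
  n <- net$n_nodes
  if (n < 1) stop("network must have at least one node", call. = FALSE)
  pop <- matrix(0L, nrow = pop_size, ncol = n)
  has_nb <- net$degree > 0
  for (r in seq_len(pop_size)) {
    lab <- seq_len(n)
    for (v in which(has_nb)) {
      nb <- net$adj[[v]]
      lab[v] <- nb[sample.int(length(nb), 1L)]
    }
    pop[r, ] <- lab
  }
  pop
}

#' Linear fitness calibration
#'
#' Shifts raw modularity values by the population minimum so that fitness
#' is non-negative, as fitness-proportional selection requires. When every
#' member has the same raw objective all fitnesses are zero and selection
#' must fall back to uniform sampling (see [roulette_select()]).
#'
#' @param raw_q numeric vector of raw objective (modularity) values.
#' @return non-negative numeric vector with minimum exactly 0.
#' @export
calibrated_fitness <- function(raw_q) {
  if (length(raw_q) == 0) stop("empty objective vector", call. = FALSE)
  if (any(!is.finite(raw_q))) stop("objective values must be finite", call. = FALSE)
  raw_q - min(raw_q)
}

#' Population convergence rate
#'
#' The rate-of-change statistic `phi = f_avg / (f_max - f_min)` of the
#' calibrated fitness: small when the population is spread out (early
#' search), large as it concentrates. A fully converged population
#' (`f_max == f_min`) returns `Inf` as the sentinel.
#'
#' @param fitness non-negative fitness vector.
#' @return scalar `phi >= 0`, or `Inf` when converged.
#' @export
convergence_rate <- function(fitness) {
  fmax <- max(fitness); fmin <- min(fitness)
  if (fmax == fmin) return(Inf)
  mean(fitness) / (fmax - fmin)
}

#' Dynamic crossover and mutation rates
#'
#' Instantiates the inverse power-function schedule: mutation probability
#' `pm = 1/(phi + 1)` decreases as the population converges (high variation
#' early to preserve diversity, low variation late to protect good
#' solutions) and the crossover probability is its complement
#' `pc = 1 - pm`. Both are clamped to sane operating ranges; the converged
#' sentinel `phi = Inf` yields the lower mutation bound.
#'
#' @param phi convergence rate from [convergence_rate()].
#' @param pm_bounds,pc_bounds length-2 clamping intervals in (0, 1).
#' @return named list with elements `pc` and `pm`.
#' @export
dynamic_rates <- function(phi, pm_bounds = c(0.01, 0.5), pc_bounds = c(0.5, 0.99)) {
  pm_raw <- if (is.infinite(phi)) 0 else 1 / (phi + 1)
  pm <- min(max(pm_raw, pm_bounds[1]), pm_bounds[2])
  pc <- min(max(1 - pm, pc_bounds[1]), pc_bounds[2])
  list(pc = pc, pm = pm)
}

#' Roulette-wheel selection
#'
#' Fitness-proportional sampling with replacement: member `i` is drawn with
#' probability `f_i / sum(f)`. A degenerate all-zero fitness vector falls
#' back to uniform probabilities.
#'
#' @param fitness non-negative fitness vector.
#' @param n_draws number of indices to draw.
#' @return integer vector of selected member indices.
#' @export
roulette_select <- function(fitness, n_draws) {
  if (any(fitness < 0)) stop("fitness must be non-negative", call. = FALSE)
  prob <- if (sum(fitness) == 0) rep(1, length(fitness)) else fitness
  sample.int(length(fitness), n_draws, replace = TRUE, prob = prob)
}

# Indices (1-based) of the circular segment [a, b) on strings of length n,
# cut points 0-based; empty when a == b.
circular_segment <- function(a, b, n) {
  if (a == b) return(integer(0))
  if (a < b) (a:(b - 1L)) + 1L else c(a:(n - 1L), if (b > 0) 0:(b - 1L)) + 1L
}

#' Strongest-first circular crossover
#'
#' Members are paired in descending-fitness order (best with second best,
#' third with fourth, ...; ties broken by member index). Each pair crosses
#' with probability `pc` by swapping a circular segment of the label
#' string: two cut points are drawn uniformly on `0..n-1` and the positions
#' `[cut1, cut2)` — wrapping past the end when `cut1 > cut2` — are
#' exchanged between the parents. Non-crossing pairs and the unpaired last
#' member of an odd population are copied unchanged.
#'
#' @param pop chromosome matrix (one member per row).
#' @param fitness fitness vector aligned with `pop` rows.
#' @param pc crossover probability in `[0, 1]`.
#' @return offspring matrix of the same shape as `pop`.
#' @export
strongest_first_crossover <- function(pop, fitness, pc) {
  np <- nrow(pop); n <- ncol(pop)
  ord <- order(-fitness, seq_len(np))
  offspring <- pop[ord, , drop = FALSE]
  n_pairs <- np %/% 2L
  if (n_pairs == 0L || n < 2L) return(offspring)
  cross <- stats::runif(n_pairs) < pc
  for (p in seq_len(n_pairs)) {
    if (!cross[p]) next
    i <- 2L * p - 1L; j <- 2L * p
    cuts <- sample.int(n, 2L, replace = TRUE) - 1L
    seg <- circular_segment(cuts[1], cuts[2], n)
    if (length(seg) == 0L) next
    tmp <- offspring[i, seg]
    offspring[i, seg] <- offspring[j, seg]
    offspring[j, seg] <- tmp
  }
  offspring
}

#' Neighbour-constrained mutation
#'
#' Each locus independently, with probability `pm`, takes the current label
#' of a uniformly random graph neighbour of that node (labels are read from
#' the pre-mutation chromosome, so loci mutate synchronously). Isolated
#' nodes never change. Constraining mutation to neighbour labels keeps
#' every mutant inside the space of locally plausible community
#' assignments.
#'
#' @param chrom integer label vector (one chromosome).
#' @param pm per-locus mutation probability in `[0, 1]`.
#' @param net the [binary_network()] supplying neighbourhoods.
#' @return mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, pm, net) {
  n <- length(chrom)
  hit <- which(stats::runif(n) < pm & net$degree > 0)
  if (length(hit) == 0L) return(chrom)
  src <- chrom
  for (v in hit) {
    nb <- net$adj[[v]]
    chrom[v] <- src[nb[sample.int(length(nb), 1L)]]
  }
  chrom
}

#' Immune (vaccination) operator
#'
#' Treats the current best member's assignment on the hub nodes as a
#' vaccine: the labels of the top-decile-degree nodes (at least one; ties
#' by node index) are extracted from the best chromosome and injected into
#' a random 20% of the non-best members. Immune selection then keeps each
#' vaccinated member only if its modularity did not decrease, otherwise it
#' reverts. The best member is never modified, so the population's best
#' objective cannot degrade.
#'
#' @param pop chromosome matrix.
#' @param raw_q modularity of each row of `pop`.
#' @param net the [binary_network()].
#' @return list with the updated `pop` and `raw_q`.
#' @export
immune_operator <- function(pop, raw_q, net) {
  np <- nrow(pop); n <- ncol(pop)
  best <- which.max(raw_q)
  n_vac <- max(1L, ceiling(n / 10))
  hubs <- order(-net$degree, seq_len(n))[seq_len(n_vac)]
  vaccine <- pop[best, hubs]
  others <- setdiff(seq_len(np), best)
  if (length(others) == 0L) return(list(pop = pop, raw_q = raw_q))
  n_tgt <- ceiling(0.2 * length(others))
  targets <- others[sample.int(length(others), n_tgt)]
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  for (t in targets) {
    cand <- pop[t, ]
    cand[hubs] <- vaccine
    qc <- q_of_labels(cand, e1, e2, net$degree, nrow(net$edges))
    if (qc >= raw_q[t]) {
      pop[t, ] <- cand
      raw_q[t] <- qc
    }
  }
  list(pop = pop, raw_q = raw_q)
}
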