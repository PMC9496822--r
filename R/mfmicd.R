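#' Memetic immunogenetic community detection
#'
#' Divides an undirected binary network into communities by maximising
#' modularity with a two-stage memetic search. The global stage is an
#' immunogenetic algorithm: identifier-passing initialisation
#' ([initialize_population()]), fitness calibration
#' ([calibrated_fitness()]), dynamically scheduled crossover/mutation
#' rates driven by the population convergence rate ([convergence_rate()],
#' [dynamic_rates()]), roulette-wheel parent selection
#' ([roulette_select()]), strongest-first circular crossover
#' ([strongest_first_crossover()]), neighbour-constrained mutation
#' ([mutate_chromosome()]) and a vaccination-style immune operator
#' ([immune_operator()]), with elitist (parents + offspring) survivor
#' truncation. The local stage refines the global best with a penalised
#' tabu search ([tabu_local_search()]). Neither the number of communities
#' nor any other structural parameter is supplied in advance.
#'
#' With `runs > 1` the whole two-stage search is restarted independently;
#' the best partition over all restarts is reported together with the mean
#' pairwise normalised mutual information across restarts
#' (`stability_nmi`), a measure of how reproducible the division is.
#'
#' @param net a [binary_network()] with at least one edge (or anything
#'   [network_from_adjacency()] accepts).
#' @param pop_size population size of the genetic stage.
#' @param max_gen_global generations of the genetic stage.
#' @param max_gen_tabu rounds of the tabu refinement.
#' @param tabu_tenure tabu tenure in rounds.
#' @param lambda_penalty weight of the disconnected-community penalty in
#'   the tabu objective.
#' @param pm_bounds,pc_bounds clamping intervals for the mutation and
#'   crossover probabilities.
#' @param runs independent restarts; the best result is kept.
#' @param seed integer seed making the whole fit reproducible; `NULL`
#'   continues the current RNG stream.
#' @return an object of class `mfmicd`: a list with `membership` (named
#'   canonical community labels), `q` (its modularity, recomputed
#'   independently of the search), `n_communities`, `trace` (per-generation
#'   data frame with columns `generation`, `best_q`, `mean_q`, `pc`, `pm`
#'   for the winning restart), `stability_nmi` (`NA` for a single run),
#'   `runs`, `seed`, `params` and `network`.
#' @examples
#' tri2 <- binary_network(rbind(c(1,2), c(1,3), c(2,3),
#'                              c(4,5), c(4,6), c(5,6)))
#' fit <- mfmicd(tri2, pop_size = 20, max_gen_global = 10, seed = 1)
#' fit$q           # 0.5: the two triangles
#' membership_groups(fit$membership)
#' @export
mfmicd <- function(net,
                   pop_size = 100,
                   max_gen_global = 50,
                   max_gen_tabu = 20,
                   tabu_tenure = 10,
                   lambda_penalty = 0.1,
                   pm_bounds = c(0.01, 0.5),
                   pc_bounds = c(0.5, 0.99),
                   runs = 1,
                   seed = NULL) {
  if (!inherits(net, "binary_network")) net <- network_from_adjacency(net)
  if (nrow(net$edges) == 0) {
    stop("community detection needs at least one edge", call. = FALSE)
  }
  stopifnot(pop_size >= 2, max_gen_global >= 1, max_gen_tabu >= 0,
            tabu_tenure >= 1, runs >= 1,
            length(pm_bounds) == 2, length(pc_bounds) == 2,
            all(pm_bounds > 0), all(pm_bounds < 1),
            all(pc_bounds > 0), all(pc_bounds < 1))
  if (!is.null(seed)) set.seed(seed)
  params <- list(pop_size = pop_size, max_gen_global = max_gen_global,
                 max_gen_tabu = max_gen_tabu, tabu_tenure = tabu_tenure,
                 lambda_penalty = lambda_penalty, pm_bounds = pm_bounds,
                 pc_bounds = pc_bounds)
  results <- vector("list", runs)
  for (r in seq_len(runs)) {
    results[[r]] <- mfmicd_single(net, params)
  }
  qs <- vapply(results, `[[`, numeric(1), "q")
  win <- which.max(qs)
  stability <- if (runs >= 2) {
    pairwise_stability(lapply(results, `[[`, "membership"))
  } else {
    NA_real_
  }
  structure(
    list(
      membership = results[[win]]$membership,
      q = results[[win]]$q,
      n_communities = max(canonical_membership(results[[win]]$membership)),
      trace = results[[win]]$trace,
      stability_nmi = stability,
      runs = runs,
      seed = seed,
      params = params,
      network = net,
      call = match.call()
    ),
    class = "mfmicd"
  )
}

# One full global + local search on the current RNG stream.
mfmicd_single <- function(net, p) {
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  deg <- net$degree; ne <- nrow(net$edges)
  eval_q <- function(pop) {
    apply(pop, 1L, q_of_labels, e1 = e1, e2 = e2, degree = deg, n_edges = ne)
  }
  pop <- initialize_population(net, p$pop_size)
  raw_q <- eval_q(pop)
  trace <- vector("list", p$max_gen_global)
  for (gen in seq_len(p$max_gen_global)) {
    fit <- calibrated_fitness(raw_q)
    phi <- convergence_rate(fit)
    rates <- dynamic_rates(phi, p$pm_bounds, p$pc_bounds)
    sel <- roulette_select(fit, p$pop_size)
    offspring <- strongest_first_crossover(pop[sel, , drop = FALSE],
                                           fit[sel], rates$pc)
    for (i in seq_len(nrow(offspring))) {
      offspring[i, ] <- mutate_chromosome(offspring[i, ], rates$pm, net)
    }
    off_q <- eval_q(offspring)
    imm <- immune_operator(offspring, off_q, net)
    all_pop <- rbind(pop, imm$pop)
    all_q <- c(raw_q, imm$raw_q)
    keep <- order(-all_q, seq_along(all_q))[seq_len(p$pop_size)]
    pop <- all_pop[keep, , drop = FALSE]
    raw_q <- all_q[keep]
    trace[[gen]] <- data.frame(generation = gen, best_q = max(raw_q),
                               mean_q = mean(raw_q), pc = rates$pc,
                               pm = rates$pm)
  }
  best <- pop[which.max(raw_q), ]
  membership <- if (p$max_gen_tabu > 0) {
    tabu_local_search(net, best, max_gen = p$max_gen_tabu,
                      tenure = p$tabu_tenure, lambda = p$lambda_penalty)
  } else {
    out <- canonical_membership(best)
    names(out) <- net$node_names
    out
  }
  list(membership = membership,
       q = modularity_q(net, membership),
       trace = do.call(rbind, trace))
}

#' @export
print.mfmicd <- function(x, ...) {
  cat("Memetic immunogenetic community division\n")
  cat(sprintf("  network: %d nodes, %d edges\n",
              x$network$n_nodes, nrow(x$network$edges)))
  cat(sprintf("  communities: %d   modularity Q = %.4f\n",
              x$n_communities, x$q))
  if (!is.na(x$stability_nmi)) {
    cat(sprintf("  stability NMI over %d runs: %.4f\n",
                x$runs, x$stability_nmi))
  }
  invisible(x)
}

#' @export
summary.mfmicd <- function(object, ...) {
  sizes <- community_sizes(object$membership)
  groups <- membership_groups(object$membership)
  structure(
    list(fit = object, sizes = sizes,
         members = lapply(groups, function(g) object$network$node_names[g])),
    class = "summary.mfmicd"
  )
}

#' @export
print.summary.mfmicd <- function(x, ...) {
  print(x$fit)
  cat("  community sizes:", paste(x$sizes, collapse = ", "), "\n")
  for (i in seq_along(x$members)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$members[[i]], collapse = " ")))
  }
  invisible(x)
}

#' Plot the search trace of a fit
#'
#' Left axis: best and mean modularity per generation of the genetic
#' stage. Right axis: the dynamically scheduled crossover (`pc`) and
#' mutation (`pm`) probabilities.
#'
#' @param x an `mfmicd` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfmicd <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tr$generation, tr$best_q, type = "l", lwd = 2,
                 xlab = "generation", ylab = "modularity Q",
                 ylim = range(c(tr$best_q, tr$mean_q)), ...)
  graphics::lines(tr$generation, tr$mean_q, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(tr$generation, tr$pc, type = "l", col = "grey40",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::lines(tr$generation, tr$pm, col = "grey40", lty = 3)
  graphics::axis(4)
  graphics::mtext("rate", side = 4, line = 2.5)
  graphics::legend("right", legend = c("best Q", "mean Q", "pc", "pm"),
                   lty = c(1, 2, 1, 3), lwd = c(2, 1, 1, 1),
                   col = c("black", "black", "grey40", "grey40"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
as.data.frame.mfmicd <- function(x, ...) {
  data.frame(node = names(x$membership),
             community = unname(x$membership))
}
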