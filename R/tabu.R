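# Tabu-search local refinement of a partition.

# Number of communities whose induced subgraph is disconnected. A
# disconnected "community" is an artefact of label strings, not a real
# module; it is penalised rather than forbidden outright.
count_disconnected_communities <- function(labels, adj) {
  bad <- 0L
  for (nodes in unname(split(seq_along(labels), labels))) {
    if (length(nodes) == 1L) next
    inset <- logical(length(labels))
    inset[nodes] <- TRUE
    seen <- logical(length(labels))
    queue <- nodes[1]
    seen[queue] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    if (any(inset & !seen)) bad <- bad + 1L
  }
  bad
}

#' Tabu-search refinement of a partition
#'
#' Steepest-descent-with-memory local search on the penalised objective
#' `F = Q - lambda * (# communities whose induced subgraph is
#' disconnected)`. The neighbourhood of a state is every single-node move
#' to a community already containing a graph neighbour of that node, plus
#' splitting the node off into a fresh singleton. After a node leaves a
#' community, the reverse attribute (node, old community) is tabu for
#' `tenure` rounds; an aspiration rule readmits a tabu move when it beats
#' the best `F` seen, so good states inside the forbidden region are not
#' lost. The best state by `F` over all rounds is returned. Because the
#' start state is itself scored, the result never has lower `F` than the
#' start — and never lower `Q` when the start has no disconnected
#' communities.
#'
#' @param net a [binary_network()] with >= 1 edge.
#' @param start per-node community labels to refine.
#' @param max_gen number of search rounds.
#' @param tenure tabu tenure in rounds.
#' @param lambda penalty weight per disconnected community.
#' @return named canonical membership vector of the best state found.
#' @export
tabu_local_search <- function(net, start, max_gen = 20, tenure = 10,
                              lambda = 0.1) {
  if (nrow(net$edges) == 0) {
    stop("modularity is undefined on an edgeless network", call. = FALSE)
  }
  n <- net$n_nodes
  labels <- as.integer(canonical_membership(start))
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  deg <- net$degree; ne <- nrow(net$edges)
  score <- function(lab) {
    q_of_labels(lab, e1, e2, deg, ne) -
      lambda * count_disconnected_communities(lab, net$adj)
  }
  next_label <- max(labels) + 1L
  best_labels <- labels
  best_f <- score(labels)
  tabu_until <- new.env(parent = emptyenv())
  for (round in seq_len(max_gen)) {
    move_best <- NULL
    move_best_f <- -Inf
    sizes <- tabulate(labels, nbins = max(labels))
    for (v in seq_len(n)) {
      cur <- labels[v]
      nb_labels <- unique(labels[net$adj[[v]]])
      cand_labels <- setdiff(sort(nb_labels), cur)
      if (sizes[cur] > 1L) cand_labels <- c(cand_labels, next_label)
      for (tgt in cand_labels) {
        trial <- labels
        trial[v] <- tgt
        f <- score(trial)
        key <- paste0(v, ":", cur)
        is_tabu <- !is.null(tabu_until[[key]]) && tabu_until[[key]] >= round
        if (is_tabu && f <= best_f) next
        if (f > move_best_f) {
          move_best_f <- f
          move_best <- c(v, cur, tgt)
        }
      }
    }
    if (is.null(move_best)) break
    v <- move_best[1]; old <- move_best[2]; tgt <- move_best[3]
    labels[v] <- tgt
    if (tgt == next_label) next_label <- next_label + 1L
    tabu_until[[paste0(v, ":", old)]] <- round + tenure
    if (move_best_f > best_f) {
      best_f <- move_best_f
      best_labels <- labels
    }
  }
  out <- canonical_membership(best_labels)
  names(out) <- net$node_names
  out
}
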