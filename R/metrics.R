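# Partition-quality metrics and the brute-force oracle used in tests.

# Fast modularity kernel used inside the genetic loop: Q = sum_c intra_c/m
# minus sum_c (deg_c / 2m)^2. `e1`, `e2` are the edge endpoint indices.
q_of_labels <- function(labels, e1, e2, degree, n_edges) {
  intra <- sum(labels[e1] == labels[e2])
  dc <- rowsum(degree, labels)
  intra / n_edges - sum((dc / (2 * n_edges))^2)
}

#' Modularity of a partition
#'
#' Newman modularity `Q = sum_i (e_ii - a_i^2)` where `e` is the k-by-k
#' matrix of edge fractions between communities (off-diagonal entries split
#' half-and-half) and `a_i = sum_j e_ij` is community `i`'s share of edge
#' endpoints. Q is the fraction of intra-community edges minus its
#' expectation under a degree-preserving random rewiring; values above 0.3
#' are conventionally taken as evidence of community structure. Isolated
#' nodes contribute zero endpoint mass.
#'
#' @param net a [binary_network()] with at least one edge.
#' @param membership per-node community labels (any vector; canonicalised
#'   internally).
#' @return Q, a scalar in `[-1, 1)`.
#' @examples
#' tri2 <- binary_network(rbind(c(1,2), c(1,3), c(2,3),
#'                              c(4,5), c(4,6), c(5,6)))
#' modularity_q(tri2, c(1, 1, 1, 2, 2, 2))  # 0.5
#' @export
modularity_q <- function(net, membership) {
  if (nrow(net$edges) == 0) {
    stop("modularity is undefined on an edgeless network", call. = FALSE)
  }
  if (length(membership) != net$n_nodes) {
    stop("membership length must equal the number of nodes", call. = FALSE)
  }
  m <- canonical_membership(membership)
  q_of_labels(m, net$edges[, 1], net$edges[, 2], net$degree, nrow(net$edges))
}

# Community edge-fraction matrix e and endpoint fractions a; exposed for the
# invariant sum(e) == 1 and as a slow independent route to Q in tests.
community_edge_matrix <- function(net, membership) {
  m <- canonical_membership(membership)
  k <- max(m)
  n_edges <- nrow(net$edges)
  e <- matrix(0, k, k)
  for (i in seq_len(n_edges)) {
    a <- m[net$edges[i, 1]]; b <- m[net$edges[i, 2]]
    if (a == b) {
      e[a, a] <- e[a, a] + 1 / n_edges
    } else {
      e[a, b] <- e[a, b] + 0.5 / n_edges
      e[b, a] <- e[b, a] + 0.5 / n_edges
    }
  }
  list(e = e, a = rowSums(e))
}

#' Normalised mutual information between two partitions
#'
#' Entropy-normalised mutual information of the community assignments
#' (natural log; the base cancels). 1 means identical partitions, 0 means
#' the partitions carry no information about each other. When either
#' partition is a single community its entropy vanishes and the normalised
#' ratio degenerates; the convention here is 1 when the two partitions are
#' identical and 0 otherwise.
#'
#' @param p1,p2 per-node community labels over the same node set.
#' @return NMI in `[0, 1]`; symmetric in its arguments.
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: orthogonal
#' @export
nmi <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("partitions must cover the same node set", call. = FALSE)
    }
    p2 <- p2[names(p1)]
  }
  a <- canonical_membership(p1)
  b <- canonical_membership(p2)
  n <- length(a)
  conf <- table(a, b)
  ci <- rowSums(conf)
  cj <- colSums(conf)
  if (length(ci) == 1 && length(cj) == 1) return(1)
  num <- 0
  for (i in seq_along(ci)) {
    for (j in seq_along(cj)) {
      cij <- conf[i, j]
      if (cij > 0) num <- num + cij * log(cij * n / (ci[i] * cj[j]))
    }
  }
  den <- -sum(ci * log(ci / n)) - sum(cj * log(cj / n))
  if (den == 0) return(if (identical(unname(a), unname(b))) 1 else 0)
  unname(2 * num / den)
}

#' Mean pairwise partition stability
#'
#' The mean [nmi()] over all unordered pairs of partitions: 1 when repeated
#' runs always agree, near 0 when they are unrelated. Used as the stability
#' criterion of the adaptive edge-count scan.
#'
#' @param partitions list of at least two membership vectors over the same
#'   nodes.
#' @return scalar in `[0, 1]`.
#' @export
pairwise_stability <- function(partitions) {
  k <- length(partitions)
  if (k < 2) stop("need at least two partitions", call. = FALSE)
  tot <- 0; np <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      tot <- tot + nmi(partitions[[i]], partitions[[j]])
      np <- np + 1
    }
  }
  tot / np
}

# Apply f to every set partition of n elements, encoded as a restricted
# growth string (1-based). Enumeration order is lexicographic in the
# canonical labelling, so the first maximum found is the canonically
# smallest one.
enumerate_set_partitions <- function(n, f) {
  a <- integer(n)
  recurse <- function(i, maxl) {
    if (i > n) {
      f(a)
      return(invisible(NULL))
    }
    for (v in seq_len(maxl + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(maxl, v))
    }
  }
  recurse(1L, 0L)
  invisible(NULL)
}

#' Exhaustive modularity maximisation (test oracle)
#'
#' Enumerates every set partition of the node set and returns the one with
#' maximum modularity. Exponential in the Bell numbers, hence refused above
#' 10 nodes; it exists purely as an independent oracle for validating the
#' heuristic detector on small graphs. Ties resolve to the canonically
#' (lexicographically) smallest labelling.
#'
#' @param net a [binary_network()] with at most 10 nodes and >= 1 edge.
#' @return list with `membership` (canonical, named) and `q`.
#' @export
exhaustive_best_partition <- function(net) {
  if (net$n_nodes > 10) {
    stop("exhaustive search is limited to 10 nodes", call. = FALSE)
  }
  if (nrow(net$edges) == 0) {
    stop("modularity is undefined on an edgeless network", call. = FALSE)
  }
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  deg <- net$degree; ne <- nrow(net$edges)
  best_q <- -Inf
  best <- NULL
  enumerate_set_partitions(net$n_nodes, function(a) {
    q <- q_of_labels(a, e1, e2, deg, ne)
    if (q > best_q + 1e-12) {
      best_q <<- q
      best <<- a
    }
  })
  names(best) <- net$node_names
  list(membership = best, q = best_q)
}
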