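# Graph fixtures built in code.

two_triangles <- function() {
  binary_network(rbind(c(1, 2), c(1, 3), c(2, 3),
                       c(4, 5), c(4, 6), c(5, 6)))
}

two_triangles_bridged <- function() {
  binary_network(rbind(c(1, 2), c(1, 3), c(2, 3),
                       c(4, 5), c(4, 6), c(5, 6), c(3, 4)))
}

# Erdos-Renyi graph conditioned on connectivity (small n only).
random_connected_graph <- function(n, p_range = c(0.25, 0.7)) {
  repeat {
    p <- stats::runif(1, p_range[1], p_range[2])
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    net <- binary_network(pairs[keep, , drop = FALSE], n_nodes = n)
    if (igraph::is_connected(as_igraph(net))) return(net)
  }
}

random_membership <- function(n, k) {
  canonical_membership(sample.int(k, n, replace = TRUE))
}

# Direct-definition modularity: intra-edge fraction minus the
# degree-null expectation, computed without the e-matrix route.
modularity_direct <- function(net, membership) {
  m <- canonical_membership(membership)
  ne <- nrow(net$edges)
  intra <- sum(m[net$edges[, 1]] == m[net$edges[, 2]]) / ne
  expected <- sum(tapply(net$degree, m, sum)^2) / (2 * ne)^2
  intra - expected
}
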