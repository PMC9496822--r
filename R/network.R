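#' Construct an undirected binary network
#'
#' The elementary container for community detection: a simple undirected,
#' unweighted graph over named nodes. Edges are stored as a two-column
#' integer matrix of 1-based node indices with `a < b`; self-loops and
#' duplicates are rejected. An adjacency list is precomputed because the
#' genetic operators and the tabu search query neighbourhoods constantly.
#'
#' @param edges two-column matrix (or data.frame) of node indices or node
#'   names; may have zero rows.
#' @param n_nodes total number of nodes (required when `edges` uses indices
#'   and isolated nodes exist).
#' @param node_names optional character vector of unique node labels;
#'   defaults to `as.character(seq_len(n_nodes))`.
#' @return an object of class `binary_network` with elements `n_nodes`,
#'   `edges`, `node_names`, `adj` (list of integer neighbour vectors) and
#'   `degree`.
#' @examples
#' net <- binary_network(rbind(c(1, 2), c(2, 3)), n_nodes = 3)
#' net$degree
#' @export
binary_network <- function(edges, n_nodes = NULL, node_names = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0 && ncol(edges) != 2) {
    stop("`edges` must have two columns", call. = FALSE)
  }
  if (is.character(edges)) {
    if (is.null(node_names)) {
      node_names <- unique(as.vector(t(edges)))
    }
    idx <- matrix(match(edges, node_names), ncol = 2)
    if (anyNA(idx)) stop("edge refers to a node absent from `node_names`", call. = FALSE)
    edges <- idx
  }
  storage.mode(edges) <- "integer"
  if (is.null(n_nodes)) {
    n_nodes <- if (is.null(node_names)) {
      if (nrow(edges) == 0L) 0L else max(edges)
    } else {
      length(node_names)
    }
  }
  n_nodes <- as.integer(n_nodes)
  if (is.null(node_names)) node_names <- as.character(seq_len(n_nodes))
  if (length(node_names) != n_nodes || anyDuplicated(node_names)) {
    stop("`node_names` must be unique and of length `n_nodes`", call. = FALSE)
  }
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge index out of range", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed in a binary network", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed", call. = FALSE)
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  dimnames(edges) <- NULL
  adj <- rep(list(integer(0)), n_nodes)
  if (nrow(edges) > 0) {
    nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    for (k in names(nb)) adj[[as.integer(k)]] <- sort(nb[[k]])
  }
  structure(
    list(
      n_nodes = n_nodes,
      edges = edges,
      node_names = node_names,
      adj = adj,
      degree = vapply(adj, length, integer(1))
    ),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf(
    "binary_network: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)
  ))
  invisible(x)
}

#' Build a binary network from a 0/1 adjacency matrix
#'
#' @param mat square symmetric matrix; nonzero off-diagonal entries become
#'   edges. The diagonal is ignored.
#' @param node_names optional node labels; defaults to column names.
#' @return a [binary_network()].
#' @export
network_from_adjacency <- function(mat, node_names = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("adjacency matrix must be square", call. = FALSE)
  if (max(abs(mat - t(mat))) > 1e-8) {
    stop("adjacency matrix is not symmetric", call. = FALSE)
  }
  if (is.null(node_names)) node_names <- colnames(mat)
  idx <- which(upper.tri(mat) & mat != 0, arr.ind = TRUE)
  binary_network(idx, n_nodes = nrow(mat), node_names = node_names)
}

#' Dense adjacency matrix of a binary network
#' @param net a [binary_network()].
#' @return square 0/1 integer matrix with node names as dimnames.
#' @export
network_adjacency <- function(net) {
  a <- matrix(0L, net$n_nodes, net$n_nodes,
              dimnames = list(net$node_names, net$node_names))
  if (nrow(net$edges) > 0) {
    a[net$edges] <- 1L
    a[net$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  a
}

#' Convert to an igraph object
#'
#' Used for the greedy-modularity baseline and for independent cross-checks;
#' the detector itself operates on `binary_network` directly.
#' @param net a [binary_network()].
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$node_names)
  if (nrow(net$edges) > 0) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Read a network from disk
#'
#' Two plain-text dialects: `edgelist` (two tab-separated node names per
#' line, no header) and `matrix` (dense CSV of 0/1 with a header row of node
#' names). Node order is authoritative from the file: first appearance for
#' edge lists, header order for matrices. Duplicate edge lines are collapsed
#' with a warning; self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"matrix"`.
#' @return a [binary_network()].
#' @export
read_network <- function(path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", comment.char = "")
    if (ncol(tab) < 2) stop("edge list needs two tab-separated columns", call. = FALSE)
    a <- tab[[1]]; b <- tab[[2]]
    nodes <- unique(as.vector(rbind(a, b)))
    ia <- match(a, nodes); ib <- match(b, nodes)
    loops <- ia == ib
    if (any(loops)) {
      warning("dropping ", sum(loops), " self-loop(s)")
      ia <- ia[!loops]; ib <- ib[!loops]
    }
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key)) {
      warning("collapsing ", sum(duplicated(key)), " duplicate edge line(s)")
      keep <- !duplicated(key)
      ia <- ia[keep]; ib <- ib[keep]
    }
    binary_network(cbind(ia, ib), n_nodes = length(nodes), node_names = nodes)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    mat <- as.matrix(tab)
    network_from_adjacency(mat, node_names = colnames(tab))
  }
}

#' Write a network to disk
#'
#' @param net a [binary_network()].
#' @param path output file.
#' @param format `"edgelist"` (tab-separated node-name pairs) or `"matrix"`
#'   (dense CSV with node-name header).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- data.frame(a = net$node_names[net$edges[, 1]],
                     b = net$node_names[net$edges[, 2]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(network_adjacency(net)), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
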