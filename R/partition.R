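#' Canonicalise a community labelling
#'
#' Any vector of community labels (arbitrary integers, characters, ...) is
#' renumbered to consecutive integers `1..k` so that the community holding
#' the smallest node index gets label 1, the community holding the smallest
#' index not yet covered gets label 2, and so on. Two labellings describe
#' the same partition iff their canonical forms are identical.
#'
#' @param labels vector of per-node community labels.
#' @return integer vector in `1..k`, names preserved.
#' @examples
#' canonical_membership(c(5, 5, 9, 9))   # 1 1 2 2
#' @export
canonical_membership <- function(labels) {
  out <- match(labels, unique(labels))
  names(out) <- names(labels)
  out
}

#' Split a membership vector into groups
#' @param membership per-node community labels.
#' @return list of integer node-index vectors, one per community, ordered by
#'   canonical community number.
#' @export
membership_groups <- function(membership) {
  m <- canonical_membership(membership)
  unname(split(seq_along(m), m))
}

#' Community sizes of a membership vector
#' @param membership per-node community labels.
#' @return integer vector of group sizes in canonical community order.
#' @export
community_sizes <- function(membership) {
  tabulate(canonical_membership(membership))
}

#' Read / write partition files
#'
#' The on-disk dialect is a headerless TSV `node_name<TAB>community_id`
#' with communities numbered `0..k-1` by smallest member; in R the
#' partition is a named integer membership vector with communities
#' `1..k`. Round trips are exact.
#'
#' @param membership named (or unnamed) per-node community labels.
#' @param path file path.
#' @param node_names node labels used when `membership` is unnamed.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns a named canonical membership vector.
#' @export
write_partition <- function(membership, path, node_names = names(membership)) {
  if (is.null(node_names)) node_names <- as.character(seq_along(membership))
  m <- canonical_membership(membership)
  utils::write.table(
    data.frame(node = node_names, community = m - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_partition
#' @param net optional [binary_network()]; if given, node names in the file
#'   must match the network's and the result is ordered like the network.
#' @export
read_partition <- function(path, net = NULL) {
  if (file.size(path) == 0) stop("empty partition file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer"))
  m <- tab[[2]] + 1L
  names(m) <- tab[[1]]
  if (!is.null(net)) {
    if (!setequal(names(m), net$node_names) || length(m) != net$n_nodes) {
      stop("partition node names do not match the network", call. = FALSE)
    }
    m <- m[net$node_names]
  }
  canonical_membership(m)
}
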