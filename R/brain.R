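# Mapping detected modules onto the 32-channel 10-20 electrode layout and
# region-level statistics.

.regions_32 <- list(
  Frontal   = c("Fp1", "Fp2", "F3", "F4", "Fz", "AF3", "AF4"),
  Temporal  = c("F7", "T7", "P7", "FC5", "CP5", "F8", "T8", "P8", "FC6", "CP6"),
  Parietal  = c("P3", "P4", "Pz"),
  Occipital = c("O1", "O2", "Oz", "PO3", "PO4"),
  Central   = c("C3", "C4", "Cz", "CP1", "CP2", "FC1", "FC2")
)

#' The 32-channel 10-20 electrode-to-region map
#'
#' The standard 32-electrode subset of the international 10-20 system,
#' partitioned into five scalp regions: Frontal (7 electrodes), Temporal
#' (10), Parietal (3), Occipital (5) and Central (7). Electrode names are
#' matched case-insensitively ("FP1" and "Fp1" are the same electrode) and
#' stored in canonical capitalisation.
#'
#' @return object of class `electrode_map`: list with `region_members`
#'   (region -> electrode vector) and `region_of` (named vector,
#'   electrode -> region).
#' @export
electrode_map <- function() {
  members <- .regions_32
  stopifnot(identical(lengths(members),
                      c(Frontal = 7L, Temporal = 10L, Parietal = 3L,
                        Occipital = 5L, Central = 7L)))
  all_e <- unlist(members, use.names = FALSE)
  stopifnot(length(all_e) == 32, !anyDuplicated(toupper(all_e)))
  region_of <- stats::setNames(rep(names(members), lengths(members)), all_e)
  structure(list(region_members = members, region_of = region_of),
            class = "electrode_map")
}

# Case-insensitive electrode name canonicalisation against the map.
canonical_electrodes <- function(x, emap = electrode_map()) {
  canon <- names(emap$region_of)
  idx <- match(toupper(x), toupper(canon))
  if (anyNA(idx)) {
    stop("unknown electrode name(s): ",
         paste(x[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  canon[idx]
}

#' The k largest modules of a partition
#'
#' Communities ordered by node count, descending; ties are broken by the
#' smallest member name (alphabetically), so repeated calls are
#' deterministic. Asking for more modules than exist returns all of them
#' with a warning.
#'
#' @param membership named per-node community labels.
#' @param k number of modules to return.
#' @return list of character vectors of node names, largest first.
#' @export
top_k_modules <- function(membership, k) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  if (is.null(names(membership))) {
    names(membership) <- as.character(seq_along(membership))
  }
  groups <- lapply(membership_groups(membership),
                   function(g) sort(names(membership)[g]))
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, `[[`, character(1), 1))
  if (k > length(groups)) {
    warning("only ", length(groups), " communities exist; returning all")
    k <- length(groups)
  }
  groups[ord[seq_len(k)]]
}

#' Per-region electrode proportions
#'
#' For each scalp region, the percentage of that region's electrodes
#' present in `node_list`, reported to one decimal. Quantifies how much of
#' each brain region participates in a set of modules.
#'
#' @param node_list electrode names (any capitalisation).
#' @param emap an [electrode_map()].
#' @return data frame with columns `region`, `nodes` (comma-joined
#'   members present, in region order), `percent`.
#' @examples
#' region_proportions(c("Fp1", "AF3", "F3", "AF4", "Fz", "F4"))$percent[1]
#' # 85.7: six of the seven frontal electrodes
#' @export
region_proportions <- function(node_list, emap = electrode_map()) {
  nodes <- unique(canonical_electrodes(node_list, emap))
  rows <- lapply(names(emap$region_members), function(r) {
    members <- emap$region_members[[r]]
    present <- members[members %in% nodes]
    data.frame(region = r,
               nodes = paste(present, collapse = ","),
               percent = round(100 * length(present) / length(members), 1))
  })
  do.call(rbind, rows)
}

#' Nodes shared between two sets of modules
#'
#' The sorted intersection of the two sides' module unions: the electrodes
#' that participate in the given modules under both conditions.
#'
#' @param modules_a,modules_b lists of node-name vectors.
#' @return sorted character vector.
#' @export
common_nodes <- function(modules_a, modules_b) {
  sort(intersect(unique(unlist(modules_a)), unique(unlist(modules_b))))
}

#' Count edges running between communities
#'
#' @param net a [binary_network()].
#' @param membership per-node community labels covering the network.
#' @return integer count of inter-community edges.
#' @export
intermodule_edge_count <- function(net, membership) {
  if (length(membership) != net$n_nodes) {
    stop("membership length must equal the number of nodes", call. = FALSE)
  }
  m <- canonical_membership(membership)
  sum(m[net$edges[, 1]] != m[net$edges[, 2]])
}

#' Worked-example module electrode sets
#'
#' Published module memberships from a theta-band emotion study on the
#' 32-channel layout, bundled so the region analysis has a concrete worked
#' example: the electrodes of the three largest modules detected in one
#' subject's positive- and negative-valence functional networks, and the
#' 13 electrodes the two largest modules share across the two states.
#'
#' @return list with character vectors `positive_top3`, `negative_top3`
#'   and `common_top2`.
#' @export
emotion_study_modules <- function() {
  list(
    positive_top3 = c("Fp1", "AF3", "F3", "AF4", "Fz", "F4",
                      "CP6", "T7", "FC6", "FC5",
                      "Oz", "PO4",
                      "C4", "C3", "CP1", "CP2"),
    negative_top3 = c("Fp1", "AF3", "F3", "AF4", "Fz", "F4",
                      "CP6", "T7", "FC6", "F8", "FC5",
                      "Oz", "PO4", "O2",
                      "C4", "FC2", "C3", "CP1", "CP2"),
    common_top2 = c("Fp1", "AF3", "Oz", "C4", "CP6", "PO4", "F3",
                    "C3", "T7", "AF4", "Fz", "FC6", "CP2")
  )
}
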