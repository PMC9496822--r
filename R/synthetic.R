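# Seed-deterministic generators for everything the pipeline consumes:
# planted-partition graphs for the detection core, coupled-phase surrogate
# EEG for the signal front end, and the Zachary karate-club fixture.

#' Planted-partition random graph
#'
#' Nodes are divided into blocks of the given sizes; each within-block
#' pair becomes an edge with probability `p_in`, each cross-block pair
#' with probability `p_out < p_in`. The ground-truth block structure is
#' returned alongside the graph, so recovery can be scored with [nmi()].
#'
#' @param sizes integer vector of block sizes.
#' @param p_in,p_out within- and cross-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list with `network` (a [binary_network()]) and `membership`
#'   (named ground-truth labels).
#' @examples
#' g <- planted_partition_graph(c(8, 8, 8, 8), 0.9, 0.05, seed = 1)
#' g$network
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = NULL) {
  if (any(sizes < 1)) stop("block sizes must be positive", call. = FALSE)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_in, p_out)
  keep <- stats::runif(nrow(pairs)) < p
  net <- binary_network(pairs[keep, , drop = FALSE], n_nodes = n)
  truth <- canonical_membership(block)
  names(truth) <- net$node_names
  list(network = net, membership = truth)
}

#' Coupled-phase surrogate EEG signals
#'
#' Emulates multichannel narrow-band recordings with planted group
#' structure. Each group shares a latent phase process — a carrier
#' frequency inside `band` (groups are spread evenly across the band)
#' plus a slow random phase drift. Each channel follows its group's
#' latent phase: per sample, with probability `coupling` it copies the
#' phase exactly, otherwise an independent uniform phase perturbation is
#' added. The observed signal is the cosine of the channel phase plus
#' white Gaussian noise. Phase locking between same-group channels grows
#' monotonically with `coupling`; at `coupling = 1`, `noise_sd = 0`
#' same-group channels are identical.
#'
#' @param groups per-channel group labels (named to set channel names).
#' @param coupling within-group phase-copy probability in `[0, 1]`.
#' @param fs sampling rate in Hz.
#' @param duration_s epoch duration in seconds.
#' @param band carrier band `(low_hz, high_hz)`.
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a [signal_epoch()]; the planted labels are attached as
#'   attribute `"groups"`.
#' @export
coupled_phase_signals <- function(groups, coupling,
                                  fs = 512, duration_s = 60,
                                  band = c(4, 7), noise_sd = 0.1,
                                  seed = NULL) {
  if (coupling < 0 || coupling > 1) {
    stop("`coupling` must be in [0, 1]", call. = FALSE)
  }
  n_samp <- round(fs * duration_s)
  if (n_samp < 2) stop("duration_s * fs must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gl <- canonical_membership(groups)
  n_groups <- max(gl)
  n_ch <- length(gl)
  ch_names <- names(groups)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(n_ch))
  tt <- (seq_len(n_samp) - 1) / fs
  # one latent narrow-band phase walk per group
  f_g <- band[1] + (seq_len(n_groups) - 0.5) * diff(band) / n_groups
  latent <- matrix(0, n_groups, n_samp)
  for (g in seq_len(n_groups)) {
    drift <- cumsum(stats::rnorm(n_samp, 0, 0.03))
    latent[g, ] <- 2 * pi * f_g[g] * tt + drift
  }
  dat <- matrix(0, n_ch, n_samp)
  for (c in seq_len(n_ch)) {
    locked <- stats::runif(n_samp) < coupling
    jitter <- stats::runif(n_samp, -pi, pi)
    phase <- latent[gl[c], ] + ifelse(locked, 0, jitter)
    dat[c, ] <- cos(phase) + stats::rnorm(n_samp, 0, noise_sd)
  }
  ep <- signal_epoch(dat, fs, ch_names)
  attr(ep, "groups") <- stats::setNames(gl, ch_names)
  ep
}

#' Zachary karate-club fixture
#'
#' The 34-node, 78-edge karate-club friendship network with its observed
#' 2-faction split, bundled as a plain-text fixture. The classic
#' real-world benchmark for community detection: the faction split scores
#' modularity well above the 0.3 community-structure criterion.
#'
#' @return list with `network` (a [binary_network()]) and `membership`
#'   (the 2-faction labelling, named).
#' @export
karate_fixture <- function() {
  edges <- utils::read.table(
    system.file("extdata", "karate_edges.tsv", package = "mfmicd"),
    sep = "\t", colClasses = "character"
  )
  fact <- utils::read.table(
    system.file("extdata", "karate_factions.tsv", package = "mfmicd"),
    sep = "\t", colClasses = c("character", "integer")
  )
  nodes <- fact[[1]]
  net <- binary_network(as.matrix(edges), node_names = nodes)
  membership <- canonical_membership(stats::setNames(fact[[2]], nodes))
  list(network = net, membership = membership)
}
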