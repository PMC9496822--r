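# From multichannel time series to a binarized functional network:
# band-pass filter -> middle window -> analytic phase -> phase-locking
# value -> top-m edge binarization (with an adaptive edge-count scan).

#' Construct a multichannel signal epoch
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_names unique channel labels; default row names or
#'   `"ch1".."chN"`.
#' @return object of class `signal_epoch` with elements `data`, `fs`,
#'   `channel_names`.
#' @export
signal_epoch <- function(data, fs, channel_names = rownames(data)) {
  data <- as.matrix(data)
  if (nrow(data) < 2 || ncol(data) < 1) {
    stop("an epoch needs at least 2 channels and 1 sample", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data) || anyDuplicated(channel_names)) {
    stop("`channel_names` must be unique, one per channel", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "signal_epoch")
}

#' @export
print.signal_epoch <- function(x, ...) {
  cat(sprintf("signal_epoch: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read a signal epoch from CSV
#'
#' Expects rows = channels with a header row of channel names after
#' transposition-free storage: the file holds one channel per row, first
#' column the channel name, remaining columns samples.
#' @param path CSV file.
#' @param fs sampling rate in Hz (not stored in the CSV dialect).
#' @return a [signal_epoch()].
#' @export
read_signals <- function(path, fs) {
  tab <- utils::read.csv(path, header = FALSE, colClasses = "character")
  nm <- tab[[1]]
  dat <- apply(as.matrix(tab[, -1, drop = FALSE]), 2, as.numeric)
  signal_epoch(matrix(dat, nrow = length(nm)), fs = fs, channel_names = nm)
}

#' @rdname read_signals
#' @param epoch a [signal_epoch()] to write.
#' @export
write_signals <- function(epoch, path) {
  utils::write.table(
    cbind(epoch$channel_names, format(epoch$data, trim = TRUE, digits = 10)),
    path, sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Per-channel 4-pole Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the pass band is preserved with zero phase
#' distortion — essential ahead of phase-locking analysis, where filter
#' phase shifts would masquerade as connectivity.
#'
#' @param epoch a [signal_epoch()].
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @return filtered [signal_epoch()] of identical shape.
#' @export
bandpass_filter <- function(epoch, low_hz, high_hz) {
  nyq <- epoch$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(epoch$data, 1L, function(x) signal::filtfilt(bf, x)))
  signal_epoch(out, epoch$fs, epoch$channel_names)
}

#' Extract the middle third of an epoch
#'
#' Connectivity is unstable at the start and end of a recording; the
#' conventional remedy is to divide the trial into three equal parts and
#' keep only the middle one (samples `[floor(n/3), floor(2n/3))`,
#' 0-based half-open — e.g. seconds 21–40 of a 60 s trial).
#'
#' @param epoch a [signal_epoch()].
#' @param total_duration_s declared duration of the epoch in seconds; the
#'   epoch must actually span it.
#' @return the middle-third [signal_epoch()].
#' @export
extract_middle_window <- function(epoch, total_duration_s) {
  n <- ncol(epoch$data)
  if (abs(n / epoch$fs - total_duration_s) > 1 / epoch$fs) {
    stop(sprintf("epoch spans %.3f s, not the declared %.3f s",
                 n / epoch$fs, total_duration_s), call. = FALSE)
  }
  lo <- floor(n / 3) + 1L
  hi <- floor(2 * n / 3)
  signal_epoch(epoch$data[, lo:hi, drop = FALSE], epoch$fs,
               epoch$channel_names)
}

# Analytic signal via the FFT construction: zero the negative frequencies,
# double the positive ones, keep DC and (for even n) Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of each channel
#'
#' The analytic-signal (Hilbert-transform) phase of each channel, in
#' radians. Meaningful only for narrow-band signals, so call it after
#' [bandpass_filter()].
#'
#' @param epoch a narrow-band [signal_epoch()].
#' @return object of class `phase_series`: list with `phases` (channels x
#'   samples, radians), `fs`, `channel_names`.
#' @export
instantaneous_phase <- function(epoch) {
  rms <- sqrt(rowMeans(epoch$data^2))
  if (any(rms == 0)) {
    stop("degenerate all-zero channel: ",
         paste(epoch$channel_names[rms == 0], collapse = ", "),
         call. = FALSE)
  }
  ph <- t(apply(epoch$data, 1L, function(x) Arg(analytic_signal(x))))
  structure(list(phases = ph, fs = epoch$fs,
                 channel_names = epoch$channel_names),
            class = "phase_series")
}

#' Phase-locking value matrix
#'
#' For each channel pair the PLV is the magnitude of the time-averaged
#' unit phasor of the phase difference,
#' `|mean_t exp(i (phi_a(t) - phi_b(t)))|`: 1 for perfect phase locking,
#' near 0 (shrinking as `1/sqrt(N)`) for independent phases. `trim`
#' samples are dropped from each end first, to discard filter and
#' Hilbert edge transients.
#'
#' @param phases a `phase_series` from [instantaneous_phase()].
#' @param trim samples to drop at each end before averaging.
#' @return object of class `plv_matrix`: list with `values` (symmetric,
#'   unit diagonal, entries in `[0,1]`), `channel_names`,
#'   `n_samples_used`.
#' @export
compute_plv_matrix <- function(phases, trim = 0) {
  ph <- phases$phases
  if (any(!is.finite(ph))) stop("non-finite phases", call. = FALSE)
  n <- ncol(ph)
  if (n - 2 * trim < 2) stop("fewer than 2 samples after trimming", call. = FALSE)
  if (trim > 0) ph <- ph[, (trim + 1):(n - trim), drop = FALSE]
  z <- exp(1i * ph)
  # PLV_ab = |<z_a conj(z_b)>|; the Gram product gives all pairs at once.
  g <- (z %*% Conj(t(z))) / ncol(ph)
  v <- Mod(g)
  v[v > 1] <- 1
  diag(v) <- 1
  dimnames(v) <- list(phases$channel_names, phases$channel_names)
  structure(list(values = v, channel_names = phases$channel_names,
                 n_samples_used = ncol(ph)),
            class = "plv_matrix")
}

#' Binarize a connectivity matrix by edge count
#'
#' Keeps exactly the `m_edges` strongest off-diagonal pairs as edges of an
#' unweighted network. Fixing the edge count rather than a numeric
#' threshold makes networks comparable across subjects whose overall
#' connectivity levels differ. Ties are broken deterministically by
#' (descending value, then node pair order). A resulting edge set that is
#' empty or complete is almost certainly a mis-set threshold and triggers
#' a warning.
#'
#' @param plv a `plv_matrix` (or plain symmetric matrix).
#' @param m_edges number of edges to keep, in `0..n(n-1)/2`.
#' @return a [binary_network()].
#' @export
binarize_top_m <- function(plv, m_edges) {
  v <- if (inherits(plv, "plv_matrix")) plv$values else as.matrix(plv)
  nm <- if (inherits(plv, "plv_matrix")) plv$channel_names else colnames(v)
  n <- nrow(v)
  max_m <- n * (n - 1) / 2
  if (m_edges < 0 || m_edges > max_m) {
    stop("`m_edges` must be between 0 and n(n-1)/2", call. = FALSE)
  }
  ut <- which(upper.tri(v), arr.ind = TRUE)
  vals <- v[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m_edges)]
  net <- binary_network(ut[keep, , drop = FALSE], n_nodes = n,
                        node_names = nm)
  if (m_edges == 0 || m_edges == max_m) {
    warning("binarized network is ",
            if (m_edges == 0) "edgeless" else "complete",
            "; community structure cannot be meaningful")
  }
  net
}

#' Adaptive edge-count selection
#'
#' Scans candidate edge counts `m_min..m_max`; for each, binarizes the
#' connectivity matrix and runs the community detector `runs` times,
#' recording the mean modularity and the mean pairwise NMI across runs
#' (stability). The chosen count maximises stability, with ties broken by
#' higher mean Q and then by the smaller count. This adapts the threshold
#' to each subject's connectivity instead of fixing one numeric cutoff for
#' everyone.
#'
#' @param plv a `plv_matrix` (or symmetric matrix).
#' @param m_min,m_max edge-count range to scan.
#' @param runs detector restarts per candidate count (>= 2 for a defined
#'   stability).
#' @param seed integer seed; each candidate count derives its own
#'   sub-seed so the scan is reproducible.
#' @param ... further arguments passed to [mfmicd()] (e.g. smaller
#'   `pop_size` to speed the scan up).
#' @return list with `chosen_m` and `report` (data frame: `m`, `mean_q`,
#'   `stability_nmi`).
#' @export
adaptive_threshold_scan <- function(plv, m_min, m_max, runs = 5,
                                    seed = NULL, ...) {
  if (m_min > m_max) stop("`m_min` must not exceed `m_max`", call. = FALSE)
  ms <- seq.int(m_min, m_max)
  report <- data.frame(m = ms, mean_q = NA_real_, stability_nmi = NA_real_)
  for (i in seq_along(ms)) {
    net <- binarize_top_m(plv, ms[i])
    sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    fits <- vector("list", runs)
    if (!is.null(sub_seed)) set.seed(sub_seed)
    for (r in seq_len(runs)) {
      fits[[r]] <- mfmicd(net, seed = NULL, ...)
    }
    report$mean_q[i] <- mean(vapply(fits, `[[`, numeric(1), "q"))
    report$stability_nmi[i] <- if (runs >= 2) {
      pairwise_stability(lapply(fits, `[[`, "membership"))
    } else {
      1
    }
  }
  ord <- order(-report$stability_nmi, -report$mean_q, report$m)
  list(chosen_m = report$m[ord[1]], report = report)
}
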