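# Synchronization statistics: pairwise/network mean phase coherence and the
# pooled-interval bursting measure, plus the network-frequency summary.

#' Pairwise mean phase coherence (MPC)
#'
#' Each spike of the probe train is assigned a phase by its linear position
#' between the bracketing reference spikes: the reference spike that is
#' largest while strictly less than the probe time, and the one that is
#' smallest while greater than or equal to it (a probe spike coincident with
#' a reference spike therefore gets phase zero). The MPC is the magnitude of
#' the mean unit phasor over usable probe spikes: 1 for complete phase
#' locking at *any* common phase, near 0 for unrelated spiking. The measure
#' is not symmetric in its arguments.
#'
#' @param reference Sorted spike times of the reference train (ms); needs
#'   at least 2 spikes.
#' @param probe Sorted spike times of the probe train (ms). Spikes at or
#'   before the first reference spike, or after the last, are discarded.
#' @return MPC in \[0, 1\], or `NA` if the pair is undefined (fewer than 2
#'   reference spikes or no usable probe spikes).
#' @export
mpc_pair <- function(reference, probe) {
  if (length(reference) < 2) return(NA_real_)
  usable <- probe[probe > reference[1] & probe <= reference[length(reference)]]
  if (!length(usable)) return(NA_real_)
  i <- findInterval(usable, reference, left.open = TRUE)
  phase <- (usable - reference[i]) / (reference[i + 1] - reference[i])
  Mod(mean(exp(2i * pi * phase)))
}

#' Network mean phase coherence
#'
#' Mean of [mpc_pair()] over all ordered pairs (i, j), i != j (both
#' orderings enter, since the pair measure is asymmetric). Undefined pairs
#' are excluded from the average and counted.
#'
#' @param raster A `spike_raster` (restricted to its analysis window) or a
#'   plain list of spike-time vectors.
#' @param window Optional window override (ms).
#' @return Network MPC in \[0, 1\] with attribute `n_undefined`; `NA` if
#'   every pair is undefined.
#' @export
mpc_network <- function(raster, window = NULL) {
  tr <- if (inherits(raster, "spike_raster")) raster_window(raster, window)
        else raster
  n <- length(tr)
  vals <- numeric(0)
  n_undef <- 0L
  for (i in seq_len(n)) {
    ref <- tr[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      v <- mpc_pair(ref, tr[[j]])
      if (is.na(v)) n_undef <- n_undef + 1L else vals <- c(vals, v)
    }
  }
  out <- if (length(vals)) mean(vals) else NA_real_
  attr(out, "n_undefined") <- n_undef
  out
}

#' Bursting measure B
#'
#' Phase-zero synchrony statistic computed from the time-ordered pooled
#' spike list of all neurons. With `tau_i` the successive differences of
#' the pooled sorted spike times (across neurons) and `N` the number of
#' neurons,
#' \deqn{B = (\sqrt{\langle\tau^2\rangle - \langle\tau\rangle^2} /
#'           \langle\tau\rangle - 1) / \sqrt{N}.}
#' Pooled intervals from a synchronous raster have a much larger relative
#' dispersion than from an asynchronous one: B is about 0 for random
#' (Poisson) spiking and approaches 1 for perfect phase-zero locking at
#' large spike and neuron counts.
#'
#' @inheritParams mpc_network
#' @param n_neurons Number of neurons (defaults to the raster size; needed
#'   when a plain list is passed).
#' @return B (dimensionless); `NA` if fewer than 2 pooled spikes.
#' @export
burst_measure <- function(raster, window = NULL, n_neurons = NULL) {
  tr <- if (inherits(raster, "spike_raster")) raster_window(raster, window)
        else raster
  if (is.null(n_neurons)) n_neurons <- length(tr)
  pooled <- sort(unlist(tr, use.names = FALSE))
  if (length(pooled) < 2) return(NA_real_)
  tau <- diff(pooled)
  m1 <- mean(tau)
  if (m1 <= 0) return(NA_real_)
  v <- mean(tau^2) - m1^2
  (sqrt(max(v, 0)) / m1 - 1) / sqrt(n_neurons)
}

#' Mean network firing frequency
#'
#' Total spike count in the analysis window divided by (number of neurons
#' times window length).
#'
#' @inheritParams burst_measure
#' @return Frequency in Hz.
#' @export
mean_network_frequency <- function(raster, window = NULL, n_neurons = NULL) {
  tr <- if (inherits(raster, "spike_raster")) raster_window(raster, window)
        else raster
  if (is.null(n_neurons)) n_neurons <- length(tr)
  w <- if (inherits(raster, "spike_raster")) {
    if (is.null(window)) raster$window else window
  } else window
  if (is.null(w)) stop("window required when passing a plain spike list")
  total <- sum(vapply(tr, length, integer(1)))
  1000 * total / (n_neurons * (w[2] - w[1]))
}

#' Summary of the three network measures
#'
#' @inheritParams mpc_network
#' @return One-row data.frame: `frequency` (Hz), `B`, `mpc`,
#'   `mpc_undefined_pairs`, `window_start`, `window_end`.
#' @export
measure_raster <- function(raster, window = NULL) {
  w <- if (is.null(window)) raster$window else window
  m <- mpc_network(raster, window = w)
  data.frame(frequency = mean_network_frequency(raster, window = w),
             B = burst_measure(raster, window = w),
             mpc = as.numeric(m),
             mpc_undefined_pairs = attr(m, "n_undefined"),
             window_start = w[1], window_end = w[2])
}
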