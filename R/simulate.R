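# Fixed-step RK4 simulation front-ends over the compiled integrators.

.model_id <- function(params) if (inherits(params, "ml_params")) 1L else 2L

# flatten a neuron_params object into the vector layout the C++ side expects
.pack_params <- function(p) {
  if (inherits(p, "ml_params")) {
    as.numeric(c(p$cm, p$g_l, p$e_l, p$g_ca, p$e_ca, p$g_k, p$e_k,
                 p$v1, p$v2, p$v3, p$v4, p$phi_w))
  } else {
    as.numeric(c(p$cm, p$g_na, p$e_na, p$g_kdr, p$e_k, p$g_ks, p$g_l, p$e_l,
                 p$m_half, p$m_slope, p$h_half, p$h_slope,
                 p$tau_h0, p$tau_h1, p$tau_h_half, p$tau_h_slope,
                 p$n_half, p$n_slope, p$tau_n0, p$tau_n1, p$tau_n_half,
                 p$tau_n_slope, p$z_half, p$z_slope, p$tau_z, p$r_h, p$r_z))
  }
}

#' Integrate a single neuron
#'
#' Fourth-order Runge-Kutta at fixed step `dt` (default: the model's shipped
#' step, 0.10 ms for Morris-Lecar and 0.05 ms for the pyramidal model), with
#' online spike detection at the -20 mV threshold. The applied current is
#' `i_const` plus optional square pulses (`pulse_onsets`/`pulse_amp`/
#' `pulse_dur`), summed additively when pulses overlap.
#'
#' @param params A `neuron_params` object.
#' @param i_const Constant applied current (uA/cm^2).
#' @param state0 Initial state; defaults to the resting state at `i_const`
#'   (or at 0 if there is none).
#' @param dt Integration step (ms).
#' @param t_end Simulation end time (ms).
#' @param pulse_onsets Sorted onset times of square current pulses (ms).
#' @param pulse_amp,pulse_dur Pulse amplitude (uA/cm^2) and duration (ms).
#' @param keep_trace Keep the full sampled trajectory (time + state columns).
#' @return List with `spikes` (interpolated upward-crossing times), `peaks`
#'   (spike-peak times), `final_state`, `peak_state` (grid state at the last
#'   spike peak), and optionally `trace`.
#' @export
integrate_single <- function(params, i_const = 0, state0 = NULL, dt = NULL,
                             t_end = 1000, pulse_onsets = numeric(0),
                             pulse_amp = 0, pulse_dur = 0,
                             keep_trace = FALSE) {
  if (is.null(dt)) dt <- params$dt
  stopifnot(dt > 0, t_end > 0)
  if (is.null(state0)) {
    state0 <- tryCatch(rest_state(params, i_const),
                       error = function(e) rest_state(params, 0))
  }
  .integrate_single_cpp(.model_id(params), .pack_params(params),
                        as.numeric(state0), dt, t_end, i_const,
                        as.numeric(pulse_onsets), pulse_amp, pulse_dur,
                        params$spike_threshold, keep_trace)
}

#' Detect spikes in a uniformly sampled voltage trace
#'
#' One spike per upward crossing of `threshold`; after a crossing, a new
#' spike requires the voltage to first fall back below threshold. Crossing
#' times are linearly interpolated between samples.
#'
#' @param v Voltage samples (mV), uniform spacing.
#' @param dt Sample spacing (ms).
#' @param threshold Detection threshold (mV), default -20.
#' @param t0 Time of the first sample (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, dt, threshold = -20, t0 = 0) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  below <- v < threshold
  up <- which(below[-n] & !below[-1])
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  # the first sample can only start a spike if the trace begins below
  # threshold; crossings after that are separated by a downward re-crossing
  # by construction of `up`
  t0 + (up - 1 + frac) * dt
}

#' Spike raster container
#'
#' Per-neuron sorted spike-time lists with the simulation duration and the
#' analysis window (defaults 3000-10000 ms: the initial transient is
#' disregarded).
#'
#' @param spikes List of numeric vectors, one per neuron, strictly
#'   increasing spike times in ms.
#' @param duration Simulation duration (ms).
#' @param window Analysis window `c(start, end)` in ms.
#' @return Object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, duration, window = c(3000, 10000)) {
  stopifnot(is.list(spikes), duration > 0, length(window) == 2,
            window[1] < window[2])
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s)) {
      if (any(diff(s) <= 0)) stop("spike times not strictly increasing for neuron ", i)
      if (s[1] < 0 || s[length(s)] > duration + 1e-9)
        stop("spike times outside [0, duration] for neuron ", i)
    }
  }
  structure(list(spikes = spikes, duration = duration,
                 window = as.numeric(window), n = length(spikes)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ns <- vapply(x$spikes, length, integer(1))
  cat(sprintf("spike_raster: %d neurons, %d spikes, %.0f ms (window %.0f-%.0f ms)\n",
              x$n, sum(ns), x$duration, x$window[1], x$window[2]))
  invisible(x)
}

#' Restrict a raster to its analysis window
#' @param raster A `spike_raster`.
#' @param window Optional window override `c(start, end)` (ms).
#' @return List of per-neuron spike vectors clipped to the window.
#' @export
raster_window <- function(raster, window = NULL) {
  w <- if (is.null(window)) raster$window else window
  lapply(raster$spikes, function(s) s[s >= w[1] & s <= w[2]])
}

#' Synapse specification
#'
#' All synapses in a run share one weight `s`. The shipped kernel is a
#' current-based alpha function `s * (t/tau) * exp(1 - t/tau)` (peak `s`
#' uA/cm^2 at `t = tau` after the presynaptic spike); inputs sum linearly.
#' Presynaptic spikes are detected when the membrane voltage breaches
#' -20 mV, and delivery is bound to the integration grid with a latency of
#' exactly one step.
#'
#' @param s Synaptic weight (peak current, uA/cm^2); `s >= 0`.
#' @param tau Kernel time-to-peak (ms).
#' @param kernel Kernel name; `"alpha"` is the only shipped implementation.
#' @return Object of class `synapse_spec`.
#' @export
synapse_spec <- function(s = 0, tau = NULL, kernel = "alpha") {
  if (is.null(tau)) tau <- model_parameters()$network$synapse_tau
  stopifnot(s >= 0, tau > 0)
  if (!identical(kernel, "alpha"))
    stop("unknown synaptic kernel: ", kernel)
  structure(list(s = s, tau = tau, kernel = kernel, threshold = -20),
            class = "synapse_spec")
}

#' Integrate a coupled network
#'
#' All-excitatory network of identical model neurons on a directed graph.
#' Each neuron receives its own constant current (and, optionally, its own
#' Poisson square-pulse train); when a neuron's voltage breaches -20 mV its
#' synaptic kernel is triggered in every target at the next integration
#' step.
#'
#' @param params A `neuron_params` object shared by all neurons.
#' @param adjacency N x N directed 0/1 matrix (or an `adjacency` object from
#'   [watts_strogatz()]); entry (i, j) = 1 means i synapses onto j.
#' @param synapse A [synapse_spec()].
#' @param drive List with `i_const` (length-N currents) and optionally
#'   `pulse_onsets` (length-N list of sorted onset times), `pulse_amp`,
#'   `pulse_dur`.
#' @param state0 N x dim initial-state matrix; default: every neuron at the
#'   resting state of its own drive current (sub-threshold) or of zero
#'   current.
#' @param dt Step (ms), default the model's shipped step.
#' @param t_end Duration (ms), default 10000.
#' @param window Analysis window, default `c(3000, t_end)`.
#' @return A `spike_raster` (with `final_state` attached as an attribute).
#' @export
integrate_network <- function(params, adjacency, synapse, drive,
                              state0 = NULL, dt = NULL, t_end = 10000,
                              window = NULL) {
  if (inherits(adjacency, "adjacency")) adjacency <- adjacency$matrix
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
  i_const <- drive$i_const
  if (length(i_const) == 1) i_const <- rep(i_const, n)
  if (length(i_const) != n)
    stop("drive$i_const length does not match adjacency size")
  if (is.null(dt)) dt <- params$dt
  if (is.null(window)) window <- c(3000, t_end)

  if (is.null(state0)) {
    # rest state of each neuron's own drive; +1 mV nudge so that neurons
    # whose fixed point is unstable (supra-threshold drive) actually leave
    # it -- the exact equilibrium is invariant under the integrator
    state0 <- t(vapply(i_const, function(ic) {
      st <- tryCatch(rest_state(params, ic),
                     error = function(e) rest_state(params, 0))
      st[1] <- st[1] + 1
      st
    }, numeric(if (inherits(params, "ml_params")) 2 else 4)))
  }
  pulses <- drive$pulse_onsets
  if (is.null(pulses)) pulses <- list()
  pulse_amp <- if (is.null(drive$pulse_amp)) 0 else drive$pulse_amp
  pulse_dur <- if (is.null(drive$pulse_dur)) 0 else drive$pulse_dur

  # adjacency -> CSR-style target list grouped by source
  targ <- lapply(seq_len(n), function(i) which(adjacency[i, ] != 0) - 1L)
  offsets <- c(0L, cumsum(vapply(targ, length, integer(1))))
  res <- .integrate_network_cpp(.model_id(params), .pack_params(params),
                                state0, as.numeric(i_const), pulses,
                                pulse_amp, pulse_dur,
                                as.integer(unlist(targ)),
                                as.integer(offsets), synapse$s, synapse$tau,
                                dt, t_end, params$spike_threshold)
  r <- spike_raster(res$spikes, duration = t_end, window = window)
  attr(r, "final_state") <- res$final_state
  r
}

#' Write / read a spike raster as CSV
#'
#' Columns `neuron_id, spike_time_ms`, sorted by time. The header carries
#' the raster geometry in comment lines so the round trip is lossless.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `read_raster_csv` returns the reconstructed `spike_raster`.
#' @export
write_raster_csv <- function(raster, path) {
  ns <- vapply(raster$spikes, length, integer(1))
  df <- data.frame(neuron_id = rep(seq_along(raster$spikes), ns),
                   spike_time_ms = unlist(raster$spikes))
  if (nrow(df)) df <- df[order(df$spike_time_ms, df$neuron_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d duration=%.10g window=%.10g,%.10g",
                     raster$n, raster$duration, raster$window[1],
                     raster$window[2]), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# n="))
    stop("malformed raster file (missing geometry header): ", path)
  m <- regmatches(hdr, regexec(
    "^# n=(\\d+) duration=([0-9.eE+-]+) window=([0-9.eE+-]+),([0-9.eE+-]+)$",
    hdr))[[1]]
  if (length(m) != 5) stop("malformed raster header in ", path)
  n <- as.integer(m[2])
  df <- read.csv(path, skip = 1)
  if (!identical(names(df), c("neuron_id", "spike_time_ms")))
    stop("malformed raster CSV columns in ", path)
  if (nrow(df) && (any(!is.finite(df$spike_time_ms)) ||
                   any(!is.finite(df$neuron_id))))
    stop("non-numeric entries in raster CSV ", path)
  spikes <- rep(list(numeric(0)), n)
  if (nrow(df)) {
    sp <- split(df$spike_time_ms, factor(df$neuron_id, levels = seq_len(n)))
    spikes <- unname(lapply(sp, function(s) sort(as.numeric(s))))
  }
  spike_raster(spikes, duration = as.numeric(m[3]),
               window = c(as.numeric(m[4]), as.numeric(m[5])))
}
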