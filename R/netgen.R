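# Synthetic-input generation: small-world graphs, heterogeneous constant
# drive, Poisson square-pulse drive, and fixture rasters of known synchrony.

# run code under a local RNG stream without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# deterministic per-component seed streams from one master seed
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
          else as.double(k)
    s <- (s * 48271 + kk + 1) %% 2147483629
  }
  as.integer(s)
}

#' Directed Watts-Strogatz small-world adjacency
#'
#' Starts from a 1-D ring with periodic boundaries in which every neuron is
#' directionally coupled to its nearest neighbours, then rewires each
#' outgoing edge independently with probability `p` to a uniformly random
#' target that is neither the source nor an existing target of that source.
#' `p = 0` gives the local lattice, `p = 1` a random graph; the edge count
#' is invariant under rewiring.
#'
#' @param n Number of neurons.
#' @param k Connectivity radius. With `mode = "radius"` (default) each
#'   neuron projects to the k nearest neighbours *on each side* (out-degree
#'   2k); `mode = "total"` projects to the k nearest neighbours in total.
#' @param p Rewiring probability in \[0, 1\].
#' @param seed RNG seed.
#' @param mode `"radius"` or `"total"` (see `k`).
#' @return Object of class `adjacency`: list with `matrix` (n x n 0/1,
#'   zero diagonal) and construction metadata.
#' @export
watts_strogatz <- function(n, k, p, seed, mode = c("radius", "total")) {
  mode <- match.arg(mode)
  stopifnot(n >= 3, k >= 1, p >= 0, p <= 1)
  offs <- if (mode == "radius") c(seq_len(k), -seq_len(k))
          else { m <- k
                 o <- integer(0)
                 side <- 1L
                 d <- 1L
                 while (length(o) < m) { o <- c(o, side * d)
                   if (side == -1L) d <- d + 1L
                   side <- -side }
                 o }
  if (max(abs(offs)) > (n - 1) %/% 2)
    stop("connectivity radius too large for ring of size ", n)
  A <- matrix(0L, n, n)
  for (o in offs) {
    tgt <- ((seq_len(n) - 1 + o) %% n) + 1
    A[cbind(seq_len(n), tgt)] <- 1L
  }
  with_seed(seed, {
    for (i in seq_len(n)) {
      for (j in which(A[i, ] == 1L)) {
        if (runif(1) < p) {
          free <- which(A[i, ] == 0L)
          free <- free[free != i]
          if (length(free)) {
            A[i, j] <- 0L
            A[i, sample(free, 1)] <- 1L
          }
        }
      }
    }
  })
  structure(list(matrix = A, n = n, k = k, p = p, seed = seed, mode = mode),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("adjacency: n=%d k=%d p=%.3f (%s mode, %d edges, seed %d)\n",
              x$n, x$k, x$p, x$mode, sum(x$matrix), x$seed))
  invisible(x)
}

#' Export an adjacency as an edge-list CSV
#' @param adj An `adjacency` object.
#' @param path File path; columns `source,target` (1-based).
#' @export
write_edgelist_csv <- function(adj, path) {
  idx <- which(adj$matrix != 0, arr.ind = TRUE)
  df <- data.frame(source = idx[, 1], target = idx[, 2])
  df <- df[order(df$source, df$target), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# single-neuron steady frequency (Hz) at constant current, from rest
# (nudged 1 mV off equilibrium: exact fixed points, stable or not, are
# invariant under the integrator)
.steady_freq <- function(params, i_const, settle = 2000, measure = 3000,
                         dt = NULL) {
  st0 <- tryCatch(rest_state(params, i_const),
                  error = function(e) rest_state(params, 0))
  st0[1] <- st0[1] + 1
  r <- integrate_single(params, i_const = i_const, state0 = st0, dt = dt,
                        t_end = settle + measure)
  sp <- r$spikes[r$spikes >= settle]
  if (length(sp) < 3) return(0)
  # require firing to persist to the end of the run
  if (sp[length(sp)] < settle + 0.75 * measure) return(0)
  isi <- diff(sp)
  1000 / mean(utils::tail(isi, 3))
}

#' Heterogeneous constant drive calibrated to a target frequency spread
#'
#' Draws per-neuron constant currents from a Gaussian centred on
#' `mean_current` whose SD is calibrated, through the local slope of the
#' f-I curve, so that the SD of the neurons' intrinsic firing frequencies
#' equals `target_freq_sd` (default 1 Hz).
#'
#' @param params A `neuron_params` object.
#' @param mean_current Mean applied current (uA/cm^2); must be above
#'   rheobase.
#' @param target_freq_sd Target SD of intrinsic frequencies (Hz).
#' @param n Number of neurons.
#' @param seed RNG seed.
#' @return Numeric vector of currents with attributes `current_sd` and
#'   `fi_slope` (Hz per uA/cm^2).
#' @export
gaussian_drive <- function(params, mean_current, target_freq_sd = 1, n,
                           seed) {
  key <- paste(params$variant, format(mean_current, digits = 12),
               params[["phi_w"]], params[["r_z"]], params[["r_h"]],
               sep = "|")
  cache <- .prcsync_env$fi_slope_cache
  if (is.null(cache)) cache <- list()
  if (!is.null(cache[[key]])) {
    slope <- cache[[key]]
  } else {
    f0 <- .steady_freq(params, mean_current)
    if (f0 <= 0) stop("mean_current ", mean_current, " is below rheobase")
    di <- max(0.02 * abs(mean_current), 1e-3)
    f_hi <- .steady_freq(params, mean_current + di)
    f_lo <- .steady_freq(params, mean_current - di)
    if (f_lo <= 0) { f_lo <- f0; di <- di / 2 } # one-sided at the edge
    slope <- (f_hi - f_lo) / (2 * di)
    if (slope <= 0) stop("non-positive f-I slope at mean_current")
    cache[[key]] <- slope
    .prcsync_env$fi_slope_cache <- cache
  }
  current_sd <- target_freq_sd / slope
  cur <- with_seed(seed, rnorm(n, mean_current, current_sd))
  structure(cur, current_sd = current_sd, fi_slope = slope)
}

#' Poisson square-pulse drive
#'
#' Independent homogeneous Poisson trains of square current pulses per
#' neuron on top of a constant sub-threshold baseline; overlapping pulses
#' sum additively. Defaults for amplitude (30 uA/cm^2) and duration
#' (0.2 ms) come from the shipped parameter file; with these values at
#' least two successive pulses are required to fire a resting pyramidal
#' cell.
#'
#' @param f_noise Mean pulse rate per neuron (Hz), `>= 0`.
#' @param t_end Duration covered by the trains (ms).
#' @param n Number of neurons.
#' @param seed RNG seed.
#' @param baseline Constant baseline current (uA/cm^2).
#' @param amplitude,duration Pulse amplitude (uA/cm^2) and width (ms).
#' @return Drive list (`i_const`, `pulse_onsets`, `pulse_amp`, `pulse_dur`)
#'   ready for [integrate_network()].
#' @export
poisson_pulse_drive <- function(f_noise, t_end, n, seed, baseline = 0,
                                amplitude = NULL, duration = NULL) {
  stopifnot(f_noise >= 0, t_end > 0, n >= 1)
  stim <- model_parameters()$stimulus$poisson_pulse
  if (is.null(amplitude)) amplitude <- stim$amplitude
  if (is.null(duration)) duration <- stim$duration
  rate_ms <- f_noise / 1000
  onsets <- with_seed(seed, lapply(seq_len(n), function(i) {
    if (rate_ms == 0) return(numeric(0))
    m <- stats::rpois(1, rate_ms * t_end)
    sort(runif(m, 0, t_end))
  }))
  list(i_const = rep(baseline, n), pulse_onsets = onsets,
       pulse_amp = amplitude, pulse_dur = duration, f_noise = f_noise)
}

#' Fixture raster with tunable synchrony
#'
#' Blends a common periodic spike template (each neuron keeps each template
#' spike with probability `sync_fraction`, jittered by a per-spike Gaussian
#' of SD `jitter_sd`) with independent Poisson background at the remaining
#' rate, giving rasters of known, controllable synchrony for testing the
#' measures.
#'
#' @param n Neurons.
#' @param rate Per-neuron mean firing rate (Hz).
#' @param jitter_sd Jitter SD on template spikes (ms).
#' @param sync_fraction Fraction of spikes locked to the template, in
#'   \[0, 1\].
#' @param seed RNG seed.
#' @param duration Raster duration (ms).
#' @param window Analysis window (ms).
#' @return A `spike_raster`.
#' @export
fixture_raster <- function(n, rate, jitter_sd, sync_fraction, seed,
                           duration = 10000, window = c(3000, 10000)) {
  stopifnot(jitter_sd >= 0, sync_fraction >= 0, sync_fraction <= 1,
            rate > 0)
  period <- 1000 / rate
  template <- seq(period / 2, duration, by = period)
  pois_rate_ms <- rate * (1 - sync_fraction) / 1000
  spikes <- with_seed(seed, lapply(seq_len(n), function(i) {
    keep <- runif(length(template)) < sync_fraction
    tpl <- template[keep]
    if (jitter_sd > 0 && length(tpl))
      tpl <- tpl + rnorm(length(tpl), 0, jitter_sd)
    m <- stats::rpois(1, pois_rate_ms * duration)
    bg <- runif(m, 0, duration)
    s <- sort(c(tpl, bg))
    s <- s[s >= 0 & s <= duration]
    s[!duplicated(s)]
  }))
  spike_raster(spikes, duration = duration, window = window)
}
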