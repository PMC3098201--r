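# Orchestration of the studies: PRC-vs-frequency families, gating-rate
# scans, network sweeps under constant-Gaussian and Poisson-pulse drive,
# difference heatmaps, and time-to-synchronization.

#' PRC family across drive currents
#'
#' One PRC per current level, with a per-level summary of firing frequency,
#' maximum advance and delay depth. For a Type II cell the delay depth
#' shrinks with frequency much faster than the advances do; Type I families
#' stay advance-only at every level.
#'
#' @param params A `neuron_params` object.
#' @param current_levels Applied currents (uA/cm^2), all above rheobase.
#' @param ... Passed to [compute_prc()].
#' @return List with `prcs` (list of `prc_curve`) and `summary`
#'   (data.frame: current, frequency, max_advance, delay_depth).
#' @export
prc_frequency_family <- function(params, current_levels, ...) {
  prcs <- lapply(current_levels, function(i) compute_prc(params, i, ...))
  summary <- data.frame(
    current = current_levels,
    frequency = vapply(prcs, function(p) attr(p, "frequency"), numeric(1)),
    max_advance = vapply(prcs, max_advance, numeric(1)),
    delay_depth = vapply(prcs, delay_depth, numeric(1)))
  list(prcs = prcs, summary = summary)
}

#' Delay depth and frequency over a gating-rate grid
#'
#' Scans one gating-rate knob (`phi_w`, `r_z` or `r_h`) against applied
#' current, reporting the PRC delay depth and firing frequency for every
#' grid cell (cells where the oscillation dies are reported with
#' `frequency = 0` and `delay_depth = NA`).
#'
#' @param params A `neuron_params` object.
#' @param i_app_levels Applied currents (uA/cm^2).
#' @param knob One of `"phi_w"`, `"r_z"`, `"r_h"`.
#' @param knob_values Values of the knob to scan.
#' @param ... Passed to [compute_prc()].
#' @return data.frame: knob, i_app, delay_depth, frequency.
#' @export
rate_scan <- function(params, i_app_levels, knob, knob_values, ...) {
  if (!knob %in% c("phi_w", "r_z", "r_h"))
    stop("knob must be one of phi_w, r_z, r_h")
  grid <- expand.grid(knob = knob_values, i_app = i_app_levels,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    p2 <- params
    p2[[knob]] <- grid$knob[r]
    validate_params(p2)
    f <- .steady_freq(p2, grid$i_app[r])
    d <- if (f > 0) delay_depth(compute_prc(p2, grid$i_app[r], ...))
         else NA_real_
    c(frequency = f, delay_depth = d)
  })
  grid$delay_depth <- vapply(res, `[[`, numeric(1), "delay_depth")
  grid$frequency <- vapply(res, `[[`, numeric(1), "frequency")
  names(grid)[1] <- knob
  grid
}

# run one network cell under constant-Gaussian drive and measure it
.run_constant_cell <- function(params, p_rewire, mean_current, s, n, k,
                               seed, t_end, window, freq_sd) {
  adj <- watts_strogatz(n, k, p_rewire, seed = derive_seed(seed, "adj"))
  cur <- gaussian_drive(params, mean_current, target_freq_sd = freq_sd,
                        n = n, seed = derive_seed(seed, "drive"))
  raster <- integrate_network(params, adj, synapse_spec(s),
                              drive = list(i_const = as.numeric(cur)),
                              t_end = t_end, window = window)
  measure_raster(raster)
}

#' Network sweep under constant-Gaussian drive
#'
#' Grid of (re-wiring p) x (mean drive current), each cell an N-neuron
#' excitatory small-world network whose per-neuron constant currents come
#' from [gaussian_drive()] (intrinsic-frequency SD 1 Hz). Reports B, MPC
#' and mean network frequency per cell and replicate.
#'
#' @param params A `neuron_params` object (or variant string).
#' @param p_values Re-wiring probabilities.
#' @param mean_currents Mean drive currents (uA/cm^2), above rheobase.
#' @param s Synaptic weight (single value).
#' @param n,k Network size and connectivity radius.
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @param replicates Replicates per cell.
#' @param t_end,window Simulation horizon and analysis window (ms).
#' @param freq_sd Target intrinsic-frequency SD (Hz).
#' @return Object of class `sweep_result`: data.frame with one row per
#'   (p, drive, replicate): p, drive, replicate, seed, frequency, B, mpc.
#' @export
constant_drive_sweep <- function(params, p_values, mean_currents, s,
                                 n = 200, k = 4, seed = 1, replicates = 1,
                                 t_end = 10000, window = NULL,
                                 freq_sd = 1) {
  if (is.character(params)) params <- neuron_params(params)
  if (is.null(window)) window <- c(3000, t_end)
  grid <- expand.grid(p = p_values, drive = mean_currents,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cell_seed <- derive_seed(seed, "cell", match(grid$p[r], p_values),
                             match(grid$drive[r], mean_currents),
                             grid$replicate[r])
    m <- .run_constant_cell(params, grid$p[r], grid$drive[r], s, n, k,
                            cell_seed, t_end, window, freq_sd)
    cbind(grid[r, , drop = FALSE], seed = cell_seed, m[1:3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(variant = params$variant, s = s, n = n, k = k,
                              t_end = t_end, window = window,
                              freq_sd = freq_sd, master_seed = seed)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' High-minus-low-frequency difference grids over (s, p)
#'
#' Runs the constant-drive network at a high and a low mean current over a
#' (synaptic weight) x (re-wiring) grid and subtracts the low-frequency
#' values of B and MPC from the high-frequency values. A Type II network
#' shows a contiguous negative-difference region where it synchronizes; a
#' Type I network stays near zero or slightly positive.
#'
#' @param params `neuron_params` or variant string.
#' @param p_values,s_values Grid axes.
#' @param high_current,low_current The two drive levels (uA/cm^2).
#' @inheritParams constant_drive_sweep
#' @return List of matrices (`B_high`, `B_low`, `B_diff`, `mpc_high`,
#'   `mpc_low`, `mpc_diff`, `freq_high`, `freq_low`), rows indexed by
#'   `s_values`, columns by `p_values`.
#' @export
coupling_rewire_heatmap <- function(params, p_values, s_values,
                                    high_current, low_current, n = 200,
                                    k = 4, seed = 1, replicates = 1,
                                    t_end = 10000, window = NULL,
                                    freq_sd = 1) {
  if (is.character(params)) params <- neuron_params(params)
  if (is.null(window)) window <- c(3000, t_end)
  run_level <- function(current, tag) {
    g <- array(NA_real_, dim = c(length(s_values), length(p_values), 3),
               dimnames = list(s_values, p_values, c("B", "mpc", "freq")))
    for (si in seq_along(s_values)) for (pi in seq_along(p_values)) {
      acc <- matrix(NA_real_, replicates, 3)
      for (rep in seq_len(replicates)) {
        cell_seed <- derive_seed(seed, tag, si, pi, rep)
        m <- .run_constant_cell(params, p_values[pi], current,
                                s_values[si], n, k, cell_seed, t_end,
                                window, freq_sd)
        acc[rep, ] <- c(m$B, m$mpc, m$frequency)
      }
      g[si, pi, ] <- colMeans(acc)
    }
    g
  }
  hi <- run_level(high_current, "hi")
  lo <- run_level(low_current, "lo")
  # keep matrix shape even for single-row/column grids
  pick <- function(g, what)
    matrix(g[, , what], length(s_values), length(p_values),
           dimnames = list(s_values, p_values))
  list(B_high = pick(hi, "B"), B_low = pick(lo, "B"),
       B_diff = pick(hi, "B") - pick(lo, "B"),
       mpc_high = pick(hi, "mpc"), mpc_low = pick(lo, "mpc"),
       mpc_diff = pick(hi, "mpc") - pick(lo, "mpc"),
       freq_high = pick(hi, "freq"), freq_low = pick(lo, "freq"),
       p_values = p_values, s_values = s_values,
       high_current = high_current, low_current = low_current)
}

#' Network sweep under Poisson square-pulse drive
#'
#' Stochastic-drive analogue of [constant_drive_sweep()]: every neuron gets
#' the same sub-threshold baseline plus an independent Poisson train of
#' square current pulses at rate `f_noise`; network frequency is modulated
#' by `f_noise` (and is largely independent of p). If several `s_values`
#' are given, difference grids between the highest and lowest `f_noise` are
#' attached.
#'
#' @param params `neuron_params` or variant string (pyramidal models).
#' @param p_values,f_noise_values,s_values Grid axes.
#' @param baseline Sub-threshold baseline current; default the shipped
#'   per-type value.
#' @inheritParams constant_drive_sweep
#' @return `sweep_result` data.frame (p, f_noise, s, replicate, seed,
#'   frequency, B, mpc) with difference grids in attribute `diff` when
#'   more than one noise rate is scanned.
#' @export
stochastic_drive_sweep <- function(params, p_values, f_noise_values,
                                   s_values, baseline = NULL, n = 200,
                                   k = 4, seed = 1, replicates = 1,
                                   t_end = 10000, window = NULL) {
  if (is.character(params)) params <- neuron_params(params)
  if (is.null(window)) window <- c(3000, t_end)
  if (is.null(baseline)) {
    stim <- model_parameters()$stimulus$poisson_pulse
    baseline <- if (params$type_label == "I") stim$baseline_type1
                else stim$baseline_type2
  }
  grid <- expand.grid(p = p_values, f_noise = f_noise_values, s = s_values,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cell_seed <- derive_seed(seed, "stoch", match(grid$p[r], p_values),
                             match(grid$f_noise[r], f_noise_values),
                             match(grid$s[r], s_values), grid$replicate[r])
    adj <- watts_strogatz(n, k, grid$p[r],
                          seed = derive_seed(cell_seed, "adj"))
    drv <- poisson_pulse_drive(grid$f_noise[r], t_end = t_end, n = n,
                               seed = derive_seed(cell_seed, "drive"),
                               baseline = baseline)
    raster <- integrate_network(params, adj, synapse_spec(grid$s[r]),
                                drive = drv, t_end = t_end,
                                window = window)
    m <- measure_raster(raster)
    cbind(grid[r, , drop = FALSE], seed = cell_seed, m[1:3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(f_noise_values) > 1) {
    f_hi <- max(f_noise_values); f_lo <- min(f_noise_values)
    agg <- function(fn, col) {
      sub <- out[out$f_noise == fn, ]
      tapply(sub[[col]], list(factor(sub$s, levels = s_values),
                              factor(sub$p, levels = p_values)),
             mean)
    }
    attr(out, "diff") <- list(
      B_diff = agg(f_hi, "B") - agg(f_lo, "B"),
      mpc_diff = agg(f_hi, "mpc") - agg(f_lo, "mpc"))
  }
  attr(out, "config") <- list(variant = params$variant, baseline = baseline,
                              n = n, k = k, t_end = t_end, window = window,
                              master_seed = seed)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sliding-window bursting-measure trajectory
#'
#' B evaluated on windows of `width` ms stepped by `step` ms from t = 0.
#'
#' @param raster A `spike_raster`.
#' @param width,step Window width and step (ms).
#' @return data.frame: window_start, window_end, B.
#' @export
burst_trajectory <- function(raster, width = 500, step = 100) {
  starts <- seq(0, raster$duration - width, by = step)
  B <- vapply(starts, function(ws)
    burst_measure(raster, window = c(ws, ws + width)), numeric(1))
  data.frame(window_start = starts, window_end = starts + width, B = B)
}

#' Time to synchronization
#'
#' From randomized initial conditions (membrane voltages uniform on
#' \[-70, -50\] mV, gating variables at the corresponding equilibria), the
#' time at which the sliding-window bursting measure first breaches
#' `threshold`. Reported per (p, drive) as mean and SD over replicates;
#' runs that never breach within `t_end` are censored and counted, not
#' averaged silently.
#'
#' @param params `neuron_params` or variant string.
#' @param p_values Re-wiring probabilities.
#' @param mean_currents Mean drive currents (uA/cm^2).
#' @param s Synaptic weight.
#' @param threshold B threshold (default 0.6).
#' @param replicates Replicates per cell (paper-scale: 100; scale down for
#'   tests).
#' @param t_end Maximum simulated time per run (ms).
#' @param window_width,window_step Sliding-window parameters (ms).
#' @inheritParams constant_drive_sweep
#' @return data.frame: p, drive, mean_time, sd_time, n_breached,
#'   n_censored, replicates.
#' @export
time_to_sync <- function(params, p_values, mean_currents, s,
                         threshold = 0.6, replicates = 5, n = 200, k = 4,
                         seed = 1, t_end = 6000, window_width = 500,
                         window_step = 100, freq_sd = 1) {
  if (is.character(params)) params <- neuron_params(params)
  dim_state <- if (inherits(params, "ml_params")) 2L else 4L
  grid <- expand.grid(p = p_values, drive = mean_currents,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    times <- rep(NA_real_, replicates)
    for (rep in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, "tts", match(grid$p[g], p_values),
                               match(grid$drive[g], mean_currents), rep)
      adj <- watts_strogatz(n, k, grid$p[g],
                            seed = derive_seed(cell_seed, "adj"))
      cur <- gaussian_drive(params, grid$drive[g],
                            target_freq_sd = freq_sd, n = n,
                            seed = derive_seed(cell_seed, "drive"))
      v0 <- with_seed(derive_seed(cell_seed, "init"),
                      runif(n, -70, -50))
      state0 <- t(vapply(v0, function(v) equilibrium_state(params, v),
                         numeric(dim_state)))
      raster <- integrate_network(params, adj, synapse_spec(s),
                                  drive = list(i_const = as.numeric(cur)),
                                  state0 = state0, t_end = t_end,
                                  window = c(0, t_end))
      tr <- burst_trajectory(raster, width = window_width,
                             step = window_step)
      hit <- which(!is.na(tr$B) & tr$B >= threshold)
      if (length(hit)) times[rep] <- tr$window_end[hit[1]]
    }
    data.frame(p = grid$p[g], drive = grid$drive[g],
               mean_time = if (any(!is.na(times))) mean(times, na.rm = TRUE)
                           else NA_real_,
               sd_time = if (sum(!is.na(times)) > 1) sd(times, na.rm = TRUE)
                         else NA_real_,
               n_breached = sum(!is.na(times)),
               n_censored = sum(is.na(times)),
               replicates = replicates)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
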