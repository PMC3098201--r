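# Frequency-current curves, the brief-pulse PRC protocol, delay-depth
# statistics and gating-rate calibration.

#' Frequency-current (f-I) curve
#'
#' Steady-state firing frequency over a scan of constant applied currents.
#' For each current the neuron is integrated from rest; frequency is the
#' reciprocal of the converged inter-spike interval, or 0 if sustained
#' firing does not persist within the settle/measure horizon. A Type I cell
#' shows frequencies continuous from zero at rheobase; a Type II cell jumps
#' to a finite frequency there.
#'
#' @param params A `neuron_params` object.
#' @param i_min,i_max Scan range (uA/cm^2), `i_max > i_min`.
#' @param n_points Number of scan points.
#' @param dt Integration step (ms), default the model's shipped step.
#' @param settle Transient discarded before measuring (ms).
#' @param measure Measurement horizon (ms).
#' @return Object of class `fi_curve`: data.frame columns `current`,
#'   `frequency` (Hz), plus attribute `rheobase` (smallest scanned current
#'   that fired; refine with [rheobase()]).
#' @export
fi_curve <- function(params, i_min, i_max, n_points = 20, dt = NULL,
                     settle = 2000, measure = 3000) {
  stopifnot(i_max > i_min, n_points >= 2)
  cur <- seq(i_min, i_max, length.out = n_points)
  freq <- vapply(cur, function(i)
    .steady_freq(params, i, settle = settle, measure = measure, dt = dt),
    numeric(1))
  out <- data.frame(current = cur, frequency = freq)
  attr(out, "rheobase") <- if (any(freq > 0)) min(cur[freq > 0]) else NA_real_
  attr(out, "variant") <- params$variant
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Rheobase by bisection
#'
#' Minimal constant current sustaining repetitive firing from rest, located
#' by bisection on the firing/quiescent outcome of single-neuron runs.
#'
#' @param params A `neuron_params` object.
#' @param i_range Initial bracket; default `c(0, 200)` for Morris-Lecar,
#'   `c(0, 10)` for the pyramidal model.
#' @param tol Bisection tolerance on the current (uA/cm^2).
#' @param settle,measure Run horizons passed to the firing test (ms).
#' @return List: `rheobase` (midpoint), `i_quiet`, `i_firing` (final
#'   bracket), `onset_frequency` (converged frequency at `i_firing`, Hz).
#' @export
rheobase <- function(params, i_range = NULL, tol = 1e-3, settle = 2000,
                     measure = 3000) {
  if (is.null(i_range))
    i_range <- if (inherits(params, "ml_params")) c(0, 200) else c(0, 10)
  fires <- function(i) .steady_freq(params, i, settle, measure) > 0
  lo <- i_range[1]; hi <- i_range[2]
  if (fires(lo)) stop("lower bracket already fires; widen i_range")
  if (!fires(hi)) stop("upper bracket does not fire; widen i_range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  f_on <- .steady_freq(params, hi, settle = 2 * settle, measure = 2 * measure)
  list(rheobase = (lo + hi) / 2, i_quiet = lo, i_firing = hi,
       onset_frequency = f_on)
}

# integrate from rest until successive spike-peak periods stabilize;
# returns the stabilized period, the state at the last spike peak, and the
# unperturbed voltage sampled at n_phases phases of the cycle
.stabilize_oscillation <- function(params, i_app, dt = NULL, n_phases = 100,
                                   rel_tol = 1e-4, max_t = 24000) {
  if (is.null(dt)) dt <- params$dt
  # above a saddle-node rheobase there may be no fixed point at i_app at all
  state <- tryCatch(rest_state(params, i_app),
                    error = function(e) rest_state(params, 0))
  state[1] <- state[1] + 1 # nudge off a possibly unstable equilibrium
  t_run <- 3000
  repeat {
    r <- integrate_single(params, i_const = i_app, state0 = state, dt = dt,
                          t_end = t_run)
    pk <- r$peaks
    if (length(pk) >= 5) {
      per <- diff(pk)
      last <- utils::tail(per, 3)
      if (max(abs(diff(last))) / mean(last) < rel_tol) {
        T0 <- mean(last)
        # unperturbed voltage as a function of phase, from the peak anchor
        tr <- integrate_single(params, i_const = i_app,
                               state0 = r$peak_state, dt = dt,
                               t_end = T0 + dt, keep_trace = TRUE)$trace
        idx <- pmin(nrow(tr), 1 + round((seq_len(n_phases) - 1) / n_phases *
                                          T0 / dt))
        return(list(T0 = T0, peak_state = r$peak_state,
                    v_phase = tr[idx, 2]))
      }
    }
    state <- r$final_state
    t_run <- t_run * 2
    if (t_run > max_t)
      stop("neuron is not oscillating steadily at i_app = ", i_app,
           " (period failed to stabilize)")
  }
}

#' Phase response curve by the brief-pulse protocol
#'
#' The synaptically isolated neuron is driven with constant current `i_app`
#' until its oscillation period stabilizes (successive spike-peak periods
#' within 0.01%). Phase zero is anchored at the spike peak. A square
#' current pulse is then delivered at each of `n_phases` equally spaced
#' phases of the cycle in separate runs, and the phase shift at phase phi
#' is `(T0 - T_pert(phi)) / T0`, with `T_pert` the period of the cycle
#' containing the pulse (first-order PRC; later cycles are ignored).
#' Advances are positive.
#'
#' @param params A `neuron_params` object.
#' @param i_app Constant applied current (uA/cm^2); must be above rheobase.
#' @param pulse_amplitude,pulse_duration Stimulus spec (uA/cm^2, ms);
#'   default: the shipped per-variant values (Morris-Lecar 100.0 for
#'   0.50 ms; pyramidal Type I 3.0, Type II 10.0, for 0.06 ms).
#' @param n_phases Number of equally spaced phases (default 100).
#' @param dt Integration step (ms).
#' @return Object of class `prc_curve`: data.frame columns `phase`,
#'   `shift`, with attributes `period` (ms), `frequency` (Hz), `i_app`,
#'   `pulse_amplitude`, `pulse_duration`, `v_phase` (unperturbed voltage at
#'   each phase), `spike_threshold`, `variant`.
#' @export
compute_prc <- function(params, i_app, pulse_amplitude = NULL,
                        pulse_duration = NULL, n_phases = 100, dt = NULL) {
  if (is.null(dt)) dt <- params$dt
  stim <- model_parameters()$stimulus$prc_pulse[[params$variant]]
  if (is.null(pulse_amplitude)) pulse_amplitude <- stim$amplitude
  if (is.null(pulse_duration)) pulse_duration <- stim$duration
  st <- .stabilize_oscillation(params, i_app, dt = dt, n_phases = n_phases)
  T0 <- st$T0
  phases <- (seq_len(n_phases) - 1) / n_phases
  shifts <- vapply(phases, function(phi) {
    r <- integrate_single(params, i_const = i_app, state0 = st$peak_state,
                          dt = dt, t_end = 2.5 * T0,
                          pulse_onsets = phi * T0,
                          pulse_amp = pulse_amplitude,
                          pulse_dur = pulse_duration)
    # the stimulus bump itself can register as a local voltage maximum
    # (notably while the Morris-Lecar spike is still above threshold), so
    # the cycle-ending peak is the first one preceded by a fresh upward
    # threshold crossing
    if (!length(r$spikes)) return(NA_real_)
    pk <- r$peaks[r$peaks >= r$spikes[1]]
    if (!length(pk)) return(NA_real_)
    (T0 - pk[1]) / T0
  }, numeric(1))
  out <- data.frame(phase = phases, shift = shifts)
  attr(out, "period") <- T0
  attr(out, "frequency") <- 1000 / T0
  attr(out, "i_app") <- i_app
  attr(out, "pulse_amplitude") <- pulse_amplitude
  attr(out, "pulse_duration") <- pulse_duration
  attr(out, "v_phase") <- st$v_phase
  attr(out, "spike_threshold") <- params$spike_threshold
  attr(out, "variant") <- params$variant
  class(out) <- c("prc_curve", "data.frame")
  out
}

#' @export
print.prc_curve <- function(x, ...) {
  cat(sprintf(
    "prc_curve: %s at i_app=%.4g (f=%.2f Hz, T0=%.2f ms); max advance %.4f, delay depth %.4f\n",
    attr(x, "variant"), attr(x, "i_app"), attr(x, "frequency"),
    attr(x, "period"), max(x$shift, na.rm = TRUE), delay_depth(x)))
  invisible(x)
}

#' Delay depth of a PRC
#'
#' Absolute value of the most negative phase shift, after excluding the
#' early spike-dominated phases: by default, phases at which the
#' *unperturbed* voltage is still above the -20 mV spike threshold are
#' ignored, since a pulse landing on the action potential itself produces
#' small spurious delays. The spike consumes a much larger portion of the
#' interspike interval in the Morris-Lecar model (where this exclusion is
#' essential) than in the pyramidal model (where it removes only the first
#' phase or two). Returns 0 when no negative values remain.
#'
#' @param prc A `prc_curve`.
#' @param early_exclusion Either `NULL` (voltage-based default above) or a
#'   phase in \[0, 1): all phases strictly below it are excluded.
#' @return Non-negative delay depth (dimensionless).
#' @export
delay_depth <- function(prc, early_exclusion = NULL) {
  keep <- rep(TRUE, nrow(prc))
  if (is.null(early_exclusion)) {
    vp <- attr(prc, "v_phase")
    if (!is.null(vp)) keep <- vp <= attr(prc, "spike_threshold")
  } else {
    keep <- prc$phase >= early_exclusion
  }
  s <- prc$shift[keep]
  s <- s[!is.na(s)]
  if (!length(s) || min(s) >= 0) return(0)
  abs(min(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum phase advance of a PRC
#' @param prc A `prc_curve`.
#' @return Largest positive shift (0 if none).
#' @export
max_advance <- function(prc) max(c(0, prc$shift), na.rm = TRUE)

#' Calibrate a gating-rate parameter to a target delay depth
#'
#' Bisection on one of the gating-rate knobs (`phi_w` for Morris-Lecar,
#' `r_z` or `r_h` for the pyramidal model), exploiting that the PRC delay
#' depth increases monotonically with each of them, until the recomputed
#' PRC's delay depth matches `target_depth`.
#'
#' @param params A `neuron_params` object (the knob's current value is the
#'   calibration starting point).
#' @param i_app Constant applied current (uA/cm^2).
#' @param target_depth Target delay depth (dimensionless).
#' @param rate_knob One of `"phi_w"`, `"r_z"`, `"r_h"`.
#' @param bracket Knob bracket; default `base * c(1/8, 8)`.
#' @param tol Tolerance on the achieved depth (default 1e-3).
#' @param max_iter Bisection iteration cap.
#' @param ... Passed to [compute_prc()] (e.g. `n_phases`, pulse overrides).
#' @return List: `value` (calibrated knob), `achieved_depth`, `iterations`.
#' @export
calibrate_rate_for_depth <- function(params, i_app, target_depth, rate_knob,
                                     bracket = NULL, tol = 1e-3,
                                     max_iter = 40, ...) {
  if (!rate_knob %in% c("phi_w", "r_z", "r_h"))
    stop("rate_knob must be one of phi_w, r_z, r_h")
  base <- params[[rate_knob]]
  if (is.null(base)) stop("parameter set has no knob ", rate_knob)
  if (is.null(bracket)) bracket <- base * c(1 / 8, 8)
  depth_at <- function(val) {
    p2 <- params
    p2[[rate_knob]] <- val
    validate_params(p2)
    # a knob value that extinguishes the oscillation has no PRC: depth NA
    tryCatch(delay_depth(compute_prc(p2, i_app, ...)),
             error = function(e) NA_real_)
  }
  d_lo <- depth_at(bracket[1])
  d_hi <- depth_at(bracket[2])
  # shrink a dead upper end geometrically toward the (alive) lower end
  tries <- 0
  while (is.na(d_hi) && tries < 8) {
    bracket[2] <- sqrt(bracket[1] * bracket[2])
    d_hi <- depth_at(bracket[2])
    tries <- tries + 1
  }
  if (is.na(d_lo) || is.na(d_hi))
    stop(sprintf(
      "calibration failure: no sustained oscillation over %s in [%.4g, %.4g] at i_app = %.4g",
      rate_knob, bracket[1], bracket[2], i_app))
  if (target_depth < d_lo - tol || target_depth > d_hi + tol)
    stop(sprintf(
      "target depth %.4g not bracketed: depth in [%.4g, %.4g] over %s in [%.4g, %.4g]",
      target_depth, d_lo, d_hi, rate_knob, bracket[1], bracket[2]))
  lo <- bracket[1]; hi <- bracket[2]
  val <- NA_real_; d_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    val <- sqrt(lo * hi) # geometric midpoint: rates act multiplicatively
    d_mid <- depth_at(val)
    if (is.na(d_mid)) { hi <- val; next } # dead cell: retreat
    if (abs(d_mid - target_depth) < tol) break
    if (d_mid < target_depth) lo <- val else hi <- val
  }
  list(value = val, achieved_depth = d_mid, iterations = it)
}
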