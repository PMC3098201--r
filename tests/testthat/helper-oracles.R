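# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (explicit loops, test-local formulas)
# rather than calling the package's production code paths.

# brute-force pairwise mean phase coherence: explicit bracketing search and
# phasor sum, one probe spike at a time
oracle_mpc <- function(reference, probe) {
  if (length(reference) < 2) return(NA_real_)
  re <- 0; im <- 0; used <- 0
  for (t in probe) {
    prev <- NA; nxt <- NA
    for (r in reference) {
      if (r < t && (is.na(prev) || r > prev)) prev <- r
      if (r >= t && (is.na(nxt) || r < nxt)) nxt <- r
    }
    if (is.na(prev) || is.na(nxt)) next
    ph <- 2 * pi * (t - prev) / (nxt - prev)
    re <- re + cos(ph); im <- im + sin(ph)
    used <- used + 1
  }
  if (used == 0) return(NA_real_)
  sqrt(re^2 + im^2) / used
}

# burst measure from its definition, written out longhand
oracle_burst <- function(trains, n_neurons = length(trains)) {
  pooled <- sort(unlist(trains))
  if (length(pooled) < 2) return(NA_real_)
  tau <- pooled[-1] - pooled[-length(pooled)]
  m <- sum(tau) / length(tau)
  m2 <- sum(tau^2) / length(tau)
  (sqrt(m2 - m^2) / m - 1) / sqrt(n_neurons)
}

# homogeneous Poisson spike train (exponential gaps), test-local
oracle_poisson_train <- function(rate_hz, t_end_ms, seed) {
  set.seed(seed)
  gaps <- stats::rexp(ceiling(rate_hz * t_end_ms / 1000 * 1.5) + 50,
                      rate = rate_hz / 1000)
  s <- cumsum(gaps)
  s[s <= t_end_ms]
}

# classical RK4 in plain R against an arbitrary derivative function
oracle_rk4 <- function(f, y0, dt, n_steps) {
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
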