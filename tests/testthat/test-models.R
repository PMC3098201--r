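# models module: parameter loading, steady states, right-hand sides.

test_that("parameter values come from the shipped file, not call sites", {
  path <- system.file("extdata", "model_parameters.json", package = "prcsync")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (v in c("ml_type1", "ml_type2", "pyr_type1", "pyr_type2")) {
    p <- neuron_params(v)
    for (key in names(raw[[v]])) {
      expect_identical(p[[key]], raw[[v]][[key]],
                       label = paste(v, key))
    }
  }
  # the two ML variants share the common parameters and differ in the
  # excitability-setting ones
  m1 <- neuron_params("ml_type1"); m2 <- neuron_params("ml_type2")
  for (key in c("cm", "g_l", "e_l", "g_k", "e_k", "e_ca", "v1", "v2"))
    expect_identical(m1[[key]], m2[[key]], label = key)
  expect_false(m1$v3 == m2$v3)
  expect_false(m1$phi_w == m2$phi_w)
  # pyramidal types differ only in the M-type conductance
  q1 <- neuron_params("pyr_type1"); q2 <- neuron_params("pyr_type2")
  expect_identical(q1$g_ks, 0)
  expect_gt(q2$g_ks, 0)
})

test_that("invalid parameter overrides are rejected", {
  expect_error(neuron_params("ml_type3"), "unknown model variant")
  expect_error(neuron_params("ml_type1", bogus = 1), "unknown parameter")
  expect_error(neuron_params("ml_type1", phi_w = 0), "phi_w")
  expect_error(neuron_params("pyr_type2", r_z = -1), "rate multipliers")
  expect_error(neuron_params("pyr_type2", g_na = -5), "conductances")
})

test_that("steady_state is a proper sigmoid", {
  expect_equal(steady_state(-30, -30, 9.5), 0.5)
  expect_equal(steady_state(1e4, -30, 9.5), 1)
  expect_equal(steady_state(-1e4, -30, 9.5), 0)
  # negative slope flips direction (inactivation)
  expect_equal(steady_state(1e4, -53, -7), 0)
  expect_error(steady_state(0, 0, 0), "slope")
  # monotone at transcribed parameters, bracketing the half-voltage
  p <- neuron_params("ml_type2")
  v <- c(p$v3 - 10, p$v3, p$v3 + 10)
  w <- steady_state(v, p$v3, p$v4 / 2)
  expect_true(all(diff(w) > 0))
  expect_equal(w[2], 0.5)
})

test_that("ml_rhs vanishes at a root-found sub-threshold fixed point", {
  p <- neuron_params("ml_type1")
  # independent root-finding oracle: w nullcline substituted into the
  # voltage equation, test-local formulas
  winf <- function(v) 0.5 * (1 + tanh((v - p$v3) / p$v4))
  minf <- function(v) 0.5 * (1 + tanh((v - p$v1) / p$v2))
  ivolt <- function(v, i) i - p$g_l * (v - p$e_l) -
    p$g_ca * minf(v) * (v - p$e_ca) - p$g_k * winf(v) * (v - p$e_k)
  vstar <- uniroot(function(v) ivolt(v, 30), c(-80, -30), tol = 1e-12)$root
  d <- ml_rhs(c(vstar, winf(vstar)), p, i_ext = 30)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("dw/dt scales linearly with phi_w, dV/dt unchanged", {
  p1 <- neuron_params("ml_type2")
  p2 <- neuron_params("ml_type2", phi_w = 2 * p1$phi_w)
  st <- c(-35, 0.2)
  d1 <- ml_rhs(st, p1, i_ext = 90)
  d2 <- ml_rhs(st, p2, i_ext = 90)
  expect_equal(d2[2], 2 * d1[2])
  expect_equal(d2[1], d1[1])
})

test_that("Type I ML above rheobase has no fixed point (nullcline scan)", {
  p <- neuron_params("ml_type1")
  winf <- function(v) 0.5 * (1 + tanh((v - p$v3) / p$v4))
  minf <- function(v) 0.5 * (1 + tanh((v - p$v1) / p$v2))
  ivolt <- function(v, i) i - p$g_l * (v - p$e_l) -
    p$g_ca * minf(v) * (v - p$e_ca) - p$g_k * winf(v) * (v - p$e_k)
  # scan the sub-threshold nullcline branch (a depolarization-block
  # crossing persists near 0 mV and is not the resting branch)
  v <- seq(-80, -10, by = 0.05)
  # below rheobase: rest + saddle; above: the pair has vanished (SNIC)
  expect_true(any(diff(sign(ivolt(v, 30))) != 0))
  expect_false(any(diff(sign(ivolt(v, 45))) != 0))
})

test_that("pyr_rhs respects g_Ks = 0, r_z scaling, and its fixed point", {
  q1 <- neuron_params("pyr_type1")
  # z is irrelevant to dV/dt when g_Ks = 0
  d_a <- pyr_rhs(c(-60, 0.9, 0.05, 0.1), q1, i_ext = 0)
  d_b <- pyr_rhs(c(-60, 0.9, 0.05, 0.9), q1, i_ext = 0)
  expect_equal(d_a[1], d_b[1])
  # r_z = 2 doubles dz/dt at fixed state
  q2 <- neuron_params("pyr_type2")
  q2r <- neuron_params("pyr_type2", r_z = 2)
  st <- c(-55, 0.7, 0.1, 0.05)
  expect_equal(pyr_rhs(st, q2r)[4], 2 * pyr_rhs(st, q2)[4])
  # and r_h = 2 doubles dh/dt
  q2h <- neuron_params("pyr_type2", r_h = 2)
  expect_equal(pyr_rhs(st, q2h)[2], 2 * pyr_rhs(st, q2)[2])
  # resting fixed point at sub-threshold current: derivatives vanish
  st0 <- rest_state(q2, 0.5)
  expect_lt(max(abs(pyr_rhs(st0, q2, i_ext = 0.5))), 1e-8)
  expect_error(pyr_rhs(c(NaN, 0.5, 0.5, 0.5), q2), "non-finite")
})

test_that("gating variables stay in [0,1] under integration", {
  for (v in c("ml_type2", "pyr_type2")) {
    p <- neuron_params(v)
    i <- if (startsWith(v, "ml")) 100 else 2.5
    r <- integrate_single(p, i_const = i, t_end = 800, keep_trace = TRUE,
                          state0 = rest_state(p, 0) + c(1, rep(0, if (startsWith(v, "ml")) 1 else 3)))
    gating <- r$trace[, -(1:2), drop = FALSE]
    expect_true(all(gating >= 0 & gating <= 1), label = v)
  }
})

test_that("f-I curves are Type I (continuous) vs Type II (jump) at onset", {
  # pyramidal: Type I fires below 2 Hz just above rheobase, Type II jumps
  q1 <- neuron_params("pyr_type1")
  # bracket below the depolarization-block regime (no spikes at ~10)
  rb1 <- rheobase(q1, i_range = c(0, 0.5), tol = 5e-4, settle = 3000,
                  measure = 5000)
  expect_gt(rb1$onset_frequency, 0)
  expect_lt(rb1$onset_frequency, 2)
  q2 <- neuron_params("pyr_type2")
  f2 <- prcsync:::.steady_freq(q2, 1.45)
  expect_true(f2 == 0 || f2 > 5) # nothing between silence and ~the jump
})
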