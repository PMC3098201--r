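# simulate module: spike detection, single-neuron and network integration.

test_that("detect_spikes counts upward crossings with re-arming", {
  dt <- 0.1
  t <- seq(0, 100 - dt, by = dt)
  v <- -30 + 20 * sin(2 * pi * 50 / 1000 * t) # 50 Hz, spans -20 mV
  expect_length(detect_spikes(v, dt), 5)
  expect_length(detect_spikes(rep(-40, 1000), dt), 0)
  expect_length(detect_spikes(numeric(0), dt), 0)
  # no double counting without a downward re-crossing: staircase up
  v2 <- c(-40, -10, -5, -2, 0, 5)
  expect_length(detect_spikes(v2, dt), 1)
  # interpolation: crossing of a straight line lands between samples
  v3 <- c(-30, -10)
  expect_equal(detect_spikes(v3, 1), 0.5)
})

test_that("single-neuron integration: quiescence, periodicity, dt-convergence", {
  p <- neuron_params("ml_type1")
  # sub-threshold: resting initial state, zero spikes
  r0 <- integrate_single(p, i_const = 20, t_end = 1500)
  expect_length(r0$spikes, 0)
  # supra-threshold: inter-spike intervals constant to < 0.1% after transient
  r1 <- integrate_single(p, i_const = 50, t_end = 4000,
                         state0 = rest_state(p, 0) + c(1, 0))
  isi <- diff(r1$spikes)
  late <- tail(isi, 5)
  expect_gt(length(isi), 10)
  expect_lt(diff(range(late)) / mean(late), 1e-3)
  # halving dt changes the steady-state period by < 0.1%
  r2 <- integrate_single(p, i_const = 50, dt = p$dt / 2, t_end = 4000,
                         state0 = rest_state(p, 0) + c(1, 0))
  per1 <- mean(tail(diff(r1$spikes), 5))
  per2 <- mean(tail(diff(r2$spikes), 5))
  expect_lt(abs(per1 - per2) / per2, 1e-3)
  # spike count over a horizon matches the measured period
  f_hz <- 1000 / per1
  expect_equal(length(r1$spikes), f_hz * 4, tolerance = 0.05)
})

test_that("compiled integrator matches a plain-R RK4 oracle", {
  p <- neuron_params("pyr_type2")
  st0 <- rest_state(p, 0) + c(5, 0, 0, 0)
  dt <- 0.05; nstep <- 200
  ref <- oracle_rk4(function(y) pyr_rhs(y, p, i_ext = 2), st0, dt, nstep)
  r <- integrate_single(p, i_const = 2, state0 = st0, dt = dt,
                        t_end = nstep * dt, keep_trace = TRUE)
  expect_equal(as.numeric(r$trace[nstep + 1, -1]), ref, tolerance = 1e-12)
  # and for the Morris-Lecar model
  m <- neuron_params("ml_type2")
  sm0 <- c(-30, 0.1)
  refm <- oracle_rk4(function(y) ml_rhs(y, m, i_ext = 100), sm0, 0.1, 150)
  rm <- integrate_single(m, i_const = 100, state0 = sm0, dt = 0.1,
                         t_end = 15, keep_trace = TRUE)
  expect_equal(as.numeric(rm$trace[151, -1]), refm, tolerance = 1e-12)
})

test_that("integration blow-up is reported with the failing step", {
  p <- neuron_params("ml_type1")
  expect_error(integrate_single(p, i_const = 1e12, t_end = 10,
                                state0 = c(-40, 0)),
               "blew up")
})

test_that("uncoupled network equals independent single-neuron runs", {
  p <- neuron_params("ml_type2")
  n <- 4
  adj <- matrix(0L, n, n); adj[1, 2] <- 1L # an edge, but s = 0
  cur <- c(96, 100, 105, 110)
  st0 <- t(sapply(cur, function(i) rest_state(p, 0) + c(1, 0)))
  net <- integrate_network(p, adj, synapse_spec(0),
                           drive = list(i_const = cur), state0 = st0,
                           t_end = 2000, window = c(0, 2000))
  for (i in seq_len(n)) {
    solo <- integrate_single(p, i_const = cur[i], state0 = st0[i, ],
                             t_end = 2000)
    expect_equal(net$spikes[[i]], solo$spikes, tolerance = 1e-12)
  }
})

test_that("symmetric two-neuron pair stays identical; coupling shifts spikes", {
  p <- neuron_params("ml_type2")
  adj <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  st0 <- rbind(rest_state(p, 0) + c(1, 0), rest_state(p, 0) + c(1, 0))
  net <- integrate_network(p, adj, synapse_spec(10),
                           drive = list(i_const = c(100, 100)),
                           state0 = st0, t_end = 2000, window = c(0, 2000))
  expect_identical(net$spikes[[1]], net$spikes[[2]])
  # excitatory coupling actually does something relative to s = 0
  net0 <- integrate_network(p, adj, synapse_spec(0),
                            drive = list(i_const = c(100, 100)),
                            state0 = st0, t_end = 2000, window = c(0, 2000))
  expect_false(isTRUE(all.equal(net$spikes[[1]], net0$spikes[[1]])))
})

test_that("network runs are bit-identical across repeats and reject bad input", {
  p <- neuron_params("ml_type2")
  adj <- watts_strogatz(20, 2, 0.3, seed = 5)
  drive <- list(i_const = rep(100, 20))
  a <- integrate_network(p, adj, synapse_spec(8), drive, t_end = 1200,
                         window = c(0, 1200))
  b <- integrate_network(p, adj, synapse_spec(8), drive, t_end = 1200,
                         window = c(0, 1200))
  expect_identical(a$spikes, b$spikes)
  expect_error(integrate_network(p, adj, synapse_spec(8),
                                 drive = list(i_const = rep(100, 19))),
               "length")
  bad <- adj$matrix; diag(bad)[1] <- 1L
  expect_error(integrate_network(p, bad, synapse_spec(8), drive),
               "diagonal")
})

test_that("raster CSV round-trips losslessly and rejects malformed files", {
  r <- fixture_raster(n = 7, rate = 12, jitter_sd = 2, sync_fraction = 0.6,
                      seed = 42, duration = 2000, window = c(500, 2000))
  path <- tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path)
  expect_equal(r2$spikes, r$spikes, tolerance = 1e-12)
  expect_identical(r2$window, r$window)
  expect_identical(r2$duration, r$duration)
  expect_identical(r2$n, r$n)
  # truncated file: explicit error, not a silent partial load
  lines <- readLines(path)
  writeLines(lines[1:3], path) # decapitate the table
  bad <- tryCatch(read_raster_csv(path), error = function(e) e)
  r3 <- if (inherits(bad, "error")) NULL else bad
  # either an explicit parse error, or (if the fragment parses) far fewer
  # spikes than written -- assert we are told something is wrong
  expect_true(inherits(bad, "error") ||
                sum(lengths(r3$spikes)) < sum(lengths(r$spikes)))
  writeLines(c("neuron_id,spike_time_ms", "1,5"), path)
  expect_error(read_raster_csv(path), "header")
})

test_that("spike_raster validates its invariants", {
  expect_error(spike_raster(list(c(3, 2, 5)), duration = 10), "increasing")
  expect_error(spike_raster(list(c(3, 12)), duration = 10), "outside")
  r <- spike_raster(list(c(1, 2), numeric(0)), duration = 10,
                    window = c(0, 10))
  expect_identical(r$n, 2L)
})
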