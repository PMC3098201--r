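#' @useDynLib prcsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif uniroot sd
#' @importFrom utils read.csv write.csv
NULL

.prcsync_env <- new.env(parent = emptyenv())

#' Load the shipped model-parameter file
#'
#' All numeric parameter values of the neuron models, the stimulus protocols
#' and the network defaults live in a single versioned JSON file shipped with
#' the package (`inst/extdata/model_parameters.json`), so there is exactly one
#' source of truth. Everything downstream reads from this file.
#'
#' @param path Optional path to an alternative parameter file.
#' @return Named list with entries `ml_type1`, `ml_type2`, `pyr_type1`,
#'   `pyr_type2`, `stimulus`, `network`.
#' @export
model_parameters <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.prcsync_env$params)) return(.prcsync_env$params)
    path <- system.file("extdata", "model_parameters.json", package = "prcsync")
    if (!nzchar(path)) stop("parameter file not found in installed package")
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    .prcsync_env$params <- p
    return(p)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Construct a validated neuron-parameter object
#'
#' @param variant One of `"ml_type1"`, `"ml_type2"`, `"pyr_type1"`,
#'   `"pyr_type2"`.
#' @param ... Named overrides of individual parameter values (e.g.
#'   `phi_w = 0.08`, `r_z = 2`).
#' @return Object of class `c("ml_params"|"pyr_params", "neuron_params")`.
#' @examples
#' p <- neuron_params("ml_type2", phi_w = 0.08)
#' @export
neuron_params <- function(variant, ...) {
  all <- model_parameters()
  if (!variant %in% c("ml_type1", "ml_type2", "pyr_type1", "pyr_type2"))
    stop("unknown model variant: ", variant)
  p <- all[[variant]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter override(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$variant <- variant
  class(p) <- c(if (p$model == "morris_lecar") "ml_params" else "pyr_params",
                "neuron_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$cm > 0)
  if (inherits(p, "ml_params")) {
    g <- c(p$g_l, p$g_ca, p$g_k)
    if (any(g < 0)) stop("conductances must be >= 0")
    if (p$v2 == 0 || p$v4 == 0) stop("slope parameters must be nonzero")
    if (p$phi_w <= 0) stop("phi_w must be > 0")
  } else {
    g <- c(p$g_na, p$g_kdr, p$g_ks, p$g_l)
    if (any(g < 0)) stop("conductances must be >= 0")
    sl <- c(p$m_slope, p$h_slope, p$n_slope, p$z_slope)
    if (any(sl == 0)) stop("slope parameters must be nonzero")
    if (p$r_h <= 0 || p$r_z <= 0) stop("rate multipliers must be > 0")
  }
  invisible(p)
}

#' Sigmoidal steady-state activation
#'
#' Logistic activation `1 / (1 + exp(-(v - half) / slope))`. A negative
#' `slope` gives an inactivation curve (decreasing in `v`). Morris-Lecar's
#' tanh-form steady states `0.5 * (1 + tanh((v - Vh)/Vs))` equal
#' `steady_state(v, Vh, Vs/2)`.
#'
#' @param v Membrane voltage (mV), vectorized.
#' @param half Half-activation voltage (mV).
#' @param slope Slope factor (mV); must be nonzero.
#' @return Activation in (0, 1).
#' @export
steady_state <- function(v, half, slope) {
  if (slope == 0) stop("slope must be nonzero")
  1 / (1 + exp(-(v - half) / slope))
}

#' Right-hand side of the Morris-Lecar equations
#'
#' Current-balance and recovery dynamics for state `(V, w)`:
#' `C dV/dt = I_ext + I_syn - g_L (V - E_L) - g_Ca m_inf(V) (V - E_Ca)
#'  - g_K w (V - E_K)`, `dw/dt = phi_w (w_inf(V) - w) cosh((V - V3)/(2 V4))`.
#' The calcium activation m is instantaneous. Pure-R reference
#' implementation; the integrators use an identical compiled version.
#'
#' @param state Numeric vector `c(v, w)`.
#' @param params An `ml_params` object.
#' @param i_ext Applied current (uA/cm^2).
#' @param i_syn Synaptic current (uA/cm^2).
#' @return Numeric vector `c(dv, dw)` (mV/ms, 1/ms).
#' @export
ml_rhs <- function(state, params, i_ext = 0, i_syn = 0) {
  if (any(!is.finite(state))) stop("non-finite state")
  v <- state[1]; w <- state[2]
  minf <- steady_state(v, params$v1, params$v2 / 2)
  winf <- steady_state(v, params$v3, params$v4 / 2)
  dv <- (i_ext + i_syn - params$g_l * (v - params$e_l) -
           params$g_ca * minf * (v - params$e_ca) -
           params$g_k * w * (v - params$e_k)) / params$cm
  dw <- params$phi_w * (winf - w) * cosh((v - params$v3) / (2 * params$v4))
  c(dv, dw)
}

#' Right-hand side of the cortical pyramidal neuron model
#'
#' Single-compartment model with instantaneous Na activation (`m_inf^3 h`),
#' delayed-rectifier K (`n^4`), a slow low-threshold M-type K current gated
#' by `z` (conductance `g_Ks`; 0 models full cholinergic suppression and
#' gives a Type I cell, 1.5 mS/cm^2 a Type II cell), and leak. Gating
#' relaxation rates for h and z carry multipliers `r_h`, `r_z` (default 1).
#'
#' @param state Numeric vector `c(v, h, n, z)`.
#' @param params A `pyr_params` object.
#' @inheritParams ml_rhs
#' @return Numeric vector `c(dv, dh, dn, dz)`.
#' @export
pyr_rhs <- function(state, params, i_ext = 0, i_syn = 0) {
  if (any(!is.finite(state))) stop("non-finite state")
  v <- state[1]; h <- state[2]; n <- state[3]; z <- state[4]
  p <- params
  minf <- steady_state(v, p$m_half, p$m_slope)
  hinf <- steady_state(v, p$h_half, p$h_slope)
  ninf <- steady_state(v, p$n_half, p$n_slope)
  zinf <- steady_state(v, p$z_half, p$z_slope)
  tau_h <- p$tau_h0 + p$tau_h1 * steady_state(v, p$tau_h_half, -p$tau_h_slope)
  tau_n <- p$tau_n0 + p$tau_n1 * steady_state(v, p$tau_n_half, -p$tau_n_slope)
  dv <- (i_ext + i_syn - p$g_na * minf^3 * h * (v - p$e_na) -
           p$g_kdr * n^4 * (v - p$e_k) - p$g_ks * z * (v - p$e_k) -
           p$g_l * (v - p$e_l)) / p$cm
  c(dv, p$r_h * (hinf - h) / tau_h, (ninf - n) / tau_n,
    p$r_z * (zinf - z) / p$tau_z)
}

#' Model right-hand side dispatcher
#' @inheritParams ml_rhs
#' @export
neuron_rhs <- function(state, params, i_ext = 0, i_syn = 0) {
  if (inherits(params, "ml_params")) ml_rhs(state, params, i_ext, i_syn)
  else pyr_rhs(state, params, i_ext, i_syn)
}

#' Gating variables at their voltage equilibria
#' @param params A `neuron_params` object.
#' @param v Membrane voltage (mV).
#' @return Full state vector with gating variables at steady state for `v`.
#' @export
equilibrium_state <- function(params, v) {
  p <- params
  if (inherits(p, "ml_params")) {
    c(v, steady_state(v, p$v3, p$v4 / 2))
  } else {
    c(v, steady_state(v, p$h_half, p$h_slope),
      steady_state(v, p$n_half, p$n_slope),
      steady_state(v, p$z_half, p$z_slope))
  }
}

# steady-state current balance: I needed to hold the cell at v
.iv_curve <- function(params, v) {
  vapply(v, function(vv) {
    st <- equilibrium_state(params, vv)
    -neuron_rhs(st, params, i_ext = 0)[1] * params$cm
  }, numeric(1))
}

#' Resting state at a given applied current
#'
#' Locates the most hyperpolarized steady state of the full system at
#' constant current `i_ext` (root of the steady-state I-V relation), with
#' gating variables at equilibrium. Errors if no sub-threshold fixed point
#' exists in the scanned voltage range.
#'
#' @param params A `neuron_params` object.
#' @param i_ext Applied current (uA/cm^2).
#' @param v_range Voltage bracket to scan (mV).
#' @return State vector at rest.
#' @export
rest_state <- function(params, i_ext = 0, v_range = c(-90, 20)) {
  vs <- seq(v_range[1], v_range[2], by = 0.25)
  f <- .iv_curve(params, vs) - i_ext
  sc <- which(f[-length(f)] * f[-1] <= 0)
  if (!length(sc))
    stop("no steady state in voltage range for i_ext = ", i_ext)
  r <- uniroot(function(v) .iv_curve(params, v) - i_ext,
               c(vs[sc[1]], vs[sc[1] + 1]), tol = 1e-10)
  equilibrium_state(params, r$root)
}
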