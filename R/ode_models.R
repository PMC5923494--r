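#' Population-level virus-dynamics model registry
#'
#' The model family applied to monolayer spread data. All variants share the
#' target-cell / infected-cell / virus structure with no cell death
#' (`delta_T = delta_I = 0`):
#' \describe{
#'   \item{CF}{cell-free transmission only (`beta_c = 0`).}
#'   \item{CC}{mass-action cell-to-cell transmission only (`beta_f = 0`);
#'     the virus equation is dropped.}
#'   \item{CCF}{both transmission modes, mass-action cell-to-cell term.}
#'   \item{aCC}{cell-to-cell only with the perimeter-fraction adjustment
#'     `fc(I)` multiplying the transmission term.}
#'   \item{aCC-dI}{as aCC with a delay `tau` on the infected cells mediating
#'     transmission: `fc(I) beta_c I(t - tau) T`.}
#'   \item{CC-dI}{mass-action cell-to-cell with the same delay.}
#'   \item{aCCF}{both modes with the adjusted cell-to-cell term.}
#' }
#'
#' @param name model name (see above).
#' @return Object of class `"model_spec"`: list with `name` and logical
#'   flags `use_cf` (cell-free term + virus equation), `use_cc`, `adjust`,
#'   `delay`.
#' @examples
#' model_spec("aCC")
#' @export
model_spec <- function(name = c("CC", "aCC", "CC-dI", "aCC-dI",
                                "CF", "CCF", "aCCF")) {
  name <- match.arg(name)
  flags <- switch(name,
    "CF"     = list(use_cf = TRUE,  use_cc = FALSE, adjust = FALSE, delay = FALSE),
    "CC"     = list(use_cf = FALSE, use_cc = TRUE,  adjust = FALSE, delay = FALSE),
    "CCF"    = list(use_cf = TRUE,  use_cc = TRUE,  adjust = FALSE, delay = FALSE),
    "aCC"    = list(use_cf = FALSE, use_cc = TRUE,  adjust = TRUE,  delay = FALSE),
    "aCC-dI" = list(use_cf = FALSE, use_cc = TRUE,  adjust = TRUE,  delay = TRUE),
    "CC-dI"  = list(use_cf = FALSE, use_cc = TRUE,  adjust = FALSE, delay = TRUE),
    "aCCF"   = list(use_cf = TRUE,  use_cc = TRUE,  adjust = TRUE,  delay = FALSE))
  structure(c(list(name = name), flags), class = "model_spec")
}

#' Rate parameters and initial conditions for a virus-dynamics model
#'
#' @param beta_f cell-free transmission rate (per virus per hour).
#' @param beta_c cell-to-cell transmission rate (per cell per hour).
#' @param rho viral production rate (per infected cell per hour).
#' @param c viral clearance rate (per hour).
#' @param tau infection-to-infectiousness delay (hours).
#' @param tau_history pre-history of the lagged infected-cell concentration:
#'   `"zero"` (default) treats cells infected at time `s` as infectious from
#'   `s + tau`, so nothing is infectious before `t0 + tau` — the eclipse
#'   reading of the delay; `"constant"` uses `I(s) = I0` for `s < t0`
#'   (appropriate when an unknown share of the initial infected cells is
#'   already infectious).
#' @param adjustment an [adjustment_params()] object (used by the adjusted
#'   models), or `NULL` for mass action.
#' @param T0,I0,V0 initial target cells, infected cells and viral load.
#' @return Object of class `"ode_params"`.
#' @export
ode_params <- function(beta_f = 0, beta_c = 0, rho = 0, c = 0, tau = 0,
                       tau_history = c("zero", "constant"),
                       adjustment = NULL, T0, I0 = 1, V0 = 0) {
  tau_history <- match.arg(tau_history)
  if (any(c(beta_f, beta_c, rho, c, tau) < 0)) stop("rates must be >= 0")
  if (T0 <= 0) stop("`T0` must be > 0")
  if (!is.null(adjustment)) stopifnot(inherits(adjustment, "adjustment_params"))
  structure(list(beta_f = beta_f, beta_c = beta_c, rho = rho, c = c,
                 tau = tau, tau_history = tau_history,
                 adjustment = adjustment,
                 T0 = T0, I0 = I0, V0 = V0),
            class = "ode_params")
}

#' Right-hand side of the virus-dynamics equations
#'
#' Mainly useful for inspection and testing; [simulate_model()] integrates
#' with a compiled core. The cell-to-cell term is `fc(I) beta_c I T`, with
#' `fc = 1` for the non-adjusted models; delays are ignored here (the lagged
#' concentration must be supplied via `I_lag`).
#'
#' @param state named numeric vector `c(T = , I = , V = )`.
#' @param t time (unused; the system is autonomous).
#' @param params an [ode_params()].
#' @param spec a [model_spec()].
#' @param I_lag lagged infected-cell concentration for the delay variants
#'   (defaults to the current `I`).
#' @return Named vector of derivatives `(dT, dI, dV)`.
#' @export
model_rhs <- function(state, t, params, spec, I_lag = state[["I"]]) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(state < 0)) stop("state must be non-negative")
  fc <- if (spec$adjust) fc_full(state[["I"]], params$adjustment) else 1
  if (is.na(fc)) stop("fc(I) evaluated to NA at I = ", state[["I"]])
  cc <- if (spec$use_cc) fc * params$beta_c * I_lag * state[["T"]] else 0
  cf <- if (spec$use_cf) params$beta_f * state[["V"]] * state[["T"]] else 0
  dV <- if (spec$use_cf) params$rho * state[["I"]] - params$c * state[["V"]] else 0
  c(dT = -(cf + cc), dI = cf + cc, dV = dV)
}

#' Integrate a virus-dynamics model at requested sampling times
#'
#' Fixed-step fourth-order Runge-Kutta with method-of-steps handling of the
#' delay variants (pre-history per `tau_history` in [ode_params()]). The
#' default step of 0.01 h resolves all model time scales used here; halving
#' it changes trajectories by well under 1e-6 relative.
#'
#' @param spec a [model_spec()].
#' @param params an [ode_params()]; for adjusted models `params$adjustment`
#'   must be set.
#' @param times ascending sampling times (h); integration starts at
#'   `times[1]`.
#' @param h integration step (h).
#' @return Data frame with columns `time`, `T`, `I`, `V`.
#' @examples
#' ap <- adjustment_params(k = 6, z = 10)
#' pp <- ode_params(beta_c = 1e-5, adjustment = ap, T0 = 4681, I0 = 1)
#' simulate_model(model_spec("aCC"), pp, times = seq(0, 240, 24))
#' @export
simulate_model <- function(spec, params, times, h = 0.01) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "ode_params"))
  if (is.unsorted(times, strictly = FALSE)) stop("`times` must be ascending")
  if (spec$delay && params$tau >= diff(range(times)) && params$tau > 0)
    stop("delay `tau` exceeds the span of `times`")
  ap <- params$adjustment
  if (spec$adjust && is.null(ap)) ap <- adjustment_params()
  if (is.null(ap)) ap <- adjustment_params()  # unused when adjust = FALSE
  bc <- if (spec$use_cc) params$beta_c else 0
  hist0 <- if (identical(params$tau_history, "constant")) params$I0 else 0
  m <- ode_traj_cpp(as.numeric(times), params$T0, params$I0, params$V0,
                    params$beta_f, bc, params$rho, params$c,
                    if (spec$delay) params$tau else 0,
                    spec$use_cf, spec$adjust,
                    ap$k, ap$z, ap$phi, ap$a, ap$b, h, hist0)
  data.frame(time = as.numeric(times), T = m[, 1], I = m[, 2], V = m[, 3])
}

#' Model-predicted contributor fractions along a trajectory
#'
#' Returns the raw adjustment term `fc(I(t))` and the target-availability
#' corrected series `fc(I(t)) T(t)/T0`, the quantity directly comparable to
#' the contributor fraction observed in the agent-based simulations.
#'
#' @param trajectory result of [simulate_model()].
#' @param params the [ode_params()] used (supplies `adjustment` and `T0`).
#' @return Data frame `time`, `fc`, `fc_corrected`.
#' @export
predicted_contributors <- function(trajectory, params) {
  ap <- params$adjustment
  if (is.null(ap)) ap <- adjustment_params()
  fc <- fc_full(trajectory$I, ap)
  data.frame(time = trajectory$time, fc = fc,
             fc_corrected = fc * trajectory$T / params$T0)
}

#' Model-predicted infected-cell increment series
#'
#' The instantaneous cell-to-cell increment `beta_c fc(I(t)) I(t) T(t)`
#' along a trajectory, for comparison with the empirical per-step increments
#' of the agent-based model (see [abm_increment_rate()]; when calibrating
#' against such runs use `beta_c = btilde_c * Vcc`).
#'
#' @inheritParams predicted_contributors
#' @param beta_c optional override of the transmission rate (per cell per h).
#' @param adjust if `FALSE`, evaluate with `fc = 1` (mass action).
#' @return Data frame `time`, `dI`.
#' @export
ode_increment <- function(trajectory, params, beta_c = params$beta_c,
                          adjust = !is.null(params$adjustment)) {
  fc <- if (adjust) {
    ap <- params$adjustment
    if (is.null(ap)) ap <- adjustment_params()
    fc_full(trajectory$I, ap)
  } else 1
  data.frame(time = trajectory$time,
             dI = beta_c * fc * trajectory$I * trajectory$T)
}
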