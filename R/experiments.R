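#' @name experiments
#' @title Scripted end-to-end analysis scenarios
#' @description
#' Each `run_*` function generates agent-based replicate data for one study
#' condition, aggregates it into per-time means and SDs, fits the relevant
#' virus-dynamics models by maximum likelihood, and returns a scenario
#' report: the aggregated data, every fit, the AICc ranking and the
#' diagnostic series. Default scales (lattice side, replicate count,
#' optimizer restarts) are reduced relative to the `full_scale` settings
#' (side-90 lattice, 100 replicates) so that a full scenario completes in
#' minutes on one CPU; every report is reproducible from its configuration
#' and seed.
NULL

default_bounds <- function() list(
  beta_c   = c(1e-9, 1e-2),
  beta_f   = c(1e-12, 1e-2),
  rho      = c(1e-4, 1e3),
  c        = c(1e-3, 10),
  theta    = c(1, 20),
  z        = c(0.05, 100),
  tau      = c(1e-3, 48),
  sigma_me = c(1e-4, 1e4))

# dataset of infected-cell counts from an aggregate table, from time `from`
cells_dataset <- function(agg, from = 0) {
  a <- agg[agg$time_h > from + 1e-9, ]
  vd_dataset(a$time_h, a$I_mean, a$I_sd, a$n)
}

virus_dataset <- function(agg, from = 0, error_model = "relative") {
  a <- agg[agg$time_h > from + 1e-9, ]
  vd_dataset(a$time_h, a$V_mean, a$V_sd, a$n, observable = "viral_load",
             error_model = error_model)
}

fit_family <- function(models, dataset, fixed, n_restarts, seed, h = 0.02) {
  b <- default_bounds()
  fits <- lapply(models, function(mn) {
    spec <- model_spec(mn)
    free <- c("beta_c", "sigma_me")
    if (spec$adjust) free <- c(free, "theta", "z")
    if (spec$delay) free <- c(free, "tau")
    if (spec$use_cf) free <- c(free, "beta_f", "rho")
    fit_model(spec, dataset, bounds = b[free], fixed = fixed,
              n_restarts = n_restarts, seed = seed, h = h)
  })
  names(fits) <- models
  fits
}

#' Single-focus cell-to-cell spread scenario
#'
#' Replicate simulations start from one central infected cell with
#' cell-to-cell transmission only; the mean infected-cell count sampled
#' every 24 h is fitted with the mass-action (CC), adjusted (aCC) and
#' delayed (CC-dI, aCC-dI) models. The key outputs are the AICc ranking and
#' the fold-difference between the aCC and CC transmission-rate estimates.
#'
#' @param side lattice side (cells per edge).
#' @param n_reps replicate simulations.
#' @param base_seed replicate `r` uses seed `base_seed + r`.
#' @param n_restarts optimizer restarts per fit.
#' @param params an [abm_params()]; scenario flags applied internally.
#' @param models which models to fit.
#' @param full_scale if `TRUE`, use a side-90 lattice and 100 replicates.
#' @return Scenario report list: `scenario`, `aggregate`, `fits`,
#'   `delta_aicc`, `beta_ratio` (aCC/CC), `contributors` (observed vs
#'   predicted contributor fractions), `config`.
#' @export
run_single_focus <- function(side = 40, n_reps = 20, base_seed = 1,
                             n_restarts = 8, params = abm_params(),
                             models = c("CC", "aCC", "CC-dI", "aCC-dI"),
                             full_scale = FALSE) {
  if (full_scale) { side <- 90; n_reps <- 100 }
  lat <- hex_lattice(side)
  sim <- run_abm_replicates(params, lat, "single_focus_cc", n_reps,
                            base_seed = base_seed)
  agg <- sim$aggregate
  ds <- cells_dataset(agg, from = 0)
  fixed <- list(T0 = lat$n_sites, I0 = 1, V0 = 0, t0 = 0, psi = 1, k = 6)
  fits <- fit_family(models, ds, fixed, n_restarts, seed = base_seed)
  da <- delta_aicc(fits)
  ratio <- if (all(c("CC", "aCC") %in% models))
    fits[["aCC"]]$estimates[["beta_c"]] / fits[["CC"]]$estimates[["beta_c"]]
  else NA_real_
  contrib <- NULL
  if ("aCC" %in% models) {
    best <- fits[[if ("aCC-dI" %in% models) "aCC-dI" else "aCC"]]
    op <- make_ode_params(best$estimates, fixed, best$spec)
    traj <- simulate_model(best$spec, op, agg$time_h)
    pc <- predicted_contributors(traj, op)
    contrib <- data.frame(time_h = agg$time_h, observed = agg$contrib_mean,
                          predicted = pc$fc, predicted_corrected = pc$fc_corrected)
  }
  list(scenario = "single_focus_cc", aggregate = agg, fits = fits,
       delta_aicc = da, beta_ratio = ratio, contributors = contrib,
       config = list(side = side, n_reps = n_reps, base_seed = base_seed,
                     n_restarts = n_restarts, params = params))
}

#' Multi-focus cell-to-cell spread scenario
#'
#' Infection is initiated stochastically over a 17-h window, extracellular
#' virus is washed out and cell-free infection blocked at the end of the
#' window, and spread continues by cell-to-cell transmission only. Models
#' are fitted from the end of the initiation window onward, taking the mean
#' infected-cell count at that time as initial condition. Besides the model
#' comparison, the report includes the contributor-fraction comparison
#' (observed vs `fc(I) T/T0`) and, optionally, the per-step infected-cell
#' increment comparison between the agent-based runs and the calibrated
#' model increment `beta_c fc(I) I T` with `beta_c = btilde_c Vcc`.
#'
#' @inheritParams run_single_focus
#' @param psi_mode `"expected"` uses the expected inoculum size as the focus
#'   count in the adjustment scaling; `"realized"` uses the mean realized
#'   count at the end of the initiation window.
#' @param increments if `TRUE`, record per-step counts and compute the
#'   increment comparison.
#' @return Scenario report list (as [run_single_focus()], plus
#'   `increments` when requested).
#' @export
run_multifocus <- function(side = 40, n_reps = 20, base_seed = 1,
                           n_restarts = 8, params = abm_params(),
                           models = c("CC", "aCC", "aCC-dI"),
                           psi_mode = c("expected", "realized"),
                           increments = FALSE, full_scale = FALSE) {
  psi_mode <- match.arg(psi_mode)
  if (full_scale) { side <- 90; n_reps <- 100 }
  lat <- hex_lattice(side)
  sim <- run_abm_replicates(params, lat, "multifocus_cc", n_reps,
                            base_seed = base_seed, record_steps = increments)
  agg <- sim$aggregate
  t0 <- params$t_init
  I0 <- agg$I_mean[match(t0, agg$time_h)]
  psi <- if (psi_mode == "expected") max(1, round(params$I0hat)) else
    max(1, round(agg$I_mean[match(t0, agg$time_h)]))
  ds <- cells_dataset(agg, from = t0)
  fixed <- list(T0 = lat$n_sites, I0 = I0, V0 = 0, t0 = t0, psi = psi, k = 6)
  fits <- fit_family(models, ds, fixed, n_restarts, seed = base_seed)
  da <- delta_aicc(fits)
  ratio <- if (all(c("CC", "aCC") %in% models))
    fits[["aCC"]]$estimates[["beta_c"]] / fits[["CC"]]$estimates[["beta_c"]]
  else NA_real_
  contrib <- NULL
  if ("aCC" %in% models) {
    best <- fits[["aCC"]]
    op <- make_ode_params(best$estimates, fixed, best$spec)
    keep <- agg$time_h >= t0
    traj <- simulate_model(best$spec, op, agg$time_h[keep])
    pc <- predicted_contributors(traj, op)
    contrib <- data.frame(time_h = agg$time_h[keep],
                          observed = agg$contrib_mean[keep],
                          predicted = pc$fc,
                          predicted_corrected = pc$fc_corrected)
  }
  inc <- NULL
  if (increments && "aCC" %in% models)
    inc <- increment_comparison(sim, fits[["aCC"]], fixed, params, t0)
  list(scenario = "multifocus_cc", aggregate = agg, fits = fits,
       delta_aicc = da, beta_ratio = ratio, contributors = contrib,
       increments = inc,
       config = list(side = side, n_reps = n_reps, base_seed = base_seed,
                     n_restarts = n_restarts, psi = psi, params = params))
}

# ABM per-window mean increments (with 95% CI across replicates) vs the
# calibrated model increment beta_c fc(I) I T with beta_c = btilde_c * Vcc
increment_comparison <- function(sim, fit_acc, fixed, params, t0,
                                 window_h = 24) {
  st0 <- sim$runs[[1]]$steps
  brk <- seq(t0, max(st0$time_h), by = window_h)
  idx0 <- findInterval(st0$time_h[st0$time_h >= t0], brk,
                       rightmost.closed = TRUE)
  inc_rep <- lapply(sim$runs, function(r) {
    st <- r$steps[r$steps$time_h >= t0, ]
    sapply(split(seq_len(nrow(st)), idx0), function(ii)
      (st$I[max(ii)] - st$I[min(ii)]) / (st$time_h[max(ii)] - st$time_h[min(ii)]))
  })
  inc_m <- do.call(rbind, inc_rep)
  tt0 <- st0$time_h[st0$time_h >= t0]
  mids <- vapply(split(tt0, idx0), function(x) (min(x) + max(x)) / 2,
                 numeric(1))
  vcc <- vapply(sim$runs, function(r)
    abm_increment_rate(r$steps[r$steps$time_h >= t0, ], params)$Vcc, numeric(1))
  # Eq-12-style increments carry no explicit target-cell factor (f~c already
  # accounts for availability), so the equivalent per-cell model rate is
  # btilde_c * Vcc / T0
  beta_cal <- params$sc * params$finf * 60 * mean(vcc) / fixed$T0
  est <- fit_acc$estimates
  op <- make_ode_params(est, fixed, fit_acc$spec)
  traj <- simulate_model(fit_acc$spec, op, c(t0, mids))
  ode_dI <- ode_increment(traj[-1, ], op, beta_c = beta_cal, adjust = TRUE)
  nr <- nrow(inc_m)
  data.frame(time_h = mids,
             abm_mean = colMeans(inc_m),
             abm_lo = colMeans(inc_m) - 1.96 * apply(inc_m, 2, stats::sd) / sqrt(nr),
             abm_hi = colMeans(inc_m) + 1.96 * apply(inc_m, 2, stats::sd) / sqrt(nr),
             abm_sd = apply(inc_m, 2, stats::sd),
             ode = ode_dI$dI, beta_calibrated = beta_cal)
}

#' Mixed cell-free plus cell-to-cell transmission scenario
#'
#' Both transmission modes act simultaneously. Under slow virion diffusion
#' the CCF and aCCF models are fitted to the infected-cell counts alone;
#' under fast diffusion (165-fold larger exchange fraction) the scenario is
#' additionally fitted jointly with a cell-free-only calibration dataset on
#' both infected cells and viral load (relative errors), sharing the
#' cell-free parameters across datasets. The report tracks the predicted vs
#' observed proportion of cells infected by cell-free transmission.
#'
#' @inheritParams run_single_focus
#' @param diffusion `"slow"` or `"fast"`.
#' @param profile_beta_f if `TRUE`, profile the cell-free transmission rate
#'   of the cells-only CCF fit to assess identifiability.
#' @return Scenario report list with `fits` (cells-only fits), `joint_fits`
#'   (fast diffusion only), `delta_aicc`, `cf_proportion` comparison and
#'   `beta_f_profile` when requested.
#' @export
run_mixed_transmission <- function(diffusion = c("slow", "fast"), side = 30,
                                   n_reps = 10, base_seed = 1, n_restarts = 8,
                                   params = abm_params(),
                                   profile_beta_f = FALSE,
                                   full_scale = FALSE) {
  diffusion <- match.arg(diffusion)
  if (full_scale) { side <- 90; n_reps <- 100 }
  scen <- paste0("mixed_", diffusion, "_diffusion")
  lat <- hex_lattice(side)
  sim <- run_abm_replicates(params, lat, scen, n_reps, base_seed = base_seed)
  agg <- sim$aggregate
  t0 <- params$t_init
  I0 <- agg$I_mean[match(t0, agg$time_h)]
  psi <- max(1, round(params$I0hat))
  fixed <- list(T0 = lat$n_sites, I0 = I0, V0 = 0, t0 = t0, psi = psi,
                k = 6, c = params$c * 60)
  ds_cells <- cells_dataset(agg, from = t0)
  b <- default_bounds()
  fits <- lapply(c("CCF", "aCCF"), function(mn) {
    spec <- model_spec(mn)
    free <- c("beta_c", "beta_f", "rho", "sigma_me")
    if (spec$adjust) free <- c(free, "theta", "z")
    fit_model(spec, ds_cells, bounds = b[free], fixed = fixed,
              n_restarts = n_restarts, seed = base_seed, h = 0.02)
  })
  names(fits) <- c("CCF", "aCCF")
  prof <- if (profile_beta_f) profile_ci(fits[["CCF"]], "beta_f") else NULL

  joint <- NULL; sim_cf <- NULL
  if (diffusion == "fast") {
    sim_cf <- run_abm_replicates(params, lat, "cf_only_fast", n_reps,
                                 base_seed = base_seed + 1000)
    agg_cf <- sim_cf$aggregate
    ds_mix <- list(vd_dataset(ds_cells$times, ds_cells$xbar, ds_cells$sd,
                              ds_cells$n, error_model = "relative"),
                   virus_dataset(agg, from = t0))
    ds_cf <- list(cells_rel = vd_dataset(
                    agg_cf$time_h[agg_cf$time_h > t0],
                    agg_cf$I_mean[agg_cf$time_h > t0],
                    agg_cf$I_sd[agg_cf$time_h > t0], n_reps,
                    error_model = "relative"),
                  virus = virus_dataset(agg_cf, from = t0))
    fixed_cf <- list(T0 = lat$n_sites,
                     I0 = agg_cf$I_mean[match(t0, agg_cf$time_h)],
                     V0 = 0, t0 = t0, c = params$c * 60)
    joint <- lapply(c("CCF", "aCCF"), function(mn) {
      spec <- model_spec(mn)
      free <- c("beta_c", "beta_f", "rho")
      if (spec$adjust) free <- c(free, "theta", "z")
      bl <- c(b[free], list(sigma_me1 = c(1e-4, 1e2), sigma_me2 = c(1e-4, 1e2)))
      joint_fit(list(spec, model_spec("CF")), list(ds_mix, ds_cf),
                bounds = bl, fixed_list = list(fixed, fixed_cf),
                n_restarts = n_restarts, seed = base_seed, h = 0.02)
    })
    names(joint) <- c("CCF", "aCCF")
  }

  cf_prop <- cf_proportion_comparison(agg, fits, fixed, t0)
  list(scenario = scen, aggregate = agg, fits = fits,
       delta_aicc = delta_aicc(fits),
       joint_fits = joint,
       joint_delta_aicc = if (!is.null(joint)) delta_aicc(joint) else NULL,
       cf_only_aggregate = if (!is.null(sim_cf)) sim_cf$aggregate else NULL,
       beta_f_profile = prof, cf_proportion = cf_prop,
       config = list(side = side, n_reps = n_reps, base_seed = base_seed,
                     n_restarts = n_restarts, diffusion = diffusion,
                     params = params))
}

# observed vs model-predicted proportion of cells infected by cell-free
# transmission, among transmission-infected cells (inoculated cells are
# assigned neither mode and are excluded from the denominator)
cf_proportion_comparison <- function(agg, fits, fixed, t0) {
  keep <- agg$time_h >= t0
  times <- agg$time_h[keep]
  denom <- agg$n_cf_mean[keep] + agg$n_cc_mean[keep]
  observed <- ifelse(denom > 0, agg$n_cf_mean[keep] / denom, NA_real_)
  out <- data.frame(time_h = times, observed = observed)
  for (nm in names(fits)) {
    ft <- fits[[nm]]
    op <- make_ode_params(ft$estimates, fixed, ft$spec)
    tt <- seq(t0, max(times), length.out = 241)
    traj <- simulate_model(ft$spec, op, tt)
    fc <- if (ft$spec$adjust) fc_full(traj$I, op$adjustment) else 1
    d_cf <- op$beta_f * traj$V * traj$T
    d_cc <- op$beta_c * fc * traj$I * traj$T
    cum <- function(x) c(0, cumsum((head(x, -1) + tail(x, -1)) / 2 * diff(tt)))
    p <- cum(d_cf) / pmax(cum(d_cf) + cum(d_cc), 1e-12)
    out[[paste0("predicted_", nm)]] <- stats::approx(tt, p, xout = times)$y
  }
  out
}

#' Cell-free-only spread scenario
#'
#' Cell-to-cell transmission is disabled and the standard cell-free model is
#' fitted to the infected-cell counts. Under slow virion diffusion infection
#' spreads locally and the mass-action model fits poorly (large reduced
#' chi-squared); under fast diffusion the system approaches the well-mixed
#' situation the model assumes.
#'
#' @inheritParams run_mixed_transmission
#' @return Report list with the CF fit and `reduced_chisq`.
#' @export
run_cf_only <- function(diffusion = c("slow", "fast"), side = 30,
                        n_reps = 10, base_seed = 1, n_restarts = 8,
                        params = abm_params(), full_scale = FALSE) {
  diffusion <- match.arg(diffusion)
  if (full_scale) { side <- 90; n_reps <- 100 }
  scen <- paste0("cf_only_", diffusion)
  lat <- hex_lattice(side)
  sim <- run_abm_replicates(params, lat, scen, n_reps, base_seed = base_seed)
  agg <- sim$aggregate
  t0 <- params$t_init
  # viral turnover (rho, c) is estimated from the data here: the standard
  # model's constant per-cell production has to absorb the ramping export of
  # newly infected cells
  fixed <- list(T0 = lat$n_sites, I0 = agg$I_mean[match(t0, agg$time_h)],
                V0 = 0, t0 = t0)
  ds <- cells_dataset(agg, from = t0)
  b <- default_bounds()
  degenerate <- all(diff(ds$xbar) == 0)
  fit <- if (degenerate) NULL else
    fit_model(model_spec("CF"), ds,
              bounds = b[c("beta_f", "rho", "c", "sigma_me")],
              fixed = fixed, n_restarts = n_restarts, seed = base_seed,
              h = 0.02)
  list(scenario = scen, aggregate = agg, fit = fit,
       reduced_chisq = if (is.null(fit)) NA_real_ else reduced_chisq(fit),
       degenerate = degenerate,
       config = list(side = side, n_reps = n_reps, base_seed = base_seed,
                     n_restarts = n_restarts, diffusion = diffusion,
                     params = params))
}
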