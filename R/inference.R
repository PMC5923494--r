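#' Replicate time-series observations for model fitting
#'
#' One observation channel: per-time means across replicate simulations (or
#' experiments), the empirical standard deviation across replicates and the
#' replicate count. The likelihood combines the replicate variance of the
#' mean, `sd^2/n`, with an estimated measurement error (see
#' [log_likelihood()]).
#'
#' @param times sampling times (h), strictly increasing.
#' @param xbar per-time mean of the observable.
#' @param sd per-time empirical standard deviation across replicates.
#' @param n replicates per time point (scalar or vector).
#' @param observable `"infected_cells"` or `"viral_load"`.
#' @param error_model `"absolute"` (default) or `"relative"`; relative error
#'   divides residual and replicate SD by the model prediction, the choice
#'   used when viral load and infected cells are fitted together.
#' @return Object of class `"vd_dataset"`.
#' @export
vd_dataset <- function(times, xbar, sd, n,
                       observable = c("infected_cells", "viral_load"),
                       error_model = c("absolute", "relative")) {
  observable <- match.arg(observable)
  error_model <- match.arg(error_model)
  n <- rep_len(n, length(times))
  stopifnot(length(xbar) == length(times), length(sd) == length(times))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(sd < 0)) stop("`sd` must be >= 0")
  structure(list(times = as.numeric(times), xbar = as.numeric(xbar),
                 sd = as.numeric(sd), n = as.numeric(n),
                 observable = observable, error_model = error_model),
            class = "vd_dataset")
}

# number of data points in a channel list
n_points <- function(channels) sum(vapply(channels, function(ch)
  length(ch$times), integer(1)))

as_channels <- function(dataset) {
  if (inherits(dataset, "vd_dataset")) list(dataset) else {
    stopifnot(all(vapply(dataset, inherits, logical(1), "vd_dataset")))
    dataset
  }
}

# Gaussian log-likelihood contribution of one channel given predictions f
ll_channel <- function(ch, f, sigma_me) {
  if (any(!is.finite(f))) return(-Inf)
  if (ch$error_model == "relative") {
    if (any(f <= 0)) return(-Inf)
    r <- (ch$xbar - f) / f
    v <- (ch$sd / f)^2 / ch$n + sigma_me^2
  } else {
    r <- ch$xbar - f
    v <- ch$sd^2 / ch$n + sigma_me^2
  }
  if (any(v <= 0))
    stop("zero combined variance: require sigma_me > 0 or positive sd")
  -0.5 * sum(r^2 / v) - 0.5 * sum(log(v))
}

# `pars` then `fixed` then default
par_get <- function(name, pars, fixed, default = 0) {
  if (!is.null(pars[[name]])) pars[[name]]
  else if (!is.null(fixed[[name]])) fixed[[name]]
  else default
}

# assemble ode_params from a named parameter vector + per-dataset constants
make_ode_params <- function(pars, fixed, spec) {
  pars <- as.list(pars)
  adj <- NULL
  if (spec$adjust)
    adj <- adjustment_params(
      k = par_get("k", pars, fixed, 6),
      z = par_get("z", pars, fixed, 10),
      theta = max(1, par_get("theta", pars, fixed, 1)),
      psi = par_get("psi", pars, fixed, 1))
  ode_params(beta_f = par_get("beta_f", pars, fixed),
             beta_c = par_get("beta_c", pars, fixed),
             rho = par_get("rho", pars, fixed),
             c = par_get("c", pars, fixed),
             tau = par_get("tau", pars, fixed),
             tau_history = par_get("tau_history", pars, fixed, "zero"),
             adjustment = adj,
             T0 = par_get("T0", pars, fixed, NA),
             I0 = par_get("I0", pars, fixed, 1),
             V0 = par_get("V0", pars, fixed, 0))
}

# default prediction function: simulate the model from t0 and read the
# requested observable columns at each channel's times
make_predict_fn <- function(spec, channels, fixed, h) {
  t0 <- par_get("t0", list(), fixed, 0)
  all_times <- sort(unique(c(t0, unlist(lapply(channels, `[[`, "times")))))
  cols <- vapply(channels, function(ch)
    if (ch$observable == "viral_load") "V" else "I", character(1))
  function(pars) {
    op <- make_ode_params(pars, fixed, spec)
    traj <- simulate_model(spec, op, all_times, h = h)
    lapply(seq_along(channels), function(j)
      traj[[cols[j]]][match(channels[[j]]$times, all_times)])
  }
}

#' Gaussian log-likelihood of a model given replicate summary data
#'
#' Implements the likelihood used for all fits:
#' `l = -1/2 sum_t (xbar(t) - f(t))^2 / s2(t) - 1/2 sum_t log s2(t)`
#' with per-time combined variance `s2(t) = sd(t)^2/n + sigma_me^2`
#' (replicate variation of the mean plus estimated measurement error).
#' For relative-error channels residual and replicate SD are divided by the
#' model prediction.
#'
#' @param params named vector/list of model parameters; must include
#'   `sigma_me` unless supplied in `fixed`.
#' @param spec a [model_spec()].
#' @param dataset a [vd_dataset()] or list of them (channels).
#' @param fixed named list of pinned parameters and constants (`T0`, `I0`,
#'   `V0`, `t0`, `psi`, `k`, optionally rates).
#' @param h integration step (h).
#' @return Log-likelihood value.
#' @export
log_likelihood <- function(params, spec, dataset, fixed = list(), h = 0.01) {
  channels <- as_channels(dataset)
  predict_fn <- if (is.function(spec)) {
    function(pars) lapply(channels, function(ch) spec(pars, ch$times))
  } else make_predict_fn(spec, channels, fixed, h)
  f <- predict_fn(params)
  sig <- par_get("sigma_me", as.list(params), fixed, NA)
  if (is.na(sig)) stop("`sigma_me` must be supplied in params or fixed")
  sum(vapply(seq_along(channels), function(j)
    ll_channel(channels[[j]], f[[j]], sig), numeric(1)))
}

# logistic box transform between the unconstrained optimizer scale and the
# (possibly log10) bounded natural scale
par_transform <- function(bounds) {
  nm <- names(bounds)
  scale <- vapply(bounds, function(b)
    if (b[1] > 0) "log" else "linear", character(1))
  lo <- vapply(seq_along(bounds), function(i)
    if (scale[i] == "log") log10(bounds[[i]][1]) else bounds[[i]][1], numeric(1))
  hi <- vapply(seq_along(bounds), function(i)
    if (scale[i] == "log") log10(bounds[[i]][2]) else bounds[[i]][2], numeric(1))
  list(
    names = nm, lo = lo, hi = hi, scale = scale,
    to_natural = function(x) {
      u <- stats::plogis(x)
      v <- lo + (hi - lo) * u
      v[scale == "log"] <- 10^v[scale == "log"]
      stats::setNames(v, nm)
    },
    from_natural = function(p) {
      v <- p[nm]
      v[scale == "log"] <- log10(v[scale == "log"])
      u <- (v - lo) / (hi - lo)
      u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
      stats::setNames(stats::qlogis(u), nm)
    })
}

# shared optimizer driver: minimizes `negll(x)` over the transformed space
# from LHS restarts; returns best optim() result plus start bookkeeping
run_restarts <- function(negll, tr, n_restarts, seed, x_extra = NULL) {
  p <- length(tr$names)
  set.seed(seed)
  u <- lhs::randomLHS(max(1, n_restarts), p)
  u <- pmin(pmax(u, 0.02), 0.98)
  starts <- lapply(seq_len(nrow(u)), function(i) stats::qlogis(u[i, ]))
  if (!is.null(x_extra)) starts <- c(list(x_extra), starts)
  best <- NULL
  for (x0 in starts) {
    res <- tryCatch(suppressWarnings(
      stats::optim(x0, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("no optimizer restart produced a finite likelihood")
  best
}

#' Maximum-likelihood fit of a virus-dynamics model
#'
#' Maximizes [log_likelihood()] by Nelder-Mead in a transformed parameter
#' space (log10 for positive-bounded parameters, linear otherwise, squashed
#' into the given box), from Latin-hypercube restarts. Deterministic given
#' `seed`.
#'
#' @param spec a [model_spec()], or a function `(pars, times)` returning
#'   predicted means for an arbitrary mean model.
#' @param dataset a [vd_dataset()] or list of channels.
#' @param bounds named list of `c(lower, upper)` for every free parameter
#'   (including `sigma_me`).
#' @param fixed named list of pinned parameters/constants (must include `T0`;
#'   typically also `I0`, `t0`, `psi`).
#' @param n_restarts number of Latin-hypercube starting points.
#' @param seed RNG seed for the restart design.
#' @param h integration step (h).
#' @return Object of class `"fit_result"`: `estimates` (natural scale),
#'   `loglik`, `aicc`, `k`, `n`, `converged`, `n_restarts`, plus internal
#'   closures reused by [profile_ci()].
#' @examples
#' \donttest{
#' lat <- hex_lattice(20)
#' sim <- run_abm_replicates(abm_params(t_end = 96), lat, "single_focus_cc",
#'                           n_reps = 5, base_seed = 1)
#' agg <- sim$aggregate[-1, ]
#' ds <- vd_dataset(agg$time_h, agg$I_mean, agg$I_sd, agg$n)
#' fit_model(model_spec("CC"), ds,
#'           bounds = list(beta_c = c(1e-8, 1e-3), sigma_me = c(1e-3, 1e3)),
#'           fixed = list(T0 = lat$n_sites, I0 = 1, t0 = 0),
#'           n_restarts = 5, seed = 1)
#' }
#' @export
fit_model <- function(spec, dataset, bounds, fixed = list(),
                      n_restarts = 50, seed = 1, h = 0.01) {
  channels <- as_channels(dataset)
  predict_fn <- if (is.function(spec)) {
    # custom mean function: spec(pars, times) -> predicted means
    function(pars) lapply(channels, function(ch) spec(pars, ch$times))
  } else make_predict_fn(spec, channels, fixed, h)
  tr <- par_transform(bounds)
  negll <- function(x) {
    pars <- tr$to_natural(x)
    f <- tryCatch(predict_fn(pars), error = function(e) NULL)
    if (is.null(f)) return(Inf)
    sig <- par_get("sigma_me", as.list(pars), fixed, NA)
    ll <- sum(vapply(seq_along(channels), function(j)
      ll_channel(channels[[j]], f[[j]], sig), numeric(1)))
    if (!is.finite(ll)) Inf else -ll
  }
  best <- run_restarts(negll, tr, n_restarts, seed)
  est <- tr$to_natural(best$par)
  k <- length(bounds)
  n <- n_points(channels)
  structure(list(
    estimates = est, loglik = -best$value,
    aicc = aicc(-best$value, k, n), k = k, n = n,
    converged = best$convergence == 0, n_restarts = n_restarts,
    spec = spec, bounds = bounds, fixed = fixed,
    x_hat = best$par, negll = negll, transform = tr,
    predict_fn = predict_fn, channels = channels, ci = list()),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: loglik %.3f, AICc %.3f (k = %d, n = %d)\n",
              if (inherits(x$spec, "model_spec")) x$spec$name else "model",
              x$loglik, x$aicc, x$k, x$n))
  print(signif(x$estimates, 4))
  if (length(x$ci)) {
    cat("95% profile CIs:\n")
    for (nm in names(x$ci))
      cat(sprintf("  %s: [%.4g, %.4g]%s\n", nm, x$ci[[nm]]$lower,
                  x$ci[[nm]]$upper,
                  if (!x$ci[[nm]]$identifiable) " (ni)" else ""))
  }
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' `AICc = 2k - 2L + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood `L`.
#' @param k number of fitted parameters.
#' @param n number of data points.
#' @return AICc value.
#' @examples
#' aicc(0, 2, 10)  # 4 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc differences relative to the best model
#'
#' @param fits list of [fit_model()] results (or a numeric vector of AICc
#'   values).
#' @return Named numeric vector of `AICc - min(AICc)`; the best model gets 0.
#' @export
delta_aicc <- function(fits) {
  vals <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$aicc, numeric(1))
  if (is.null(names(vals)) && !is.numeric(fits))
    names(vals) <- vapply(fits, function(f)
      if (inherits(f$spec, "model_spec")) f$spec$name else "model",
      character(1))
  vals - min(vals)
}

# re-optimize all parameters except `pin_idx`, which is held at `x_pin`
# (transformed scale); warm start from `x_start`
profile_point <- function(fit, pin_idx, x_pin, x_start) {
  free_idx <- setdiff(seq_along(fit$x_hat), pin_idx)
  x <- x_start
  x[pin_idx] <- x_pin
  if (!length(free_idx)) return(list(ll = -fit$negll(x), x = x))
  obj <- function(xf) {
    x[free_idx] <- xf
    fit$negll(x)
  }
  res <- tryCatch(suppressWarnings(
    stats::optim(x_start[free_idx], obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-9))),
    error = function(e) NULL)
  if (is.null(res)) return(list(ll = NA_real_, x = x_start))
  x[free_idx] <- res$par
  list(ll = -res$value, x = x)
}

#' Profile-likelihood 95% confidence interval
#'
#' Scans the named parameter away from its estimate, re-optimizing all other
#' parameters at each grid value (warm-started from the neighbouring
#' solution), and reports the interval where the profile log-likelihood stays
#' within `qchisq(0.95, 1)/2 = 1.9207` of its maximum. A side on which the
#' drop is never reached before the parameter bound is reported at the bound
#' and marked open; if neither side reaches the drop the parameter is flagged
#' non-identifiable.
#'
#' @param fit a [fit_model()] result.
#' @param param name of the parameter to profile.
#' @param n_grid grid points per side.
#' @param level confidence level.
#' @return List with `lower`, `upper`, `open_lower`, `open_upper`,
#'   `identifiable`, `estimate`, and the scanned `profile` (data frame
#'   `value`, `loglik`). Attach to a fit with `fit$ci[[param]] <- result`
#'   to have it shown by `print()`.
#' @export
profile_ci <- function(fit, param, n_grid = 15, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  pin_idx <- match(param, fit$transform$names)
  if (is.na(pin_idx)) stop("parameter `", param, "` was not fitted")
  thresh <- stats::qchisq(level, 1) / 2
  ll_max <- fit$loglik
  x_hat <- fit$x_hat
  # geometric offsets on the transformed scale; the squashed box is fully
  # covered well before an offset of ~14
  offs <- 0.05 * 1.7^(seq_len(n_grid) - 1)
  offs <- pmin(offs, 14)
  scan_side <- function(dir) {
    vals <- numeric(0); lls <- numeric(0)
    x_start <- x_hat
    n_fail <- 0
    warm <- list()
    for (off in offs) {
      xp <- x_hat[pin_idx] + dir * off
      pp <- profile_point(fit, pin_idx, xp, x_start)
      if (is.na(pp$ll)) { n_fail <- n_fail + 1; next }
      vals <- c(vals, xp); lls <- c(lls, pp$ll)
      warm[[length(vals)]] <- pp$x
      x_start <- pp$x
      if (pp$ll < ll_max - thresh - 0.5) break
    }
    if (n_fail > 0.2 * n_grid) stop("profile re-optimization failed repeatedly")
    list(x = vals, ll = lls, warm = warm)
  }
  nat <- function(xp) {
    x <- x_hat; x[pin_idx] <- xp
    fit$transform$to_natural(x)[[param]]
  }
  side_ci <- function(side) {
    drop <- ll_max - side$ll
    cross <- which(drop >= thresh)
    if (!length(cross))  # never crossed: open at the parameter bound
      return(list(value = nat(utils::tail(side$x, 1)), open = TRUE))
    j <- cross[1]
    x_lo <- if (j == 1) x_hat[pin_idx] else side$x[j - 1]
    ll_lo <- if (j == 1) ll_max else side$ll[j - 1]
    x_hi <- side$x[j]
    ll_hi <- side$ll[j]
    x_start <- side$warm[[j]]
    # bisection for the exact threshold crossing
    for (it in seq_len(20)) {
      if (abs(x_hi - x_lo) < 1e-3) break
      xm <- (x_lo + x_hi) / 2
      pp <- profile_point(fit, pin_idx, xm, x_start)
      if (is.na(pp$ll)) break
      x_start <- pp$x
      if (ll_max - pp$ll >= thresh) { x_hi <- xm; ll_hi <- pp$ll }
      else { x_lo <- xm; ll_lo <- pp$ll }
    }
    w <- if (ll_lo == ll_hi) 0.5 else
      (ll_lo - (ll_max - thresh)) / (ll_lo - ll_hi)
    list(value = nat(x_lo + w * (x_hi - x_lo)), open = FALSE)
  }
  lo_side <- scan_side(-1)
  hi_side <- scan_side(+1)
  lo <- side_ci(lo_side)
  hi <- side_ci(hi_side)
  prof <- data.frame(
    value = vapply(c(rev(lo_side$x), x_hat[pin_idx], hi_side$x), nat, numeric(1)),
    loglik = c(rev(lo_side$ll), ll_max, hi_side$ll))
  list(lower = lo$value, upper = hi$value,
       open_lower = lo$open, open_upper = hi$open,
       identifiable = !(lo$open && hi$open),
       estimate = fit$estimates[[param]], profile = prof)
}

#' Reduced chi-squared statistic of a fit
#'
#' `sum(((xbar - f) / (sd/sqrt(n)))^2) / (n_points - k)`, measuring fit
#' quality on the scale of the replicate standard error. Values far above 1
#' indicate a model that cannot describe the data given its replicate
#' variability.
#'
#' @param fit a [fit_model()] result.
#' @return Reduced chi-squared value.
#' @export
reduced_chisq <- function(fit) {
  f <- fit$predict_fn(fit$estimates)
  tot <- 0
  for (j in seq_along(fit$channels)) {
    ch <- fit$channels[[j]]
    se <- ch$sd / sqrt(ch$n)
    ok <- se > 0
    tot <- tot + sum(((ch$xbar[ok] - f[[j]][ok]) / se[ok])^2)
  }
  df <- n_points(fit$channels) - fit$k
  if (df <= 0) stop("no residual degrees of freedom")
  tot / df
}

#' Simultaneous fit of several datasets with shared parameters
#'
#' Maximizes the sum of per-dataset log-likelihoods. Parameters are shared
#' when they carry the same name across datasets; dataset-specific
#' measurement errors are named `sigma_me1`, `sigma_me2`, ... and matched to
#' datasets by position. This is how a cell-free-only calibration experiment
#' pins the cell-free transmission rate while a mixed-transmission dataset
#' informs the cell-to-cell parameters.
#'
#' @param specs list of [model_spec()], one per dataset.
#' @param datasets list; each element a [vd_dataset()] or list of channels.
#' @param bounds named bounds for all free parameters (shared names appear
#'   once).
#' @param fixed_list per-dataset list of pinned constants.
#' @param n_restarts,seed,h as in [fit_model()].
#' @return A `"fit_result"` whose likelihood is the pooled one.
#' @export
joint_fit <- function(specs, datasets, bounds, fixed_list,
                      n_restarts = 50, seed = 1, h = 0.01) {
  stopifnot(length(specs) == length(datasets),
            length(fixed_list) == length(datasets))
  chans <- lapply(datasets, as_channels)
  preds <- lapply(seq_along(datasets), function(d)
    make_predict_fn(specs[[d]], chans[[d]], fixed_list[[d]], h))
  sig_names <- if (length(datasets) == 1L) "sigma_me" else
    paste0("sigma_me", seq_along(datasets))
  tr <- par_transform(bounds)
  negll <- function(x) {
    pars <- tr$to_natural(x)
    tot <- 0
    for (d in seq_along(datasets)) {
      f <- tryCatch(preds[[d]](pars), error = function(e) NULL)
      if (is.null(f)) return(Inf)
      sig <- par_get(sig_names[d], as.list(pars), fixed_list[[d]], NA)
      lld <- sum(vapply(seq_along(chans[[d]]), function(j)
        ll_channel(chans[[d]][[j]], f[[j]], sig), numeric(1)))
      if (!is.finite(lld)) return(Inf)
      tot <- tot + lld
    }
    -tot
  }
  best <- run_restarts(negll, tr, n_restarts, seed)
  est <- tr$to_natural(best$par)
  k <- length(bounds)
  n <- sum(vapply(chans, n_points, integer(1)))
  all_ch <- do.call(c, chans)
  joint_predict <- function(pars) do.call(c, lapply(preds, function(p) p(pars)))
  structure(list(
    estimates = est, loglik = -best$value,
    aicc = aicc(-best$value, k, n), k = k, n = n,
    converged = best$convergence == 0, n_restarts = n_restarts,
    spec = specs, bounds = bounds, fixed = fixed_list,
    x_hat = best$par, negll = negll, transform = tr,
    predict_fn = joint_predict, channels = all_ch, ci = list()),
    class = "fit_result")
}
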