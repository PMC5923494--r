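#' Parameters of the agent-based monolayer simulation
#'
#' All rates are per minute unless noted. The intracellular defaults are a
#' documented fixture (see the methods vignette): a single infected cell's
#' RNA content rises logistically at effective rate `alpha - gamma - rho`
#' over roughly two days to a plateau of `Rcap (alpha - gamma - rho)/alpha`
#' copies, and its exported extracellular virus follows.
#'
#' @param alpha maximal intracellular replication rate (/min).
#' @param Rcap intracellular carrying capacity (RNA copies).
#' @param gamma intracellular RNA degradation rate (/min).
#' @param rho RNA export rate (/min).
#' @param c extracellular virus clearance rate (/min).
#' @param finf infectious fraction of intracellular RNA, in `[0, 1]`.
#' @param m fraction of local virus exchanged with neighbours per step,
#'   in `[0, 1]`.
#' @param sf cell-free infection scaling (/min per virus): per-step infection
#'   probability of an uninfected cell is `min(1, sf * V_local * dt)`.
#' @param sc cell-to-cell infection scaling (/min per RNA): per infected
#'   neighbour the per-step probability is `min(1, sc * finf * R * dt)`.
#' @param I0hat expected total number of cells inoculated during the
#'   initiation window.
#' @param lam decay rate of inoculum infectivity (/h).
#' @param t_init initiation-window length (h); the media change (extracellular
#'   virus reset to zero) happens at its end.
#' @param dt time step (min).
#' @param t_end simulation horizon (h).
#' @param sample_every sampling interval for observables (h).
#' @param cf_enabled,cc_enabled enable cell-free / cell-to-cell transmission.
#' @param cf_blocked_after_init if `TRUE`, cell-free infection is switched off
#'   at the media change (antibody block of free virus).
#' @param inoculate if `TRUE` infection is seeded by the stochastic
#'   initiation protocol; if `FALSE` the caller supplies initial infected
#'   sites (e.g. one central cell).
#' @return An object of class `"abm_params"` (a validated list).
#' @export
abm_params <- function(alpha = 4e-3, Rcap = 1000, gamma = 1e-3, rho = 1e-3,
                       c = 1e-3, finf = 0.01, m = 0.005, sf = 5e-4, sc = 3e-4,
                       I0hat = 10, lam = 0.1, t_init = 17, dt = 1,
                       t_end = 240, sample_every = 24,
                       cf_enabled = TRUE, cc_enabled = TRUE,
                       cf_blocked_after_init = FALSE, inoculate = TRUE) {
  p <- list(alpha = alpha, Rcap = Rcap, gamma = gamma, rho = rho, c = c,
            finf = finf, m = m, sf = sf, sc = sc, I0hat = I0hat, lam = lam,
            t_init = t_init, dt = dt, t_end = t_end,
            sample_every = sample_every, cf_enabled = cf_enabled,
            cc_enabled = cc_enabled,
            cf_blocked_after_init = cf_blocked_after_init,
            inoculate = inoculate)
  rates <- c(alpha, Rcap, gamma, rho, c, sf, sc, I0hat, lam)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (m < 0 || m > 1) stop("`m` must be in [0, 1]")
  if (finf < 0 || finf > 1) stop("`finf` must be in [0, 1]")
  if (dt <= 0) stop("`dt` must be > 0")
  if (alpha * dt >= 0.5)
    stop("`dt` too coarse for the intracellular update (alpha*dt >= 0.5)")
  structure(p, class = "abm_params")
}

#' Initialise the per-cell simulation state
#'
#' @param lattice a [hex_lattice()].
#' @param infected_sites integer site indices initially infected (each starts
#'   with a single RNA copy).
#' @return An object of class `"abm_state"` with elements `t` (minutes),
#'   `status` (0 uninfected / 1 infected), `R`, `V`, `infected_at` (h),
#'   `mode` (`"none"`, `"inoculum"`, `"CF"`, `"CC"`) and `infector`.
#' @export
abm_state <- function(lattice, infected_sites = integer()) {
  n <- lattice$n_sites
  status <- integer(n); R <- numeric(n); V <- numeric(n)
  infected_at <- rep(NA_real_, n)
  mode <- rep("none", n); infector <- rep(NA_integer_, n)
  if (length(infected_sites)) {
    status[infected_sites] <- 1L
    R[infected_sites] <- 1
    infected_at[infected_sites] <- 0
    mode[infected_sites] <- "inoculum"
  }
  structure(list(t = 0, status = status, R = R, V = V,
                 infected_at = infected_at, mode = mode, infector = infector),
            class = "abm_state")
}

#' One explicit-Euler step of intracellular replication and viral export
#'
#' Advances, for every infected cell, the logistic-with-loss RNA dynamics
#' `dR/dt = alpha R (1 - R/Rcap) - gamma R - rho R` and, at every site, the
#' local extracellular balance `dV/dt = finf rho R - c V`. Uninfected cells
#' hold `R = 0` and are unchanged.
#'
#' @param state an [abm_state()].
#' @param params an [abm_params()].
#' @return The advanced state (time incremented by `dt`).
#' @export
step_intracellular <- function(state, params) {
  dt <- params$dt
  R0 <- state$R
  inf <- state$status == 1L
  Rn <- R0
  Rn[inf] <- R0[inf] + dt * (params$alpha * R0[inf] * (1 - R0[inf] / params$Rcap) -
                               (params$gamma + params$rho) * R0[inf])
  Vn <- state$V + dt * (params$finf * params$rho * R0 - params$c * state$V)
  if (any(Rn < 0) || any(Vn < 0))
    stop("negative state produced by intracellular step: reduce dt")
  state$R <- Rn; state$V <- Vn; state$t <- state$t + dt
  state
}

#' One synchronous neighbour-exchange diffusion step
#'
#' Each site exchanges a fraction `m/k` of the concentration difference with
#' each of its existing neighbours:
#' `V_i <- V_i + (m/k) * sum_j (V_j - V_i)`, evaluated from the pre-step
#' field. Pairwise-symmetric exchange with a no-flux boundary, so the lattice
#' total of `V` is conserved exactly and uniform fields are fixed points.
#'
#' @inheritParams step_intracellular
#' @param lattice the [hex_lattice()] the state lives on.
#' @return The state with updated `V` (time unchanged; diffusion is part of
#'   the same dt step as the intracellular update).
#' @export
step_diffusion <- function(state, params, lattice) {
  if (params$m == 0) return(state)
  nbr <- lattice$nbr_matrix
  V <- state$V
  Vn <- matrix(V[nbr], nrow = lattice$n_sites)
  deg <- rowSums(!is.na(nbr))
  s <- rowSums(Vn, na.rm = TRUE)
  state$V <- V + (params$m / lattice$k) * (s - deg * V)
  state
}

#' Stochastic cell-free and cell-to-cell infection attempts for one step
#'
#' For every uninfected cell a cell-free infection fires with probability
#' `min(1, sf * V_local * dt)` (when enabled); if it does not, each infected
#' neighbour independently attempts cell-to-cell transmission with
#' probability `min(1, sc * finf * R_donor * dt)`, donors tried in random
#' order with the first success winning. A newly infected cell starts with a
#' single RNA copy and its lineage (mode, infector, time) is recorded; a
#' cell-to-cell donor loses one RNA copy per transmission. New infections are
#' applied synchronously from the pre-step infection statuses.
#'
#' @inheritParams step_diffusion
#' @return The state with new infections applied.
#' @export
attempt_infections <- function(state, params, lattice) {
  dt <- params$dt
  n <- lattice$n_sites
  status0 <- state$status
  unin <- which(status0 == 0L)
  if (!length(unin)) return(state)
  new_mode <- character(0); new_site <- integer(0); new_src <- integer(0)
  cf_p <- if (params$cf_enabled) pmin(1, params$sf * state$V[unin] * dt) else
    numeric(length(unin))
  cf_hit <- runif(length(unin)) < cf_p
  nbr <- lattice$nbr_matrix
  for (ii in seq_along(unin)) {
    i <- unin[ii]
    if (cf_hit[ii]) {
      new_site <- c(new_site, i); new_mode <- c(new_mode, "CF")
      new_src <- c(new_src, NA_integer_)
      next
    }
    if (!params$cc_enabled) next
    dn <- nbr[i, ]
    dn <- dn[!is.na(dn)]
    dn <- dn[status0[dn] == 1L]
    if (!length(dn)) next
    if (length(dn) > 1L) dn <- sample(dn)
    for (d in dn) {
      p <- min(1, params$sc * params$finf * state$R[d] * dt)
      if (runif(1) < p) {
        new_site <- c(new_site, i); new_mode <- c(new_mode, "CC")
        new_src <- c(new_src, d)
        break
      }
    }
  }
  if (length(new_site)) {
    state$status[new_site] <- 1L
    state$R[new_site] <- 1
    state$infected_at[new_site] <- state$t / 60
    state$mode[new_site] <- new_mode
    state$infector[new_site] <- new_src
    loss <- table(new_src[!is.na(new_src)])
    if (length(loss)) {
      d <- as.integer(names(loss))
      state$R[d] <- pmax(0, state$R[d] - as.numeric(loss))
    }
  }
  state
}

# initiation density (per hour) at time t_h within the window [0, t_init)
pinit_density <- function(t_h, params) {
  params$I0hat * params$lam * exp(-params$lam * t_h) /
    (1 - exp(-params$t_init * params$lam))
}

#' Stochastic inoculation during the initiation window
#'
#' The number of newly inoculated cells in one step is Poisson with mean
#' `pinit(t) * dt`, where the initiation density
#' `pinit(t) = I0hat * lam * exp(-lam t) / (1 - exp(-lam t_init))`
#' integrates to `I0hat` over the window, so the expected total number of
#' inoculated cells is `I0hat` regardless of lattice size. Inoculated cells
#' are placed uniformly at random on uninfected sites.
#'
#' @inheritParams step_intracellular
#' @return The state with inoculations applied.
#' @export
inoculate <- function(state, params) {
  t_h <- state$t / 60
  if (t_h >= params$t_init) return(state)
  if (params$I0hat > length(state$status))
    stop("expected inoculum exceeds the number of sites")
  nnew <- stats::rpois(1, pinit_density(t_h, params) * params$dt / 60)
  if (nnew == 0) return(state)
  unin <- which(state$status == 0L)
  nnew <- min(nnew, length(unin))
  sites <- if (length(unin) == 1L) unin else sample(unin, nnew)
  state$status[sites] <- 1L
  state$R[sites] <- 1
  state$infected_at[sites] <- t_h
  state$mode[sites] <- "inoculum"
  state
}

#' Media change: reset extracellular virus
#'
#' Sets the extracellular virus concentration to zero at every site,
#' representing the replacement of culture medium at the end of the
#' initiation window. Infection statuses are untouched.
#'
#' @inheritParams step_intracellular
#' @return The state with `V = 0` everywhere.
#' @export
media_change <- function(state) {
  state$V[] <- 0
  state
}

#' Fraction of infected cells that can still transmit cell-to-cell
#'
#' Counts infected cells with at least one uninfected direct neighbour and
#' divides by the number of infected cells. This is the quantity the
#' adjustment term [fc_full()] approximates (after correction for target
#' availability).
#'
#' @param state an [abm_state()].
#' @param lattice the corresponding [hex_lattice()].
#' @return Fraction in `[0, 1]`.
#' @export
contributor_fraction <- function(state, lattice) {
  inf <- which(state$status == 1L)
  if (!length(inf)) stop("no infected cells: contributor fraction undefined")
  nbr <- lattice$nbr_matrix[inf, , drop = FALSE]
  has_unin <- apply(nbr, 1L, function(x) {
    x <- x[!is.na(x)]
    any(state$status[x] == 0L)
  })
  mean(has_unin)
}

#' Named simulation scenarios
#'
#' @return Character vector of scenario names accepted by [run_abm()].
#' @export
abm_scenarios <- function() {
  c("single_focus_cc", "multifocus_cc", "mixed_slow_diffusion",
    "mixed_fast_diffusion", "cf_only_slow", "cf_only_fast")
}

# scenario -> parameter overrides. The slow-diffusion exchange fraction is
# the one in `params`; the fast scenarios scale it 165-fold (capped at 1).
scenario_params <- function(params, scenario, m_slow = params$m,
                            m_fast = min(1, 165 * m_slow)) {
  switch(scenario,
    single_focus_cc = {
      params$cf_enabled <- FALSE; params$inoculate <- FALSE
      params$cc_enabled <- TRUE
    },
    multifocus_cc = {
      params$cf_enabled <- TRUE; params$cc_enabled <- TRUE
      params$inoculate <- TRUE; params$cf_blocked_after_init <- TRUE
    },
    mixed_slow_diffusion = {
      params$cf_enabled <- TRUE; params$cc_enabled <- TRUE
      params$inoculate <- TRUE; params$cf_blocked_after_init <- FALSE
      params$m <- m_slow
    },
    mixed_fast_diffusion = {
      params$cf_enabled <- TRUE; params$cc_enabled <- TRUE
      params$inoculate <- TRUE; params$cf_blocked_after_init <- FALSE
      params$m <- m_fast
    },
    cf_only_slow = {
      params$cf_enabled <- TRUE; params$cc_enabled <- FALSE
      params$inoculate <- TRUE; params$cf_blocked_after_init <- FALSE
      params$m <- m_slow
    },
    cf_only_fast = {
      params$cf_enabled <- TRUE; params$cc_enabled <- FALSE
      params$inoculate <- TRUE; params$cf_blocked_after_init <- FALSE
      params$m <- m_fast
    },
    stop("unknown scenario: ", scenario)
  )
  params
}

#' Run one agent-based simulation replicate
#'
#' Executes the full protocol on the given lattice: seeding (a single central
#' infected cell for `single_focus_cc`, otherwise stochastic inoculation over
#' the initiation window followed by a media change), then repeated dt-steps
#' of intracellular replication, diffusion and infection, sampling the
#' observables on a regular schedule.
#'
#' @param params an [abm_params()]; scenario-specific flags are applied on
#'   top of it.
#' @param lattice a [hex_lattice()].
#' @param scenario one of [abm_scenarios()].
#' @param seed integer RNG seed for this replicate.
#' @param record_steps if `TRUE`, additionally record the infected-cell count
#'   and contributor fraction at every dt step (needed by
#'   [abm_increment_rate()]).
#' @param sample_times optional explicit sampling times (h); defaults to the
#'   regular `sample_every` grid plus the end of the initiation window when
#'   inoculating.
#' @return A list of class `"abm_run"` with elements `series` (data frame:
#'   `time_h`, `I_count`, `V_total`, `contrib_fraction`, `cf_fraction`,
#'   `n_cf`, `n_cc`, `n_inoc`), `final` (per-cell snapshot), `saturated`,
#'   and when requested `steps` (per-step `time_h`, `I`, `contrib`).
#' @export
run_abm <- function(params, lattice, scenario = "single_focus_cc",
                    seed = 1L, record_steps = FALSE, sample_times = NULL) {
  scenario <- match.arg(scenario, abm_scenarios())
  params <- scenario_params(params, scenario)
  if (params$inoculate && params$I0hat > lattice$n_sites)
    stop("expected inoculum `I0hat` exceeds the number of lattice sites")
  if (is.null(sample_times)) {
    sample_times <- seq(0, params$t_end, by = params$sample_every)
    if (params$inoculate)
      sample_times <- sort(unique(c(sample_times, params$t_init)))
  }
  init <- if (scenario == "single_focus_cc") hex_center(lattice) else integer()
  set.seed(seed)
  raw <- abm_run_cpp(hex_nbr0(lattice), as.integer(init), params,
                     as.numeric(sample_times), record_steps)
  if (isTRUE(raw$saturated))
    warning("infection saturated the lattice before t_end; ",
            "boundary effects dominate late time points")
  series <- data.frame(
    time_h = raw$time_h, I_count = raw$I_count, V_total = raw$V_total,
    contrib_fraction = raw$contrib_fraction,
    cf_fraction = ifelse(raw$I_count > 0, raw$n_cf / raw$I_count, NA_real_),
    n_cf = raw$n_cf, n_cc = raw$n_cc, n_inoc = raw$n_inoc)
  fin <- raw$final
  fin$mode <- c("none", "inoculum", "CF", "CC")[fin$mode + 1L]
  fin$infector <- ifelse(fin$infector > 0, fin$infector, NA_integer_)
  raw$final <- fin
  out <- list(series = series, final = raw$final,
              saturated = isTRUE(raw$saturated),
              params = params, scenario = scenario, seed = seed)
  if (record_steps)
    out$steps <- data.frame(time_h = raw$step_time_h, I = raw$step_I,
                            contrib = raw$step_contrib)
  class(out) <- "abm_run"
  out
}

#' Run replicate simulations and aggregate observables
#'
#' Replicate `r` uses seed `base_seed + r`. Aggregation returns per-time-point
#' means, empirical standard deviations across replicates and the replicate
#' count — the summary statistics the likelihood (see [log_likelihood()])
#' is built on.
#'
#' @inheritParams run_abm
#' @param n_reps number of replicates.
#' @param base_seed base RNG seed.
#' @return List with `runs` (list of [run_abm()] results) and `aggregate`
#'   (data frame: `time_h`, mean/sd of `I_count` and `V_total`,
#'   mean `contrib_fraction`, mean `cf_fraction`, `n`).
#' @export
run_abm_replicates <- function(params, lattice, scenario, n_reps = 20,
                               base_seed = 1L, record_steps = FALSE,
                               sample_times = NULL) {
  runs <- lapply(seq_len(n_reps), function(r)
    run_abm(params, lattice, scenario, seed = base_seed + r,
            record_steps = record_steps, sample_times = sample_times))
  list(runs = runs, aggregate = abm_aggregate(runs))
}

#' Aggregate replicate series into per-time summary statistics
#'
#' @param runs list of `"abm_run"` objects sharing a sampling schedule.
#' @return Data frame with one row per sampling time.
#' @export
abm_aggregate <- function(runs) {
  times <- runs[[1]]$series$time_h
  getm <- function(col) sapply(runs, function(r) r$series[[col]])
  Im <- getm("I_count"); Vm <- getm("V_total")
  data.frame(
    time_h = times,
    I_mean = rowMeans(Im), I_sd = apply(Im, 1, stats::sd),
    V_mean = rowMeans(Vm), V_sd = apply(Vm, 1, stats::sd),
    contrib_mean = rowMeans(getm("contrib_fraction"), na.rm = TRUE),
    cf_mean = rowMeans(getm("cf_fraction"), na.rm = TRUE),
    n_cf_mean = rowMeans(getm("n_cf")),
    n_cc_mean = rowMeans(getm("n_cc")),
    n_inoc_mean = rowMeans(getm("n_inoc")),
    n = length(runs))
}

#' Empirical per-step infection increments and the effective donor virus load
#'
#' From a per-step record of a cell-to-cell-only run, computes the increment
#' series `dI(t)` (per hour) and the effective average infectious load of
#' contributing cells, defined so that the identity
#' `btilde_c * Vcc * integral(I(s) fc~(s) ds) = I(t_end) - I(t_start)` holds
#' exactly (trapezoidal quadrature), with `btilde_c = sc * finf` the ABM's
#' per-RNA infectivity. The product `btilde_c * Vcc` is the transmission
#' rate per contributing cell; since the contributor fraction already
#' accounts for target availability, the equivalent per-target-cell rate of
#' the population model is `btilde_c * Vcc / T0`.
#'
#' @param steps per-step data frame (`time_h`, `I`, `contrib`) from
#'   [run_abm()] with `record_steps = TRUE`, or an `"abm_run"` object.
#' @param params the [abm_params()] used for the run.
#' @return List with `time_h`, `dI` (per h, one entry per step interval),
#'   `Vcc`, `btilde_c` (per h) and `beta_tilde_Vcc = btilde_c * Vcc`.
#' @export
abm_increment_rate <- function(steps, params) {
  if (inherits(steps, "abm_run")) steps <- steps$steps
  stopifnot(!is.null(steps))
  t <- steps$time_h; I <- steps$I; f <- steps$contrib
  f[is.na(f)] <- 0
  btilde <- params$sc * params$finf * 60  # per hour
  g <- I * f
  integ <- sum(diff(t) * (head(g, -1) + tail(g, -1)) / 2)
  if (integ <= 0) stop("contributor-weighted integral is zero")
  Vcc <- (tail(I, 1) - I[1]) / (btilde * integ)
  list(time_h = head(t, -1), dI = diff(I) / diff(t), Vcc = Vcc,
       btilde_c = btilde, beta_tilde_Vcc = btilde * Vcc)
}
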