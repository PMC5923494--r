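tt <- seq(0, 240, by = 24)

test_that("disease-free state is an equilibrium of the right-hand side", {
  pp <- ode_params(beta_f = 1e-6, beta_c = 1e-6, rho = 1, c = 0.1,
                   T0 = 1000, I0 = 0, V0 = 0)
  d <- model_rhs(c(T = 1000, I = 0, V = 0), 0, pp, model_spec("CCF"))
  expect_equal(unname(d), c(0, 0, 0))
})

test_that("T + I is conserved and dynamics are monotone without cell death", {
  ap <- adjustment_params(6, 10)
  for (mn in c("CC", "aCC", "CCF", "aCCF")) {
    pp <- ode_params(beta_f = 1e-7, beta_c = 2e-6, rho = 0.3, c = 0.06,
                     adjustment = ap, T0 = 4681, I0 = 3, V0 = 0)
    tr <- simulate_model(model_spec(mn), pp, tt)
    expect_equal(tr$T + tr$I, rep(4684, length(tt)), tolerance = 1e-8)
    expect_true(all(diff(tr$I) >= 0))
    expect_true(all(diff(tr$T) <= 0))
    expect_true(all(tr$V >= 0))
  }
})

test_that("with no transmission V follows its linear closed form", {
  pp <- ode_params(rho = 2, c = 0.06, T0 = 100, I0 = 5, V0 = 7)
  tr <- simulate_model(model_spec("CF"), pp, tt)  # beta_f = 0
  Vexact <- 7 * exp(-0.06 * tt) + (2 * 5 / 0.06) * (1 - exp(-0.06 * tt))
  expect_equal(tr$V, Vexact, tolerance = 1e-9)
  expect_equal(tr$I, rep(5, length(tt)))
  expect_equal(tr$T, rep(100, length(tt)))
})

test_that("early growth matches the linearized exponential oracle", {
  # T ~ T0 while I << T0: I(t) = I0 exp(beta_c T0 t)
  pp <- ode_params(beta_c = 1e-8, T0 = 1e6, I0 = 1e-3)
  ts <- seq(0, 100, by = 10)
  tr <- simulate_model(model_spec("CC"), pp, ts)
  expect_equal(tr$I, 1e-3 * exp(1e-8 * 1e6 * ts), tolerance = 1e-6)
})

test_that("adjusted model equals mass action while fc stays at 1", {
  # with psi*theta large the effective focus size never leaves the flat branch
  ap <- adjustment_params(6, 10, theta = 20, psi = 50L)
  pp <- ode_params(beta_c = 2e-6, adjustment = ap, T0 = 4681, I0 = 5)
  ts <- seq(0, 120, by = 12)
  tr_acc <- simulate_model(model_spec("aCC"), pp, ts)
  tr_cc <- simulate_model(model_spec("CC"), pp, ts)
  expect_lt(max(tr_acc$I) / (6 * 20 * 50), 1)  # fc = 1 regime held throughout
  expect_equal(tr_acc$I, tr_cc$I, tolerance = 1e-10)
})

test_that("delay variants reduce to their undelayed parents at tau = 0", {
  ap <- adjustment_params(6, 10)
  pp <- ode_params(beta_c = 2e-6, tau = 0, adjustment = ap, T0 = 4681, I0 = 2)
  a <- simulate_model(model_spec("aCC-dI"), pp, tt)
  b <- simulate_model(model_spec("aCC"), pp, tt)
  expect_equal(a$I, b$I, tolerance = 1e-12)
})

test_that("integrator agrees with an independent adaptive solver", {
  skip_if_not_installed("deSolve")
  ap <- adjustment_params(6, 10, theta = 1.5, psi = 2L)
  pp <- ode_params(beta_c = 1.5e-6, adjustment = ap, T0 = 4681, I0 = 8)
  tr <- simulate_model(model_spec("aCC"), pp, tt)
  rhs <- function(t, y, parms) {
    cc <- 1.5e-6 * fc_full(y[2], ap) * y[2] * y[1]
    list(c(-cc, cc))
  }
  ref <- deSolve::ode(c(T = 4681, I = 8), tt, rhs, NULL,
                      rtol = 1e-10, atol = 1e-10)
  expect_equal(tr$I, unname(ref[, "I"]), tolerance = 1e-7)

  # delayed variant against deSolve's DDE solver, both pre-histories
  for (hist in c("zero", "constant")) {
    ppd <- ode_params(beta_c = 2e-6, tau = 6, tau_history = hist,
                      adjustment = ap, T0 = 4681, I0 = 8)
    trd <- simulate_model(model_spec("aCC-dI"), ppd, tt)
    h0 <- if (hist == "constant") 8 else 0
    rhsd <- function(t, y, parms) {
      Il <- if (t - 6 < 0) h0 else deSolve::lagvalue(t - 6, 2)
      cc <- 2e-6 * fc_full(y[2], ap) * Il * y[1]
      list(c(-cc, cc))
    }
    refd <- deSolve::dede(c(T = 4681, I = 8), tt, rhsd, NULL,
                          rtol = 1e-10, atol = 1e-10)
    # the pre-history kink at t0 + tau limits local order; 1e-4 relative is
    # far below any data resolution used in fits
    expect_equal(trd$I, unname(refd[, "I"]), tolerance = 1e-4)
  }
})

test_that("halving the integration step leaves trajectories unchanged", {
  ap <- adjustment_params(6, 10)
  pp <- ode_params(beta_c = 2e-6, adjustment = ap, T0 = 4681, I0 = 2)
  a <- simulate_model(model_spec("aCC"), pp, tt, h = 0.02)
  b <- simulate_model(model_spec("aCC"), pp, tt, h = 0.01)
  expect_lt(max(abs(a$I - b$I) / pmax(b$I, 1)), 1e-6)
  ppd <- ode_params(beta_c = 2e-6, tau = 4, adjustment = ap, T0 = 4681, I0 = 2)
  ad <- simulate_model(model_spec("aCC-dI"), ppd, tt, h = 0.02)
  bd <- simulate_model(model_spec("aCC-dI"), ppd, tt, h = 0.01)
  expect_lt(max(abs(ad$I - bd$I) / pmax(bd$I, 1)), 1e-4)
})

test_that("predicted contributor series behave as bounded corrections", {
  ap <- adjustment_params(6, 10)
  pp <- ode_params(beta_c = 1e-4, adjustment = ap, T0 = 500, I0 = 1)
  tr <- simulate_model(model_spec("aCC"), pp, seq(0, 480, 24))
  pc <- predicted_contributors(tr, pp)
  expect_equal(pc$fc[1], 1)
  expect_equal(pc$fc_corrected[1], 1)
  expect_true(all(pc$fc >= pc$fc_corrected - 1e-12))
  expect_true(all(pc$fc_corrected >= 0 & pc$fc <= 1))
  # late, target-depleted limit: corrected series collapses to zero
  expect_lt(tail(pc$fc_corrected, 1), 0.05)
})

test_that("model increment series matches its defining expression", {
  ap <- adjustment_params(6, 10)
  pp <- ode_params(beta_c = 2e-6, adjustment = ap, T0 = 4681, I0 = 1)
  tr <- simulate_model(model_spec("aCC"), pp, tt)
  inc <- ode_increment(tr, pp)
  expect_equal(inc$dI, 2e-6 * fc_full(tr$I, ap) * tr$I * tr$T)
  # I = 0 gives zero increment; fc = 1, T = T0 gives the mass-action rate
  tr0 <- data.frame(time = 0, T = 100, I = 0, V = 0)
  expect_equal(ode_increment(tr0, pp)$dI, 0)
  tr1 <- data.frame(time = 0, T = 4681, I = 3, V = 0)
  expect_equal(ode_increment(tr1, pp, adjust = FALSE)$dI, 2e-6 * 3 * 4681)
})

test_that("invalid inputs are rejected", {
  expect_error(ode_params(beta_c = -1, T0 = 10), "rates")
  expect_error(ode_params(T0 = 0), "T0")
  pp <- ode_params(beta_c = 1e-6, tau = 500, T0 = 10)
  expect_error(simulate_model(model_spec("aCC-dI"), pp, tt), "tau")
  expect_error(simulate_model(model_spec("CC"), pp, rev(tt)), "ascending")
})
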