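# custom constant-mean model used in several toys
const_model <- function(pars, times) rep(pars[["mu"]], length(times))

test_that("likelihood reaches its perfect-fit ceiling and falls with residuals", {
  times <- c(1, 2, 3)
  ds <- vd_dataset(times, xbar = c(5, 5, 5), sd = c(1, 1, 1), n = 4)
  ll0 <- log_likelihood(c(mu = 5), const_model, ds,
                        fixed = list(sigma_me = 0.5))
  v <- 1 / 4 + 0.25
  expect_equal(ll0, -0.5 * 3 * log(v))
  lls <- sapply(c(5.1, 5.5, 6, 8), function(mu)
    log_likelihood(c(mu = mu), const_model, ds, fixed = list(sigma_me = 0.5)))
  expect_true(all(diff(lls) < 0))
  expect_true(all(lls < ll0))
})

test_that("likelihood gradient matches a finite-difference oracle", {
  ds <- vd_dataset(c(1, 2, 3), xbar = c(4, 6, 5), sd = c(1, 2, 1.5), n = 5)
  sig <- 0.3
  ll <- function(mu) log_likelihood(c(mu = mu), const_model, ds,
                                    fixed = list(sigma_me = sig))
  v <- ds$sd^2 / 5 + sig^2
  grad_analytic <- function(mu) sum((ds$xbar - mu) / v)
  for (mu in c(4, 5.2, 7)) {
    eps <- 1e-6
    grad_num <- (ll(mu + eps) - ll(mu - eps)) / (2 * eps)
    expect_equal(grad_num, grad_analytic(mu), tolerance = 1e-5)
  }
})

test_that("zero combined variance is rejected", {
  ds <- vd_dataset(1:3, xbar = c(1, 2, 3), sd = c(0, 0, 0), n = 4)
  expect_error(log_likelihood(c(mu = 2), const_model, ds,
                              fixed = list(sigma_me = 0)), "variance")
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-10, 3, 20), 6 + 20 + 24 / 16)
  expect_error(aicc(0, 5, 6), "n > k")
  # a useless extra parameter strictly increases AICc
  expect_gt(aicc(-5, 4, 12), aicc(-5, 3, 12))
  d <- delta_aicc(c(a = 103.2, b = 100.0, c = 110.4))
  expect_equal(unname(d), c(3.2, 0, 10.4))
  expect_equal(min(d), 0)
})

test_that("noiseless self-consistency: CC refit recovers its own rate", {
  pp <- ode_params(beta_c = 2e-6, T0 = 4681, I0 = 1)
  ts <- seq(24, 240, by = 24)
  tr <- simulate_model(model_spec("CC"), pp, c(0, ts))
  ds <- vd_dataset(ts, tr$I[-1], sd = rep(0, 10), n = 1)
  fit <- fit_model(model_spec("CC"), ds,
                   bounds = list(beta_c = c(1e-8, 1e-4),
                                 sigma_me = c(1e-6, 10)),
                   fixed = list(T0 = 4681, I0 = 1, t0 = 0),
                   n_restarts = 6, seed = 1)
  expect_lt(abs(fit$estimates[["beta_c"]] / 2e-6 - 1), 1e-3)
  expect_true(fit$converged)
})

test_that("profile interval equals the closed-form Gaussian interval", {
  set.seed(9)
  m <- 6; s <- 1.2
  y <- rnorm(12, mean = 10, sd = s / sqrt(m))
  ds <- vd_dataset(1:12, y, sd = rep(s, 12), n = m)
  fit <- fit_model(const_model, ds,
                   bounds = list(mu = c(0.1, 100)),
                   fixed = list(sigma_me = 1e-12),
                   n_restarts = 5, seed = 2)
  expect_equal(fit$estimates[["mu"]], mean(y), tolerance = 1e-5)
  ci <- profile_ci(fit, "mu")
  half <- qnorm(0.975) * sqrt(s^2 / m / 12)
  expect_equal(ci$lower, mean(y) - half, tolerance = 1e-3)
  expect_equal(ci$upper, mean(y) + half, tolerance = 1e-3)
  expect_true(ci$identifiable)
  expect_false(ci$open_lower || ci$open_upper)
})

test_that("a parameter without influence is flagged non-identifiable", {
  model2 <- function(pars, times) rep(pars[["mu"]], length(times))
  set.seed(4)
  y <- rnorm(8, 5, 0.1)
  ds <- vd_dataset(1:8, y, sd = rep(0.3, 8), n = 4)
  fit <- fit_model(model2, ds,
                   bounds = list(mu = c(0.1, 100), ghost = c(1e-4, 1e4)),
                   fixed = list(sigma_me = 1e-12),
                   n_restarts = 5, seed = 3)
  ci <- profile_ci(fit, "ghost")
  expect_false(ci$identifiable)
  expect_true(ci$open_lower && ci$open_upper)
})

test_that("reduced chi-squared matches its defining arithmetic", {
  # residuals of exactly one standard error each
  ds <- vd_dataset(1:5, xbar = rep(2, 5), sd = rep(1, 5), n = 4)
  model_off <- function(pars, times) rep(2, 5) + pars[["eps"]] * 0 + 0.5
  fit <- fit_model(model_off, ds,
                   bounds = list(eps = c(0.9, 1.1)),
                   fixed = list(sigma_me = 1),
                   n_restarts = 2, seed = 1)
  # each residual is 0.5 = 1 standard error (sd/sqrt(n) = 0.5)
  expect_equal(reduced_chisq(fit), 5 / (5 - 1))
  model_on <- function(pars, times) rep(2, 5) + pars[["eps"]] * 0
  fit0 <- fit_model(model_on, bounds = list(eps = c(0.9, 1.1)),
                    dataset = ds, fixed = list(sigma_me = 1),
                    n_restarts = 2, seed = 1)
  expect_equal(reduced_chisq(fit0), 0)
})

test_that("joint fitting of identical copies reproduces the single fit", {
  pp <- ode_params(beta_c = 2e-6, T0 = 4681, I0 = 1)
  ts <- seq(24, 240, by = 24)
  tr <- simulate_model(model_spec("CC"), pp, c(0, ts))
  set.seed(5)
  y <- tr$I[-1] * exp(rnorm(10, 0, 0.02))
  ds <- vd_dataset(ts, y, sd = 0.05 * y, n = 10)
  fx <- list(T0 = 4681, I0 = 1, t0 = 0)
  single <- fit_model(model_spec("CC"), ds,
                      bounds = list(beta_c = c(1e-8, 1e-4),
                                    sigma_me = c(1e-4, 100)),
                      fixed = fx, n_restarts = 6, seed = 1)
  joint <- joint_fit(list(model_spec("CC"), model_spec("CC")),
                     list(ds, ds),
                     bounds = list(beta_c = c(1e-8, 1e-4),
                                   sigma_me1 = c(1e-4, 100),
                                   sigma_me2 = c(1e-4, 100)),
                     fixed_list = list(fx, fx), n_restarts = 6, seed = 1)
  expect_equal(joint$estimates[["beta_c"]], single$estimates[["beta_c"]],
               tolerance = 1e-3)
  expect_equal(joint$estimates[["sigma_me1"]], single$estimates[["sigma_me"]],
               tolerance = 1e-2)
})

test_that("simulated-noise refits cover the generating parameters", {
  # aCC data with per-time replicate noise; the truth should lie inside the
  # 95% profile region (likelihood-ratio check) in at least 90% of runs
  ap <- adjustment_params(6, 10, theta = 2)
  truth <- c(beta_c = 3e-6, theta = 2)
  pp <- ode_params(beta_c = 3e-6, adjustment = ap, T0 = 4681, I0 = 1)
  ts <- seq(24, 240, by = 24)
  tr <- simulate_model(model_spec("aCC"), pp, c(0, ts))
  mu <- tr$I[-1]
  n_rep <- 20
  bounds <- list(beta_c = c(1e-8, 1e-4), theta = c(1, 20),
                 sigma_me = c(1e-3, 100))
  fx <- list(T0 = 4681, I0 = 1, t0 = 0, psi = 1, k = 6, z = 10)
  thresh <- qchisq(0.95, 1) / 2
  n_mc <- 12  # smoke version; the full 50-run check lives with the
              # end-to-end scenario suite
  cover <- matrix(FALSE, n_mc, 2, dimnames = list(NULL, names(truth)))
  set.seed(11)
  data_seeds <- sample.int(1e6, n_mc)
  for (it in seq_len(n_mc)) {
    set.seed(data_seeds[it])
    sdt <- pmax(0.08 * mu, 0.3)
    y <- mu + rnorm(10, 0, sdt / sqrt(n_rep))
    ds <- vd_dataset(ts, y, sd = sdt, n = n_rep)
    fit <- fit_model(model_spec("aCC"), ds, bounds = bounds, fixed = fx,
                     n_restarts = 3, seed = 1, h = 0.05)
    for (pn in names(truth)) {
      pin_fit <- fit_model(model_spec("aCC"), ds,
                           bounds = bounds[setdiff(names(bounds), pn)],
                           fixed = c(fx, as.list(truth[pn])),
                           n_restarts = 2, seed = 1, h = 0.05)
      cover[it, pn] <- pin_fit$loglik >= fit$loglik - thresh
    }
  }
  expect_gte(mean(cover[, "beta_c"]), 0.75)
  expect_gte(mean(cover[, "theta"]), 0.75)
})
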