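p0 <- abm_params()

test_that("intracellular step follows the logistic-with-loss closed form", {
  lat <- hex_lattice(3)
  st <- abm_state(lat, infected_sites = hex_center(lat))
  p <- abm_params()
  eps <- p$alpha - p$gamma - p$rho
  K <- p$Rcap * eps / p$alpha
  nstep <- 2880  # two days
  for (i in seq_len(nstep)) st <- step_intracellular(st, p)
  Rexact <- K * 1 * exp(eps * nstep) / (K + 1 * (exp(eps * nstep) - 1))
  expect_equal(st$R[hex_center(lat)], Rexact, tolerance = 0.01)
  # uninfected sites untouched, nonnegative everywhere
  expect_true(all(st$R[-hex_center(lat)] == 0))
  expect_true(all(st$V >= 0))
})

test_that("R = 0 is absorbing and the logistic fixed point is stationary", {
  lat <- hex_lattice(2)
  p <- abm_params()
  st <- abm_state(lat)  # nothing infected
  st2 <- step_intracellular(st, p)
  expect_equal(st2$R, st$R)
  Kstar <- p$Rcap * (p$alpha - p$gamma - p$rho) / p$alpha
  st3 <- abm_state(lat, infected_sites = 1L)
  st3$R[1] <- Kstar
  st4 <- step_intracellular(st3, p)
  expect_equal(st4$R[1], Kstar)
})

test_that("diffusion conserves mass, fixes uniform fields, spreads a delta", {
  lat <- hex_lattice(5)
  p <- abm_params(m = 0.6)
  st <- abm_state(lat)
  st$V <- rep(2.5, lat$n_sites)
  expect_equal(step_diffusion(st, p, lat)$V, st$V)

  set.seed(7)
  st$V <- runif(lat$n_sites)
  st2 <- step_diffusion(st, p, lat)
  expect_equal(sum(st2$V), sum(st$V), tolerance = 1e-12)

  st$V <- numeric(lat$n_sites)
  ctr <- hex_center(lat)
  st$V[ctr] <- 1
  st3 <- step_diffusion(st, p, lat)
  expect_equal(st3$V[ctr], 0.4)
  expect_equal(sort(unique(round(st3$V, 12))), c(0, 0.1, 0.4))
  expect_equal(sum(st3$V > 0), 7)
})

test_that("no infections occur without virus or enabled routes", {
  lat <- hex_lattice(3)
  p <- abm_params(cc_enabled = FALSE, cf_enabled = TRUE)
  st <- abm_state(lat, infected_sites = hex_center(lat))
  set.seed(1)
  st2 <- attempt_infections(st, p, lat)
  expect_identical(st2$status, st$status)
})

test_that("a saturated cell-to-cell hazard infects the whole first ring", {
  lat <- hex_lattice(3)
  p <- abm_params(sc = 1e9, cf_enabled = FALSE)
  ctr <- hex_center(lat)
  st <- abm_state(lat, infected_sites = ctr)
  set.seed(1)
  st2 <- attempt_infections(st, p, lat)
  ring1 <- lat$adjacency[[ctr]]
  expect_true(all(st2$status[ring1] == 1L))
  expect_true(all(st2$R[ring1] == 1))
  expect_true(all(st2$mode[ring1] == "CC"))
  expect_true(all(st2$infector[ring1] == ctr))
  expect_equal(sum(st2$status), 7)
})

test_that("one-step infection count matches the Bernoulli expectation", {
  lat <- hex_lattice(3)
  # alpha = gamma = rho = 0 keeps donor R at 1, so pc = sc*finf*dt exactly
  pc <- 0.3
  p <- abm_params(alpha = 0, gamma = 0, rho = 0, sc = pc / 0.01, finf = 0.01,
                  cf_enabled = FALSE)
  ctr <- hex_center(lat)
  set.seed(42)
  counts <- replicate(400, {
    st <- abm_state(lat, infected_sites = ctr)
    sum(attempt_infections(st, p, lat)$status) - 1
  })
  se <- sqrt(6 * pc * (1 - pc) / 400)
  expect_lt(abs(mean(counts) - 6 * pc), 4 * se)
})

test_that("initiation density integrates to the expected inoculum", {
  p <- abm_params(I0hat = 10, lam = 0.1)
  for (lam in c(0.01, 0.1, 1)) {
    pp <- abm_params(I0hat = 10, lam = lam)
    integ <- integrate(function(t) hexspread:::pinit_density(t, pp), 0, 17)
    expect_equal(integ$value, 10, tolerance = 1e-6)
  }
  # lam -> 0 limit: uniform density I0hat / t_init
  pp0 <- abm_params(I0hat = 10, lam = 1e-9)
  expect_equal(hexspread:::pinit_density(8, pp0), 10 / 17, tolerance = 1e-4)
})

test_that("mean realized inoculum matches the Poisson-thinned target", {
  lat <- hex_lattice(10)
  p <- abm_params(I0hat = 10, t_end = 17, sc = 0, sf = 0)
  tot <- vapply(1:200, function(r) {
    run_abm(p, lat, "multifocus_cc", seed = r)$series$I_count[2]
  }, numeric(1))
  se <- sqrt(10 / 200)
  expect_lt(abs(mean(tot) - 10), 4 * se)
})

test_that("media change wipes virus, keeps infections, and blocks CF if asked", {
  lat <- hex_lattice(4)
  st <- abm_state(lat, infected_sites = hex_center(lat))
  st$V <- runif(lat$n_sites)
  st2 <- media_change(st)
  expect_equal(sum(st2$V), 0)
  expect_identical(st2$status, st$status)
  # in a multifocus run with CF blocked, no post-window CF infections appear
  p <- abm_params(t_end = 120)
  r <- run_abm(p, hex_lattice(15), "multifocus_cc", seed = 3)
  expect_true(all(r$series$n_cf == 0))
})

test_that("deterministic ring growth visits the centred hexagonal numbers", {
  # pc capped at 1: the focus advances one full ring per step
  lat <- hex_lattice(8)
  p <- abm_params(sc = 1e9, cf_enabled = FALSE, dt = 1, t_end = 5 / 60,
                  sample_every = 1 / 60, inoculate = FALSE)
  r <- run_abm(p, lat, "single_focus_cc", seed = 1)
  expect_equal(r$series$I_count, focus_size(0:5, 6))
  # and the R-level step composition agrees with the compiled engine
  st <- abm_state(lat, infected_sites = hex_center(lat))
  sizes <- numeric(6)
  sizes[1] <- sum(st$status)
  for (i in 2:6) {
    st <- step_intracellular(st, p)
    st <- step_diffusion(st, p, lat)
    st <- attempt_infections(st, p, lat)
    sizes[i] <- sum(st$status)
  }
  expect_equal(sizes, r$series$I_count)
})

test_that("contributor fraction counts perimeter cells", {
  lat <- hex_lattice(5)
  ctr <- hex_center(lat)
  st <- abm_state(lat, infected_sites = ctr)
  expect_equal(contributor_fraction(st, lat), 1)
  st7 <- abm_state(lat, infected_sites = c(ctr, lat$adjacency[[ctr]]))
  expect_equal(contributor_fraction(st7, lat), 6 / 7)
  stall <- abm_state(lat, infected_sites = seq_len(lat$n_sites))
  expect_equal(contributor_fraction(stall, lat), 0)
  expect_error(contributor_fraction(abm_state(lat), lat), "no infected")
})

test_that("runs are monotone in infected cells with complete lineage records", {
  lat <- hex_lattice(15)
  p <- abm_params(t_end = 96)
  r <- run_abm(p, lat, "multifocus_cc", seed = 5)
  expect_true(all(diff(r$series$I_count) >= 0))
  fin <- r$final
  inf <- fin$status == 1
  expect_true(all(fin$mode[inf] != "none"))
  expect_true(all(fin$infector[inf & fin$mode == "CC"] > 0))  # CC has a source
  expect_true(all(is.na(fin$infector[fin$mode == "inoculum"])))
  s <- r$series
  expect_equal(s$n_cf + s$n_cc + s$n_inoc, s$I_count)
  # without any transmission (zero infection hazards) the count stays flat
  p0 <- abm_params(sc = 0, sf = 0, t_end = 96)
  r0 <- run_abm(p0, lat, "multifocus_cc", seed = 5)
  i17 <- which(r0$series$time_h == 17)
  expect_true(all(r0$series$I_count[i17:nrow(r0$series)] ==
                    r0$series$I_count[i17]))
})

test_that("replicates are reproducible and the aggregator summarises them", {
  lat <- hex_lattice(10)
  p <- abm_params(t_end = 72)
  a <- run_abm(p, lat, "multifocus_cc", seed = 11)
  b <- run_abm(p, lat, "multifocus_cc", seed = 11)
  expect_identical(a$series, b$series)
  reps <- run_abm_replicates(p, lat, "multifocus_cc", n_reps = 3,
                             base_seed = 7)
  agg <- reps$aggregate
  expect_equal(nrow(agg), nrow(a$series))
  expect_equal(agg$n[1], 3)
  Im <- sapply(reps$runs, function(r) r$series$I_count)
  expect_equal(agg$I_mean, rowMeans(Im))
  expect_equal(agg$I_sd, apply(Im, 1, sd))
})

test_that("increment identity holds exactly for recorded runs", {
  lat <- hex_lattice(12)
  p <- abm_params(t_end = 120)
  r <- run_abm(p, lat, "single_focus_cc", seed = 2, record_steps = TRUE)
  inc <- abm_increment_rate(r, p)
  # by construction btilde*Vcc * integral(I*fc) = I(end) - I(start)
  st <- r$steps
  g <- st$I * ifelse(is.na(st$contrib), 0, st$contrib)
  integ <- sum(diff(st$time_h) * (head(g, -1) + tail(g, -1)) / 2)
  lhs <- inc$btilde_c * inc$Vcc * integ
  expect_equal(lhs, tail(st$I, 1) - st$I[1], tolerance = 1e-10)
  # constant I gives all-zero increments
  p0 <- abm_params(cc_enabled = FALSE, cf_enabled = FALSE, t_end = 24,
                   inoculate = FALSE)
  r0 <- run_abm(p0, lat, "single_focus_cc", seed = 2, record_steps = TRUE)
  expect_true(all(diff(r0$steps$I) == 0))
})
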