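#include <Rcpp.h>
using namespace Rcpp;

// Agent-based simulation of viral spread on a hexagonal monolayer.
//
// Per-site state: infection status, intracellular RNA R, local extracellular
// virus V, infection time/mode/source. One dt step applies, in order:
// scheduled events (inoculation during the initiation window, media change at
// its end, observable sampling), then intracellular replication/export
// (explicit Euler), synchronous neighbour-exchange diffusion, and stochastic
// infection attempts (cell-free from local virus, cell-to-cell from infected
// neighbours). Newly infected cells are applied synchronously at the end of
// the step. Uses R's RNG so results are reproducible via set.seed().
//
// Bookkeeping kept incrementally for speed: per-site count of infected
// neighbours (restricts the cell-to-cell scan to the infection frontier) and
// the number of infected cells that still have an uninfected neighbour (the
// contributor count).

enum { MODE_NONE = 0, MODE_INOC = 1, MODE_CF = 2, MODE_CC = 3 };

// has the infected cell i at least one uninfected neighbour?
static inline bool is_contrib(int i, const IntegerVector &status,
                              const IntegerMatrix &nbr) {
  for (int d = 0; d < 6; ++d) {
    int j = nbr(i, d);
    if (j > 0 && status[j - 1] == 0) return true;
  }
  return false;
}

// [[Rcpp::export]]
List abm_run_cpp(IntegerMatrix nbr, IntegerVector init_infected, List params,
                 NumericVector sample_times_h, bool record_steps) {
  const int n = nbr.nrow();
  const double alpha  = params["alpha"],  Rcap = params["Rcap"];
  const double gamma  = params["gamma"],  rho  = params["rho"];
  const double cclear = params["c"],      finf = params["finf"];
  const double m      = params["m"],      sf   = params["sf"];
  const double sc     = params["sc"];
  const double I0hat  = params["I0hat"],  lam  = params["lam"];
  const double t_init_h = params["t_init"], dt = params["dt"];
  const double t_end_h  = params["t_end"];
  const bool cf_enabled = params["cf_enabled"];
  const bool cc_enabled = params["cc_enabled"];
  const bool cf_block   = params["cf_blocked_after_init"];
  const bool do_inoc    = params["inoculate"];

  if (alpha * dt >= 0.5)
    stop("time step too coarse for the intracellular update (alpha*dt >= 0.5)");

  const double dt_h = dt / 60.0;
  const long nsteps = (long)std::llround(t_end_h * 60.0 / dt);

  IntegerVector status(n, 0);
  NumericVector Rv(n, 0.0), Vv(n, 0.0), Vnew(n, 0.0);
  NumericVector infected_at(n, NA_REAL);
  IntegerVector mode(n, MODE_NONE), infector(n, 0);
  std::vector<int> inf_nbr(n, 0);   // infected neighbours per site
  std::vector<char> contrib(n, 0);  // infected and has uninfected neighbour
  int n_contrib = 0;

  int n_inf = 0, n_cf = 0, n_cc = 0, n_inoc = 0;

  auto infect = [&](int i, int md, int src, double t_h) {
    status[i] = 1; Rv[i] = 1.0; infected_at[i] = t_h; mode[i] = md;
    infector[i] = src;
    ++n_inf;
    if (md == MODE_INOC) ++n_inoc;
    else if (md == MODE_CF) ++n_cf;
    else ++n_cc;
    if (is_contrib(i, status, nbr)) { contrib[i] = 1; ++n_contrib; }
    for (int d = 0; d < 6; ++d) {
      int j = nbr(i, d);
      if (j <= 0) continue;
      int jj = j - 1;
      ++inf_nbr[jj];
      if (contrib[jj] && !is_contrib(jj, status, nbr)) {
        contrib[jj] = 0; --n_contrib;
      }
    }
  };

  for (int ii = 0; ii < init_infected.size(); ++ii)
    infect(init_infected[ii] - 1, MODE_INOC, 0, 0.0);
  n_inoc = init_infected.size();  // seeds count as inoculum

  const int ns = sample_times_h.size();
  NumericVector out_t(ns), out_V(ns), out_contrib(ns);
  IntegerVector out_I(ns), out_cf(ns), out_cc(ns), out_inoc(ns);
  int sptr = 0;

  NumericVector step_I, step_contrib;
  if (record_steps) {
    step_I = NumericVector(nsteps + 1);
    step_contrib = NumericVector(nsteps + 1);
  }

  std::vector<int> pending_site, pending_mode, pending_infector;
  std::vector<int> donor_loss(n, 0);
  int donors[6];

  bool media_done = false;
  bool cf_on = cf_enabled;
  bool saturated = false;

  RNGScope rng;

  for (long step = 0; step <= nsteps; ++step) {
    const double t_h = step * dt_h;

    // inoculation: Poisson thinning of the initiation density
    if (do_inoc && t_h < t_init_h && n_inf < n) {
      double pinit = I0hat * lam * std::exp(-lam * t_h) /
                     (1.0 - std::exp(-t_init_h * lam));
      int nnew = (int)R::rpois(pinit * dt_h);
      for (int jj = 0; jj < nnew && n_inf < n; ++jj) {
        int i;
        do { i = (int)std::floor(unif_rand() * n); } while (status[i] != 0);
        infect(i, MODE_INOC, 0, t_h);
      }
    }

    // media change at the end of the initiation window
    if (do_inoc && !media_done && t_h >= t_init_h - 1e-9) {
      std::fill(Vv.begin(), Vv.end(), 0.0);
      if (cf_block) cf_on = false;
      media_done = true;
    }

    // sampling
    while (sptr < ns && sample_times_h[sptr] <= t_h + 1e-9) {
      out_t[sptr] = sample_times_h[sptr];
      out_I[sptr] = n_inf;
      out_V[sptr] = std::accumulate(Vv.begin(), Vv.end(), 0.0);
      out_contrib[sptr] = n_inf == 0 ? NA_REAL : (double)n_contrib / n_inf;
      out_cf[sptr] = n_cf; out_cc[sptr] = n_cc; out_inoc[sptr] = n_inoc;
      ++sptr;
    }
    if (record_steps) {
      step_I[step] = n_inf;
      step_contrib[step] = n_inf == 0 ? NA_REAL : (double)n_contrib / n_inf;
    }
    if (step == nsteps) break;
    if (n_inf == n) saturated = true;

    // intracellular replication / export and extracellular clearance
    for (int i = 0; i < n; ++i) {
      double Ri = Rv[i];
      if (Ri > 0.0)
        Rv[i] = Ri + dt * (alpha * Ri * (1.0 - Ri / Rcap) - (gamma + rho) * Ri);
      Vv[i] += dt * (finf * rho * Ri - cclear * Vv[i]);
      if (Rv[i] < 0.0 || Vv[i] < 0.0)
        stop("negative state produced: reduce dt");
    }

    // synchronous neighbour-exchange diffusion (conservative, no-flux)
    if (m > 0.0) {
      const double mk = m / 6.0;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int d = 0; d < 6; ++d) {
          int j = nbr(i, d);
          if (j > 0) acc += Vv[j - 1] - Vv[i];
        }
        Vnew[i] = Vv[i] + mk * acc;
      }
      std::copy(Vnew.begin(), Vnew.end(), Vv.begin());
    }

    // infection attempts (synchronous: post-dynamics fields, pre-step
    // infection statuses)
    if ((cf_on || cc_enabled) && n_inf < n) {
      pending_site.clear(); pending_mode.clear(); pending_infector.clear();
      for (int i = 0; i < n; ++i) {
        if (status[i] != 0) continue;
        const bool try_cc = cc_enabled && inf_nbr[i] > 0;
        const bool try_cf = cf_on && Vv[i] > 0.0;
        if (!try_cc && !try_cf) continue;
        int new_mode = MODE_NONE, src = 0;
        if (try_cf) {
          double p = sf * Vv[i] * dt;
          if (p > 1.0) p = 1.0;
          if (unif_rand() < p) new_mode = MODE_CF;
        }
        if (new_mode == MODE_NONE && try_cc) {
          int nd = 0;
          for (int d = 0; d < 6; ++d) {
            int j = nbr(i, d);
            if (j > 0 && status[j - 1] == 1 && mode[j - 1] != MODE_NONE)
              donors[nd++] = j - 1;
          }
          // Fisher-Yates shuffle; first successful donor wins
          for (int a = nd - 1; a > 0; --a) {
            int b = (int)std::floor(unif_rand() * (a + 1));
            std::swap(donors[a], donors[b]);
          }
          for (int a = 0; a < nd; ++a) {
            double p = sc * finf * Rv[donors[a]] * dt;
            if (p > 1.0) p = 1.0;
            if (unif_rand() < p) { new_mode = MODE_CC; src = donors[a] + 1; break; }
          }
        }
        if (new_mode != MODE_NONE) {
          pending_site.push_back(i);
          pending_mode.push_back(new_mode);
          pending_infector.push_back(src);
          if (new_mode == MODE_CC) ++donor_loss[src - 1];
        }
      }
      for (size_t p = 0; p < pending_site.size(); ++p)
        infect(pending_site[p], pending_mode[p], pending_infector[p],
               t_h + dt_h);
      for (size_t p = 0; p < pending_site.size(); ++p) {
        int s = pending_infector[p];
        if (s > 0 && donor_loss[s - 1] > 0) {
          // transfer bookkeeping: donor loses one RNA copy per transmission
          Rv[s - 1] = std::max(0.0, Rv[s - 1] - donor_loss[s - 1]);
          donor_loss[s - 1] = 0;
        }
      }
    }
  }

  List out = List::create(
    _["time_h"] = out_t, _["I_count"] = out_I, _["V_total"] = out_V,
    _["contrib_fraction"] = out_contrib,
    _["n_cf"] = out_cf, _["n_cc"] = out_cc, _["n_inoc"] = out_inoc,
    _["saturated"] = saturated,
    _["final"] = List::create(
      _["status"] = status, _["R"] = Rv, _["V"] = Vv,
      _["infected_at"] = infected_at, _["mode"] = mode,
      _["infector"] = infector));
  if (record_steps) {
    NumericVector st(nsteps + 1);
    for (long s = 0; s <= nsteps; ++s) st[s] = s * dt_h;
    out["step_time_h"] = st;
    out["step_I"] = step_I;
    out["step_contrib"] = step_contrib;
  }
  return out;
}
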