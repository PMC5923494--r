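#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 / method-of-steps integrator for the virus-dynamics model
// family (target cells T, infected cells I, extracellular virus V):
//
//   dT/dt = -bf V T - fc(I) bc I(t - tau) T
//   dI/dt = +bf V T + fc(I) bc I(t - tau) T
//   dV/dt =  rho I - c V                      (only when the V channel is on)
//
// Cell death is outside scope (delta_T = delta_I = 0), so T + I is conserved.
// fc is the perimeter-fraction adjustment evaluated at the current I scaled
// by phi = psi*theta; with `adjust = false` fc = 1 (mass action). The delay
// uses the stored I history on the integration grid; before t0 the lagged
// concentration is `hist0` (0 for the eclipse reading, I0 for a constant
// pre-history).

struct FcPars { bool adjust; double k, z, phi, a, b; };

static inline double fc_eval(double I, const FcPars &fp) {
  if (!fp.adjust) return 1.0;
  double Ieff = I / fp.phi;
  if (Ieff <= fp.k) return 1.0;
  if (Ieff < fp.k + fp.z) {
    double d = Ieff - fp.k;
    return fp.a * d * d * d + fp.b * d * d + 1.0;
  }
  double s = std::sqrt(fp.k * fp.k + 8.0 * fp.k * Ieff - 8.0 * fp.k);
  return (s - fp.k) / (2.0 * Ieff);
}

// [[Rcpp::export]]
NumericMatrix ode_traj_cpp(NumericVector times, double T0, double I0,
                           double V0, double bf, double bc, double rho,
                           double cclear, double tau, bool use_v, bool adjust,
                           double k, double z, double phi, double a, double b,
                           double h, double hist0) {
  const int nt = times.size();
  if (nt < 1) stop("no output times");
  const double t0 = times[0], tend = times[nt - 1];
  if (tend < t0) stop("times must be ascending");
  FcPars fp{adjust, k, z, phi, a, b};

  if (tend - t0 <= 0) {
    NumericMatrix out0(nt, 3);
    for (int i = 0; i < nt; ++i) {
      out0(i, 0) = T0; out0(i, 1) = I0; out0(i, 2) = V0;
    }
    return out0;
  }

  long nsteps = (long)std::ceil((tend - t0) / h - 1e-12);
  if (nsteps < 1) nsteps = 1;
  h = (tend - t0) / nsteps;  // uniform grid (last step never truncated)

  std::vector<double> Ihist(nsteps + 1);
  Ihist[0] = I0;

  // lagged I at absolute time s (grid interpolation, constant pre-history)
  long known = 0;  // highest grid index with a stored value
  auto Ilag = [&](double s) -> double {
    double u = s - tau;
    if (u < t0) return hist0;   // pre-history (0: eclipse; I0: constant)
    if (u == t0) return I0;
    double x = (u - t0) / h;
    long j = (long)std::floor(x);
    if (j >= known) return Ihist[known];
    double w = x - j;
    return (1.0 - w) * Ihist[j] + w * Ihist[j + 1];
  };

  double Tn = T0, In = I0, Vn = V0;
  NumericMatrix out(nt, 3);
  int optr = 0;
  auto emit = [&](double tcur, double Tc, double Ic, double Vc,
                  double tprev, double Tp, double Ip, double Vp) {
    while (optr < nt && times[optr] <= tcur + 1e-9) {
      double tt = times[optr];
      double w = (tcur > tprev) ? (tt - tprev) / (tcur - tprev) : 1.0;
      if (w < 0) w = 0; if (w > 1) w = 1;
      out(optr, 0) = Tp + w * (Tc - Tp);
      out(optr, 1) = Ip + w * (Ic - Ip);
      out(optr, 2) = Vp + w * (Vc - Vp);
      ++optr;
    }
  };
  emit(t0, Tn, In, Vn, t0, Tn, In, Vn);

  auto deriv = [&](double t, double T, double I, double V,
                   double &dT, double &dI, double &dV) {
    double Il = (tau > 0.0) ? Ilag(t) : I;
    double cc = fc_eval(I, fp) * bc * Il * T;
    double cf = use_v ? bf * V * T : 0.0;
    dT = -(cf + cc);
    dI = cf + cc;
    dV = use_v ? rho * I - cclear * V : 0.0;
    if (!std::isfinite(dI)) stop("non-finite derivative (check parameters)");
  };

  for (long s = 0; s < nsteps; ++s) {
    double t = t0 + s * h;
    double hh = h;
    double k1T, k1I, k1V, k2T, k2I, k2V, k3T, k3I, k3V, k4T, k4I, k4V;
    deriv(t, Tn, In, Vn, k1T, k1I, k1V);
    deriv(t + hh / 2, Tn + hh / 2 * k1T, In + hh / 2 * k1I, Vn + hh / 2 * k1V,
          k2T, k2I, k2V);
    deriv(t + hh / 2, Tn + hh / 2 * k2T, In + hh / 2 * k2I, Vn + hh / 2 * k2V,
          k3T, k3I, k3V);
    deriv(t + hh, Tn + hh * k3T, In + hh * k3I, Vn + hh * k3V, k4T, k4I, k4V);
    double Tp = Tn, Ip = In, Vp = Vn;
    Tn += hh / 6 * (k1T + 2 * k2T + 2 * k3T + k4T);
    In += hh / 6 * (k1I + 2 * k2I + 2 * k3I + k4I);
    Vn += hh / 6 * (k1V + 2 * k2V + 2 * k3V + k4V);
    if (Tn < 0) Tn = 0;
    if (Vn < 0) Vn = 0;
    Ihist[s + 1] = In;
    known = s + 1;
    emit(t + hh, Tn, In, Vn, t, Tp, Ip, Vp);
  }
  while (optr < nt) {  // numerical guard for times at tend
    out(optr, 0) = Tn; out(optr, 1) = In; out(optr, 2) = Vn; ++optr;
  }
  return out;
}
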