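#include <Rcpp.h>
using namespace Rcpp;

// Inner iteration loop for one output interval of the column solver.
// Scalar-per-species transport coefficients (the default model); the R
// engine in run-simulation.R covers per-boundary coefficient arrays and is
// the reference implementation the compiled path is tested against.
//
// Per iteration: explicit diffusion, upwind sedimentation transfer,
// optional Langmuir partition of the bottom compartment, optional
// dissolution increment.  Mirrors the arithmetic of diffusion_step(),
// sedimentation_step(), langmuir_partition() and apply_dissolution().

static double fd_at(int mode, double f0, double rate_h, double ramp_end_h,
                    double fmax, double t) {
  double f;
  switch (mode) {
  case 2:  f = f0 + rate_h * t / 3600.0; break;
  case 3: {
    double x = t / (ramp_end_h * 3600.0);
    if (x > 1.0) x = 1.0;
    f = f0 + (fmax - f0) * x;
    break;
  }
  default: f = f0;
  }
  return f > 1.0 ? 1.0 : f;
}

// [[Rcpp::export]]
List dg_core_interval(NumericMatrix C_in, NumericVector bound_in,
                      double dissolved_areal,
                      NumericVector D, NumericVector S,
                      double h, double dt, int nsteps, double t0,
                      double conc_k,
                      bool langmuir, double KD,
                      NumericVector rho_EV,
                      NumericVector d0, NumericVector d_cur_in,
                      int diss_mode, double f0, double rate_h,
                      double ramp_end_h, double fmax,
                      double C0, double H, bool clamped_in) {
  const double grav = 9.80665, NAvog = 6.02214076e23;
  NumericMatrix C = clone(C_in);
  NumericVector bound = clone(bound_in);
  NumericVector d_cur = clone(d_cur_in);
  const int n = C.nrow(), J = C.ncol();
  const double dtoh2 = dt / (h * h);
  bool clamped = clamped_in;
  std::vector<double> G(n);
  double t = t0;

  for (int step = 0; step < nsteps; ++step) {
    // --- diffusion (zero-flux walls) ---
    for (int j = 0; j < J; ++j) {
      double *c = &C(0, j);
      const double Dj = D[j];
      for (int i = 0; i < n - 1; ++i) {
        double Db = Dj;
        if (conc_k > 0) Db = Dj / (1.0 + conc_k * c[i + 1]);
        G[i] = ((c[i] - c[i + 1]) * Db) * dtoh2;
      }
      double prev = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = (i < n - 1) ? G[i] : 0.0;
        c[i] = c[i] + prev - gi;
        prev = gi;
      }
    }
    // --- sedimentation (upwind transfer; terminal row keeps its mass) ---
    for (int j = 0; j < J; ++j) {
      double *c = &C(0, j);
      const double base = S[j] * (grav * dt / h);
      if (base == 0.0) continue;
      if (base > 0.0) {            // settling: downward, bottom accumulates
        double carry = 0.0;        // outflow of the compartment above
        for (int i = 0; i < n; ++i) {
          double frac = base;
          if (conc_k > 0) frac = (S[j] / (1.0 + conc_k * c[i])) * (grav * dt / h);
          double out = (i < n - 1) ? c[i] * frac : 0.0;
          c[i] = c[i] - out + carry;
          carry = out;
        }
      } else {                     // buoyant: upward, top accumulates
        double carry = 0.0;        // outflow of the compartment below
        for (int i = n - 1; i >= 0; --i) {
          double frac = -base;
          if (conc_k > 0) frac = (-S[j] / (1.0 + conc_k * c[i])) * (grav * dt / h);
          double out = (i > 0) ? c[i] * frac : 0.0;
          c[i] = c[i] - out + carry;
          carry = out;
        }
      }
    }
    // --- Langmuir equilibrium partition of the bottom compartment ---
    if (langmuir) {
      for (int j = 0; j < J; ++j) {
        double Cp = C(n - 1, j) + bound[j] / h;   // total bottom content
        if (Cp <= 0.0) continue;
        double r = d_cur[j] / 2.0;
        double P = 1e-3 * Cp /
          (NAvog * rho_EV[j] * (4.0 / 3.0) * M_PI * std::pow(r, 3.0));
        double theta = P / (KD + P);
        double A_m = 3.0 / (4.0 * r * rho_EV[j]);
        double theta_avail = h * Cp * A_m;
        double F_b = theta / theta_avail;
        if (F_b > 1.0) F_b = 1.0;
        bound[j] = F_b * Cp * h;
        C(n - 1, j) = (1.0 - F_b) * Cp;
      }
    }
    // --- dissolution increment ---
    if (diss_mode >= 2) {
      double f_old = fd_at(diss_mode, f0, rate_h, ramp_end_h, fmax, t);
      double f_new = fd_at(diss_mode, f0, rate_h, ramp_end_h, fmax, t + dt);
      double dM = (f_new - f_old) * C0 * H;
      if (dM > 0.0) {
        double total = 0.0;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < n; ++i) total += C(i, j);
        total *= h;
        if (dM >= total) {
          clamped = true;
          dM = total;
          std::fill(C.begin(), C.end(), 0.0);
        } else {
          double fac = 1.0 - dM / total;
          for (int j = 0; j < J; ++j)
            for (int i = 0; i < n; ++i) C(i, j) *= fac;
        }
        dissolved_areal += dM;
        double f_cum = dissolved_areal / (C0 * H);
        double fac_d = std::pow((1.0 - f_cum) / (1.0 - f0), 1.0 / 3.0);
        for (int j = 0; j < J; ++j) d_cur[j] = d0[j] * fac_d;
      }
    }
    t += dt;
  }

  return List::create(_["C"] = C, _["bound"] = bound,
                      _["dissolved_areal"] = dissolved_areal,
                      _["d_current"] = d_cur, _["clamped"] = clamped);
}
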