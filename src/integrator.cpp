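// TVD-RK2 (Heun) integrator for the cell-based WUS-CLV3-CK tissue model.
// This is a line-for-line transcription of the R reference rhs(); a unit
// test pins one C++ step against the R two-stage step.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// x^n with fast paths for the small integer exponents the model uses
static inline double hpow(double x, double n) {
  if (n == 1.0) return x;
  if (n == 2.0) return x * x;
  if (n == 3.0) return x * x * x;
  if (n == 4.0) { double s = x * x; return s * s; }
  return std::pow(x, n);
}
static inline double hill_down(double x, double k, double n) {
  return 1.0 / (1.0 + hpow(x / k, n));
}
static inline double hill_up(double x, double k, double n) {
  double u = hpow(x / k, n);
  return u / (1.0 + u);
}

struct Pars {
  double A1, d_W, r_c, D_w, d_wc, d_wn, d_min, d_max, k_ww, n3, r_ex, r_im;
  double k_cw1, n1, k_cw2, n2, k_cw3, n6;
  double C_p, k_wc1, n4, k_wc2, n5, D_c, d_c;
  double ck_prod_L, ck_D_L, ck_d_L, ck_prod_R, ck_d_R;
  double ck_k_on, ck_k_off, ck_d_X, ck_s_wc, ck_k_wc, ck_s_ex, ck_k_ex, ck_n;
  bool clv3_on, ck_on, self_stab, trans_only;
  double pot, dose;
};

typedef std::vector<double> vec;

struct State {
  vec W, Wc, Wn, Co, Ci, L, R, X;
  State(int n) : W(n), Wc(n), Wn(n), Co(n), Ci(n), L(n), R(n), X(n) {}
};

// derivative of `s` into `d`; ceff is scratch of length n
static void deriv(const State& s, State& d, vec& ceff,
                  const Pars& p, int n,
                  const std::vector<int>& rp, const std::vector<int>& ci,
                  const vec& g, const vec& syn, const vec& outer,
                  const vec& deep) {
  const bool has_clv3 = p.clv3_on || p.dose > 0.0;
  for (int i = 0; i < n; ++i)
    ceff[i] = has_clv3 ? s.Co[i] + p.pot * s.Ci[i] + p.dose : 0.0;

  for (int i = 0; i < n; ++i) {
    double C = ceff[i];
    double h_tx = has_clv3 ? hill_down(C, p.k_cw1, p.n1) : 1.0;
    double h_ex = (has_clv3 && !p.trans_only) ? hill_down(C, p.k_cw2, p.n2)
                                              : 1.0;
    double stab = 0.0, ret = 0.0;
    if (p.ck_on) {
      stab = p.ck_s_wc * hill_up(s.X[i], p.ck_k_wc, p.ck_n);
      ret  = p.ck_s_ex * hill_up(s.X[i], p.ck_k_ex, p.ck_n);
    }

    // graph diffusion of cytoplasmic WUS (coefficient CLV3-regulated
    // unless transcriptional-only) and, when active, of CLV3 and ligand
    double dif_wc = 0.0, dif_co = 0.0, dif_ci = 0.0, dif_l = 0.0;
    for (int e = rp[i]; e < rp[i + 1]; ++e) {
      int j = ci[e];
      double Dw = p.D_w;
      if (has_clv3 && !p.trans_only)
        Dw *= hill_down(0.5 * (C + ceff[j]), p.k_cw3, p.n6);
      dif_wc += Dw * g[e] * (s.Wc[j] - s.Wc[i]);
      if (p.clv3_on) {
        dif_co += g[e] * (s.Co[j] - s.Co[i]);
        dif_ci += g[e] * (s.Ci[j] - s.Ci[i]);
      }
      if (p.ck_on) dif_l += g[e] * (s.L[j] - s.L[i]);
    }

    d.W[i] = syn[i] * h_tx - p.d_W * s.W[i];

    double export_i = p.r_ex * h_ex * (1.0 - ret) * s.Wn[i];
    d.Wc[i] = dif_wc + p.r_c * s.W[i] - p.d_wc * (1.0 - stab) * s.Wc[i] +
              export_i - p.r_im * s.Wc[i];

    double dn = p.d_wn;
    if (p.self_stab)
      dn *= p.d_min + (p.d_max - p.d_min) * hill_down(s.Wn[i], p.k_ww, p.n3);
    d.Wn[i] = -dn * s.Wn[i] - export_i + p.r_im * s.Wc[i];

    if (p.clv3_on) {
      double u = hpow(s.Wn[i] / p.k_wc2, p.n5);
      double v = hpow(s.Wn[i] / p.k_wc1, p.n4);
      double prod = p.C_p * (u / (1.0 + u)) / (1.0 + v);
      d.Co[i] = prod * outer[i] + p.D_c * dif_co - p.d_c * s.Co[i];
      d.Ci[i] = prod * (1.0 - outer[i]) + p.D_c * dif_ci - p.d_c * s.Ci[i];
    } else { d.Co[i] = 0.0; d.Ci[i] = 0.0; }

    if (p.ck_on) {
      double bind = p.ck_k_on * s.L[i] * s.R[i];
      d.L[i] = p.ck_prod_L * deep[i] + p.ck_D_L * dif_l - p.ck_d_L * s.L[i] -
               bind + p.ck_k_off * s.X[i];
      d.R[i] = p.ck_prod_R * deep[i] - p.ck_d_R * s.R[i] - bind +
               p.ck_k_off * s.X[i];
      d.X[i] = bind - p.ck_k_off * s.X[i] - p.ck_d_X * s.X[i];
    } else { d.L[i] = 0.0; d.R[i] = 0.0; d.X[i] = 0.0; }
  }
}

static double getd(const List& par, const char* nm) {
  return as<double>(par[nm]);
}

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix state0, IntegerVector row_ptr,
                   IntegerVector col_ind, NumericVector cond,
                   NumericVector syn, NumericVector outer_gate,
                   NumericVector deep_gate, List par, List flags,
                   double dt, int nsteps, bool clip = true,
                   int trace_every = 0) {
  const int n = state0.nrow();
  if (state0.ncol() != 8) stop("state must have 8 columns");
  std::vector<int> rp(row_ptr.begin(), row_ptr.end());
  std::vector<int> ci(col_ind.begin(), col_ind.end());
  vec g(cond.begin(), cond.end());
  vec vsyn(syn.begin(), syn.end());
  vec vout(outer_gate.begin(), outer_gate.end());
  vec vdeep(deep_gate.begin(), deep_gate.end());

  Pars p;
  p.A1 = getd(par, "A1"); p.d_W = getd(par, "d_W"); p.r_c = getd(par, "r_c");
  p.D_w = getd(par, "D_w"); p.d_wc = getd(par, "d_wc");
  p.d_wn = getd(par, "d_wn"); p.d_min = getd(par, "d_min");
  p.d_max = getd(par, "d_max"); p.k_ww = getd(par, "k_ww");
  p.n3 = getd(par, "n3"); p.r_ex = getd(par, "r_ex");
  p.r_im = getd(par, "r_im");
  p.k_cw1 = getd(par, "k_cw1"); p.n1 = getd(par, "n1");
  p.k_cw2 = getd(par, "k_cw2"); p.n2 = getd(par, "n2");
  p.k_cw3 = getd(par, "k_cw3"); p.n6 = getd(par, "n6");
  p.C_p = getd(par, "C_p"); p.k_wc1 = getd(par, "k_wc1");
  p.n4 = getd(par, "n4"); p.k_wc2 = getd(par, "k_wc2");
  p.n5 = getd(par, "n5"); p.D_c = getd(par, "D_c"); p.d_c = getd(par, "d_c");
  p.ck_prod_L = getd(par, "ck_prod_L"); p.ck_D_L = getd(par, "ck_D_L");
  p.ck_d_L = getd(par, "ck_d_L"); p.ck_prod_R = getd(par, "ck_prod_R");
  p.ck_d_R = getd(par, "ck_d_R"); p.ck_k_on = getd(par, "ck_k_on");
  p.ck_k_off = getd(par, "ck_k_off"); p.ck_d_X = getd(par, "ck_d_X");
  p.ck_s_wc = getd(par, "ck_s_wc"); p.ck_k_wc = getd(par, "ck_k_wc");
  p.ck_s_ex = getd(par, "ck_s_ex"); p.ck_k_ex = getd(par, "ck_k_ex");
  p.ck_n = getd(par, "ck_n");
  p.clv3_on = as<bool>(flags["clv3_on"]);
  p.ck_on = as<bool>(flags["ck_on"]);
  p.self_stab = as<bool>(flags["self_stab"]);
  p.trans_only = as<bool>(flags["trans_only"]);
  p.pot = as<double>(flags["pot"]);
  p.dose = as<double>(flags["dose"]);

  State s(n), s1(n), d(n);
  vec ceff(n);
  for (int i = 0; i < n; ++i) {
    s.W[i] = state0(i, 0); s.Wc[i] = state0(i, 1); s.Wn[i] = state0(i, 2);
    s.Co[i] = state0(i, 3); s.Ci[i] = state0(i, 4); s.L[i] = state0(i, 5);
    s.R[i] = state0(i, 6); s.X[i] = state0(i, 7);
  }

  int nclip = 0;
  int nframes = trace_every > 0 ? nsteps / trace_every + 1 : 0;
  NumericMatrix trace(nframes > 0 ? nframes : 1, 9);
  int frame = 0;
  vec* cols_s[8] = { &s.W, &s.Wc, &s.Wn, &s.Co, &s.Ci, &s.L, &s.R, &s.X };
  vec* cols_1[8] = { &s1.W, &s1.Wc, &s1.Wn, &s1.Co, &s1.Ci,
                     &s1.L, &s1.R, &s1.X };
  vec* cols_d[8] = { &d.W, &d.Wc, &d.Wn, &d.Co, &d.Ci, &d.L, &d.R, &d.X };

  auto record = [&](int step) {
    trace(frame, 0) = step * dt;
    for (int c = 0; c < 8; ++c) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += (*cols_s[c])[i];
      trace(frame, c + 1) = m / n;
    }
    ++frame;
  };

  for (int step = 0; step < nsteps; ++step) {
    if (trace_every > 0 && step % trace_every == 0 && frame < nframes)
      record(step);
    // stage 1: u1 = u + dt f(u)
    deriv(s, d, ceff, p, n, rp, ci, g, vsyn, vout, vdeep);
    for (int c = 0; c < 8; ++c) {
      const vec& u = *cols_s[c]; const vec& du = *cols_d[c];
      vec& u1 = *cols_1[c];
      for (int i = 0; i < n; ++i) u1[i] = u[i] + dt * du[i];
    }
    // stage 2: u <- (u + u1 + dt f(u1)) / 2
    deriv(s1, d, ceff, p, n, rp, ci, g, vsyn, vout, vdeep);
    for (int c = 0; c < 8; ++c) {
      vec& u = *cols_s[c]; const vec& u1 = *cols_1[c];
      const vec& du = *cols_d[c];
      for (int i = 0; i < n; ++i) {
        double v = 0.5 * (u[i] + u1[i] + dt * du[i]);
        if (clip && v < 0.0) { v = 0.0; ++nclip; }
        u[i] = v;
      }
    }
    if ((step & 1023) == 0) {
      for (int c = 0; c < 8; ++c)
        if (!std::isfinite((*cols_s[c])[0]))
          stop("integration blew up (non-finite state) at t = %f", step * dt);
    }
  }
  // full NaN sweep at the end
  for (int c = 0; c < 8; ++c)
    for (int i = 0; i < n; ++i)
      if (!std::isfinite((*cols_s[c])[i]))
        stop("integration blew up (non-finite state)");
  if (trace_every > 0 && frame < nframes) record(nsteps);

  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = s.W[i]; out(i, 1) = s.Wc[i]; out(i, 2) = s.Wn[i];
    out(i, 3) = s.Co[i]; out(i, 4) = s.Ci[i]; out(i, 5) = s.L[i];
    out(i, 6) = s.R[i]; out(i, 7) = s.X[i];
  }
  List res = List::create(_["state"] = out, _["nclip"] = nclip);
  if (nframes > 0) res["trace"] = trace;
  return res;
}
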