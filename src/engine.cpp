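// Compiled integration core: fixed-step operator split with forward Euler
// for membrane potential, HH gates and ion concentrations, and backward
// Euler (dense direct solve) for the Markov occupancy vectors. Mirrors the
// R reference stepper in R/engine.R exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Edges {
  arma::uvec from, to;
  arma::vec a, b;
  arma::uvec cad;
  int n;
};

static Edges parse_edges(const NumericMatrix& m) {
  Edges e;
  int k = m.nrow();
  e.n = k;
  e.from.set_size(k); e.to.set_size(k);
  e.a.set_size(k); e.b.set_size(k); e.cad.set_size(k);
  for (int i = 0; i < k; ++i) {
    e.from(i) = (arma::uword)m(i, 0) - 1;
    e.to(i)   = (arma::uword)m(i, 1) - 1;
    e.a(i) = m(i, 2);
    e.b(i) = m(i, 3);
    e.cad(i) = (arma::uword)m(i, 4);
  }
  return e;
}

static void build_Q(arma::mat& Q, const Edges& e, double V, double ca) {
  Q.zeros();
  for (int i = 0; i < e.n; ++i) {
    double r = e.a(i) * std::exp(e.b(i) * V);
    if (e.cad(i) == 1) r *= ca;
    Q(e.to(i), e.from(i)) += r;
    Q(e.from(i), e.from(i)) -= r;
  }
}

// backward-Euler step; returns |1 - sum| before renormalisation
static double be_step(arma::vec& p, const arma::mat& Q, double dt,
                      arma::mat& A, double& pmin) {
  A = -dt * Q;
  A.diag() += 1.0;
  p = arma::solve(A, p);
  double s = arma::accu(p);
  double err = std::fabs(1.0 - s);
  double mn = p.min();
  if (mn < pmin) pmin = mn;
  for (arma::uword i = 0; i < p.n_elem; ++i) if (p(i) < 0) p(i) = 0;
  p /= arma::accu(p);
  return err;
}

static double gate_inf(const double* g, double V) {
  // g: v_half, slope, sign, tau_min, tau_amp, tau_v, tau_w
  return 1.0 / (1.0 + std::exp(g[2] * (V - g[0]) / g[1]));
}

static double gate_tau(const double* g, double V) {
  double z = (V - g[5]) / g[6];
  return g[3] + g[4] * std::exp(-z * z);
}

static double free_ca_solve(double tot, double B1, double K1, double B2,
                            double K2, double x0) {
  if (tot <= 0) return 0.0;
  double x = (x0 > 0 && x0 < tot) ? x0 : tot * 0.5;
  for (int it = 0; it < 50; ++it) {
    double d1 = K1 + x, d2 = K2 + x;
    double f = x + B1 * x / d1 + B2 * x / d2 - tot;
    double fp = 1.0 + B1 * K1 / (d1 * d1) + B2 * K2 / (d2 * d2);
    double step = f / fp;
    double xn = x - step;
    if (xn <= 0) xn = x * 0.5;
    if (xn > tot) xn = 0.5 * (x + tot);
    if (std::fabs(xn - x) < 1e-18 + 1e-12 * xn) { x = xn; break; }
    x = xn;
  }
  return x;
}

static double icc_v(double t, const double* s) {
  // s: Vrest, Vamp, t_up, t_plat, s_up, pfrac, tau_plat, w_fall, Gc,
  // t_start, t_fall
  if (t < s[9]) return s[0];
  double period = s[2] + s[3];
  double u = t - s[9];
  double tp = u - period * std::floor(u / period);
  double w;
  if (tp < s[2]) {
    w = (1.0 - std::exp(-s[4] * tp / s[2])) / (1.0 - std::exp(-s[4]));
  } else {
    double u = tp - s[2];
    double sust = s[5] + (1.0 - s[5]) * std::exp(-u / s[6]);
    double s_off = std::min(s[10], s[3] - 2.0 * s[7]);
    w = sust / (1.0 + std::exp((u - s_off) / s[7]));
  }
  return s[0] + s[1] * w;
}

// [[Rcpp::export]]
List simulate_cpp(List par, NumericVector state0, int n_steps, double dt,
                  int stride, Nullable<List> clamp_, bool freeze_conc) {
  const double Cm = as<double>(par["Cm"]);
  const double F = as<double>(par["F"]);
  const double RTF = as<double>(par["RTF"]);
  const double Vc = as<double>(par["Vc"]);
  NumericVector G = par["G"];       // CaL CaT Kv BK Na NaLeak KLeak
  NumericVector nak = par["nak"];   // P_NaK K_mK K_mNa
  NumericVector ncx = par["ncx"];   // k gamma K_mNai K_mCa k_sat alpha
  NumericVector ext = par["ext"];   // Na_o K_o Ca_o
  NumericVector buf = par["buf"];   // B_CaM K_CaM B_CRT K_CRT
  NumericMatrix gates = par["gates"]; // rows: m_CaT h_CaT x_Kv y_Kv
  double gm[4][7];                    // contiguous row copies
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 7; ++j) gm[i][j] = gates(i, j);
  Edges e_cal = parse_edges(par["edges_cal"]);
  Edges e_bk = parse_edges(par["edges_bk"]);
  Edges e_na = parse_edges(par["edges_na"]);
  IntegerVector open_cal = par["open_cal"], open_bk = par["open_bk"],
    open_na = par["open_na"];
  NumericVector stim = par["stim"];
  const bool stim_on = stim[11] > 0.5;
  const bool ca_free_mode = as<bool>(par["ca_free"]);

  bool clamped = clamp_.isNotNull();
  std::vector<double> clamp_t, clamp_v;
  if (clamped) {
    List cl(clamp_);
    NumericVector ct = cl["t"], cv = cl["v"];
    clamp_t.assign(ct.begin(), ct.end());
    clamp_v.assign(cv.begin(), cv.end());
  }

  // state layout
  double V = state0[0];
  double m = state0[1], h = state0[2], x = state0[3], y = state0[4];
  arma::vec pcal(12), pbk(10), pna(6);
  for (int i = 0; i < 12; ++i) pcal(i) = state0[5 + i];
  for (int i = 0; i < 10; ++i) pbk(i) = state0[17 + i];
  for (int i = 0; i < 6; ++i) pna(i) = state0[27 + i];
  double Nai = state0[33], Ki = state0[34], Cat = state0[35];

  arma::mat Qcal(12, 12), Qbk(10, 10), Qna(6, 6);
  arma::mat Acal(12, 12), Abk(10, 10), Ana(6, 6);

  const int ncol = 19;
  int nrec = n_steps / stride + 1;
  NumericMatrix out(nrec, ncol);
  double psum_err = 0.0, p_min = 0.0;
  double denom = F * Vc / 1e-15;   // pA ms per mM
  double ca_free = ca_free_mode ? 1e-13 :
    free_ca_solve(Cat, buf[0], buf[1], buf[2], buf[3], -1);
  int rec = 0;
  size_t ci = 0;

  for (int k = 0; k <= n_steps; ++k) {
    double t = k * dt;
    if (clamped) {
      while (ci + 1 < clamp_t.size() && t >= clamp_t[ci + 1]) ++ci;
      V = clamp_v[ci];
    }
    ca_free = ca_free_mode ? 1e-13 :
      free_ca_solve(Cat, buf[0], buf[1], buf[2], buf[3], ca_free);

    // reversal potentials from tracked concentrations
    double E_Na = RTF * std::log(ext[0] / Nai);
    double E_K = RTF * std::log(ext[1] / Ki);
    double E_Ca = 0.5 * RTF * std::log(ext[2] / ca_free);

    double po_cal = 0, po_bk = 0, po_na = 0;
    for (int i = 0; i < open_cal.size(); ++i) po_cal += pcal(open_cal[i] - 1);
    for (int i = 0; i < open_bk.size(); ++i) po_bk += pbk(open_bk[i] - 1);
    for (int i = 0; i < open_na.size(); ++i) po_na += pna(open_na[i] - 1);

    double I_CaL = G[0] * po_cal * (V - E_Ca);
    double I_CaT = G[1] * m * h * (V - E_Ca);
    double I_Kv = G[2] * x * y * (V - E_K);
    double I_BK = G[3] * po_bk * (V - E_K);
    double I_Na = G[4] * po_na * (V - E_Na);
    double vf = V / RTF;
    double I_NaK = nak[0] * (ext[1] / (ext[1] + nak[1])) *
      (Nai / (Nai + nak[2])) /
      (1.0 + 0.1245 * std::exp(-0.1 * vf) + 0.0353 * std::exp(-vf));
    double num = std::exp(ncx[1] * vf) * Nai * Nai * Nai * ext[2] -
      std::exp((ncx[1] - 1.0) * vf) * ext[0] * ext[0] * ext[0] * ca_free * ncx[5];
    double den = (ncx[2] * ncx[2] * ncx[2] + ext[0] * ext[0] * ext[0]) *
      (ncx[3] + ext[2]) * (1.0 + ncx[4] * std::exp((ncx[1] - 1.0) * vf));
    double I_NCX = ncx[0] * num / den;
    double I_NaLeak = G[5] * V;
    double I_KLeak = G[6] * V;
    double I_total = I_CaL + I_CaT + I_Kv + I_BK + I_Na + I_NaK + I_NCX +
      I_NaLeak + I_KLeak;
    double I_stim = 0.0;
    if (!clamped && stim_on) {
      I_stim = stim[8] * (icc_v(t, stim.begin()) - V);
    }

    if (k % stride == 0) {
      out(rec, 0) = t; out(rec, 1) = V;
      out(rec, 2) = I_CaL; out(rec, 3) = I_CaT; out(rec, 4) = I_Kv;
      out(rec, 5) = I_BK; out(rec, 6) = I_Na; out(rec, 7) = I_NaK;
      out(rec, 8) = I_NCX; out(rec, 9) = I_NaLeak; out(rec, 10) = I_KLeak;
      out(rec, 11) = I_stim; out(rec, 12) = po_cal; out(rec, 13) = po_bk;
      out(rec, 14) = po_na; out(rec, 15) = Nai; out(rec, 16) = Ki;
      out(rec, 17) = Cat; out(rec, 18) = ca_free;
      ++rec;
      if (!std::isfinite(V) || !std::isfinite(Cat) || !std::isfinite(Nai)) {
        stop("non-finite state at t = %f ms", t);
      }
    }
    if (k == n_steps) break;

    // implicit Markov updates at beginning-of-step (V, Ca)
    build_Q(Qcal, e_cal, V, ca_free);
    build_Q(Qbk, e_bk, V, ca_free);
    build_Q(Qna, e_na, V, ca_free);
    double err = be_step(pcal, Qcal, dt, Acal, p_min);
    if (err > psum_err) psum_err = err;
    err = be_step(pbk, Qbk, dt, Abk, p_min);
    if (err > psum_err) psum_err = err;
    err = be_step(pna, Qna, dt, Ana, p_min);
    if (err > psum_err) psum_err = err;

    // explicit gate updates
    m += dt * (gate_inf(gm[0], V) - m) / gate_tau(gm[0], V);
    h += dt * (gate_inf(gm[1], V) - h) / gate_tau(gm[1], V);
    x += dt * (gate_inf(gm[2], V) - x) / gate_tau(gm[2], V);
    y += dt * (gate_inf(gm[3], V) - y) / gate_tau(gm[3], V);

    // explicit potential and concentration updates
    if (!clamped) V -= dt * (I_total - I_stim) / Cm;
    if (!freeze_conc) {
      if (!ca_free_mode) {
        double dCa = -(I_CaL + I_CaT - 2.0 * I_NCX) / (2.0 * denom);
        Cat += dt * dCa;
        if (Cat < 1e-12) Cat = 1e-12;
      }
      Nai += dt * (-(I_Na + I_NaLeak + 3.0 * I_NaK + 3.0 * I_NCX) / denom);
      Ki += dt * (-(I_Kv + I_BK + I_KLeak - 2.0 * I_NaK) / denom);
    }
  }

  NumericVector fin(36);
  fin[0] = V; fin[1] = m; fin[2] = h; fin[3] = x; fin[4] = y;
  for (int i = 0; i < 12; ++i) fin[5 + i] = pcal(i);
  for (int i = 0; i < 10; ++i) fin[17 + i] = pbk(i);
  for (int i = 0; i < 6; ++i) fin[27 + i] = pna(i);
  fin[33] = Nai; fin[34] = Ki; fin[35] = Cat;

  return List::create(_["trace"] = out, _["psum_err"] = psum_err,
                      _["p_min"] = p_min, _["final_state"] = fin);
}
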