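// Hartigan dip statistic of unimodality.
//
// dip(F_n) = min over unimodal CDFs G (convex up to a mode, concave after,
// atom allowed at the mode) of sup |F_n - G|.  Feasibility of a half-band h
// (in observation counts) is decided exactly by a forward sweep over the
// distinct sorted values: the sweep carries, as a piecewise-linear convex
// function sigma(v), the minimal slope with which a convex nondecreasing G
// within the band can arrive at value v at the current point.  A mirrored
// sweep handles the concave side; a mode placed in a gap needs the two
// sides to overlap in value, a mode placed at an atom relaxes that atom's
// gates (the jump absorbs its mass).  The dip is found by bisection on h.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct State {
  // breakpoints of sigma: values bw (increasing), slopes-at-value bs
  std::vector<double> bw, bs;
  bool empty = true;
};

// clip state to value-domain [L, R]; `ray` is sigma's right-extension slope
void clip_state(State &st, double L, double R, double ray) {
  if (st.empty) return;
  std::vector<double> &bw = st.bw, &bs = st.bs;
  if (L > R + 1e-12 || R < bw.front() - 1e-12) { st.empty = true; return; }
  double wmax = bw.back();
  if (R >= wmax) {
    if (R > wmax) { bw.push_back(R); bs.push_back(bs.back() + (R - wmax) * ray); }
  } else {
    // interpolate sigma at R, drop later breakpoints
    size_t k = 0;
    while (k + 1 < bw.size() && bw[k + 1] < R) ++k;
    double dw = bw[k + 1] - bw[k];
    double sR = dw <= 0 ? bs[k + 1] : bs[k] + (bs[k + 1] - bs[k]) * (R - bw[k]) / dw;
    bw.resize(k + 1); bs.resize(k + 1);
    if (R > bw.back() + 1e-12) { bw.push_back(R); bs.push_back(sR); }
  }
  if (L > bw.front()) {
    if (L > bw.back()) { st.empty = true; return; }
    size_t k = 0;
    while (k + 1 < bw.size() && bw[k + 1] <= L) ++k;
    if (k + 1 >= bw.size()) { st.empty = true; return; }
    double dw = bw[k + 1] - bw[k];
    double sL = dw <= 0 ? bs[k + 1] : bs[k] + (bs[k + 1] - bs[k]) * (L - bw[k]) / dw;
    bw.erase(bw.begin(), bw.begin() + k + 1);
    bs.erase(bs.begin(), bs.begin() + k + 1);
    if (bw.empty() || bw.front() > L + 1e-12) {
      bw.insert(bw.begin(), L); bs.insert(bs.begin(), sL);
    }
  }
}

struct SweepOut {
  std::vector<char> feas, feas_rel;
  std::vector<double> M, M_rel;
};

// relax_upper: atom-mode relaxes the upper gate to chi + h (forward pass);
// otherwise it relaxes the lower gate to clo - h (mirrored pass).
SweepOut sweep_convex(const std::vector<double> &u,
                      const std::vector<double> &chi,
                      const std::vector<double> &clo,
                      double h, bool relax_upper) {
  size_t m = u.size();
  SweepOut out;
  out.feas.assign(m, 0); out.feas_rel.assign(m, 0);
  out.M.assign(m, NA_REAL); out.M_rel.assign(m, NA_REAL);

  State st;
  double A0 = chi[0] - h, B0 = clo[0] + h;
  double Ar0 = relax_upper ? A0 : clo[0] - h;
  double Br0 = relax_upper ? chi[0] + h : B0;
  {
    State rel;
    rel.bw = {0.0, std::max(0.0, Br0) + 1.0}; rel.bs = {0.0, 0.0}; rel.empty = false;
    clip_state(rel, std::max(0.0, Ar0), Br0, 0.0);
    out.feas_rel[0] = !rel.empty;
    if (!rel.empty) out.M_rel[0] = rel.bw.front();
  }
  st.bw = {0.0, std::max(0.0, B0) + 1.0}; st.bs = {0.0, 0.0}; st.empty = false;
  clip_state(st, std::max(0.0, A0), B0, 0.0);
  out.feas[0] = !st.empty;
  if (!st.empty) out.M[0] = st.bw.front();

  for (size_t i = 1; i < m; ++i) {
    if (st.empty) break;
    double d = u[i] - u[i - 1];
    for (size_t k = 0; k < st.bw.size(); ++k) st.bw[k] += d * st.bs[k];
    double ray = 1.0 / d;
    double A = chi[i] - h, B = clo[i] + h;
    double Ar = relax_upper ? A : clo[i] - h;
    double Br = relax_upper ? chi[i] + h : B;
    State rel = st;
    clip_state(rel, Ar, Br, ray);
    out.feas_rel[i] = !rel.empty;
    if (!rel.empty) out.M_rel[i] = rel.bw.front();
    clip_state(st, A, B, ray);
    out.feas[i] = !st.empty;
    if (!st.empty) out.M[i] = st.bw.front();
  }
  return out;
}

bool dip_feasible(const std::vector<double> &u, const std::vector<double> &lens,
                  double h) {
  size_t m = u.size();
  double n = 0; for (double l : lens) n += l;
  std::vector<double> chi(m), clo(m);
  double c = 0;
  for (size_t i = 0; i < m; ++i) { clo[i] = c; c += lens[i]; chi[i] = c; }
  SweepOut fw = sweep_convex(u, chi, clo, h, true);
  // mirrored pass: values v -> n - v, positions reflected
  std::vector<double> u2(m), chi2(m), clo2(m), lens2(m);
  for (size_t i = 0; i < m; ++i) { u2[i] = -u[m - 1 - i]; lens2[i] = lens[m - 1 - i]; }
  c = 0;
  for (size_t i = 0; i < m; ++i) { clo2[i] = c; c += lens2[i]; chi2[i] = c; }
  SweepOut bw = sweep_convex(u2, chi2, clo2, h, false);

  double tol = 1e-9 * std::max(1.0, n);
  // mode in the gap (u_j, u_{j+1}), j = 0..m
  for (size_t j = 0; j <= m; ++j) {
    bool lok = (j == 0) || fw.feas[j - 1];
    bool rok = (j == m) || bw.feas[m - 1 - j];
    if (!lok || !rok) continue;
    double Mj = (j == 0) ? 0.0 : fw.M[j - 1];
    double Rj = (j == m) ? n : n - bw.M[m - 1 - j];
    if (Mj <= Rj + tol) return true;
  }
  // mode at the atom u_k
  for (size_t k = 0; k < m; ++k) {
    if (!fw.feas_rel[k] || !bw.feas_rel[m - 1 - k]) continue;
    double Rk = n - bw.M_rel[m - 1 - k];
    if (fw.M_rel[k] <= Rk + tol) return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  size_t n = xs.size();
  if (n < 4) stop("the dip statistic needs at least 4 observations");
  std::vector<double> u, lens;
  for (size_t i = 0; i < n; ++i) {
    if (u.empty() || xs[i] != u.back()) { u.push_back(xs[i]); lens.push_back(1); }
    else lens.back() += 1;
  }
  if (u.size() == 1) return 0.0;
  double lo = 0.0, hi = n / 4.0 + 1.0;
  for (int it = 0; it < 60 && hi - lo > 1e-10; ++it) {
    double mid = (lo + hi) / 2;
    if (dip_feasible(u, lens, mid)) hi = mid; else lo = mid;
  }
  return ((lo + hi) / 2) / n;
}
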