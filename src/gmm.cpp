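#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

// Minimal deterministic RNG (xorshift64*) so pairwise fits are reproducible
// across platforms and independent of R's RNG state.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Comp {
  double w, mx, my, a, b, c; // weight, mean, covariance (xx, xy, yy)
};

// k-means++ seeding followed by Lloyd iterations; returns assignments.
static std::vector<int> kmeans_fit(const std::vector<double> &x,
                                   const std::vector<double> &y, int k,
                                   XRng &rng) {
  int n = (int)x.size();
  std::vector<double> cx(k), cy(k), d2(n,
      std::numeric_limits<double>::infinity());
  int first = (int)(rng.unif() * n);
  if (first >= n) first = n - 1;
  cx[0] = x[first]; cy[0] = y[first];
  for (int j = 1; j < k; ++j) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - cx[j - 1], dy = y[i] - cy[j - 1];
      double d = dx * dx + dy * dy;
      if (d < d2[i]) d2[i] = d;
      tot += d2[i];
    }
    int pick = 0;
    if (tot > 0) {
      double r = rng.unif() * tot, acc = 0.0;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (acc >= r) { pick = i; break; }
      }
    } else {
      pick = (int)(rng.unif() * n);
      if (pick >= n) pick = n - 1;
    }
    cx[j] = x[pick]; cy[j] = y[pick];
  }
  std::vector<int> lab(n, 0);
  for (int iter = 0; iter < 60; ++iter) {
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double dx = x[i] - cx[j], dy = y[i] - cy[j];
        double d = dx * dx + dy * dy;
        if (d < best) { best = d; bj = j; }
      }
      if (bj != lab[i]) { lab[i] = bj; changed = true; }
    }
    std::vector<double> sx(k, 0.0), sy(k, 0.0);
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; ++i) { sx[lab[i]] += x[i]; sy[lab[i]] += y[i]; ++cnt[lab[i]]; }
    for (int j = 0; j < k; ++j) {
      if (cnt[j] > 0) { cx[j] = sx[j] / cnt[j]; cy[j] = sy[j] / cnt[j]; }
      else {
        // re-seed an empty cluster at the point farthest from its center
        double worst = -1.0; int wi = 0;
        for (int i = 0; i < n; ++i) {
          double dx = x[i] - cx[lab[i]], dy = y[i] - cy[lab[i]];
          double d = dx * dx + dy * dy;
          if (d > worst) { worst = d; wi = i; }
        }
        cx[j] = x[wi]; cy[j] = y[wi];
        changed = true;
      }
    }
    if (!changed && iter > 0) break;
  }
  return lab;
}

struct EmFit {
  double loglik;
  bool ok;
  std::vector<Comp> comps;
  std::vector<std::vector<double> > resp;
};

static EmFit em_fit(const std::vector<double> &x, const std::vector<double> &y,
                    int k, XRng &rng, double tol, int max_iter) {
  int n = (int)x.size();
  EmFit fit; fit.ok = false; fit.loglik = R_NegInf;
  double vx = 0, vy = 0, mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  for (int i = 0; i < n; ++i) { vx += (x[i]-mx)*(x[i]-mx); vy += (y[i]-my)*(y[i]-my); }
  vx /= n; vy /= n;
  double reg = 1e-6 * (vx + vy) / 2.0 + 1e-10;

  std::vector<int> lab = kmeans_fit(x, y, k, rng);
  std::vector<Comp> comps(k);
  for (int j = 0; j < k; ++j) {
    double sw = 0, smx = 0, smy = 0;
    for (int i = 0; i < n; ++i) if (lab[i] == j) { sw += 1; smx += x[i]; smy += y[i]; }
    if (sw < 1) sw = 1;
    comps[j].w = sw / n; comps[j].mx = smx / sw; comps[j].my = smy / sw;
    double sa = 0, sb = 0, sc = 0;
    for (int i = 0; i < n; ++i) if (lab[i] == j) {
      double dx = x[i] - comps[j].mx, dy = y[i] - comps[j].my;
      sa += dx * dx; sb += dx * dy; sc += dy * dy;
    }
    comps[j].a = sa / sw + reg; comps[j].b = sb / sw; comps[j].c = sc / sw + reg;
  }

  std::vector<std::vector<double> > resp(k, std::vector<double>(n));
  std::vector<double> lp(k);
  // per-component constants, refreshed each iteration:
  // log w_j - log(2*pi) - 0.5*log|Sigma_j| and the inverse-covariance terms
  std::vector<double> kc(k), ia(k), ib(k), ic(k);
  double ll_old = R_NegInf, ll = R_NegInf;
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < k; ++j) {
      double a = comps[j].a, b = comps[j].b, c = comps[j].c;
      double det = a * c - b * b;
      int guard = 0;
      while ((!std::isfinite(det) || det < reg * reg) && guard++ < 60) {
        a += reg; c += reg;
        det = a * c - b * b;
      }
      comps[j].a = a; comps[j].c = c;
      kc[j] = std::log(comps[j].w) - (M_LN2 + std::log(M_PI))
              - 0.5 * std::log(det);
      ia[j] = c / det; ib[j] = b / det; ic[j] = a / det;
    }
    // E-step with log-sum-exp
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double dx = x[i] - comps[j].mx, dy = y[i] - comps[j].my;
        lp[j] = kc[j] - 0.5 * (ia[j] * dx * dx - 2.0 * ib[j] * dx * dy
                               + ic[j] * dy * dy);
        if (lp[j] > m) m = lp[j];
      }
      if (k == 1) {
        ll += lp[0];
        resp[0][i] = 1.0;
        continue;
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) { resp[j][i] = std::exp(lp[j] - m); s += resp[j][i]; }
      ll += m + std::log(s);
      double inv = 1.0 / s;
      for (int j = 0; j < k; ++j) resp[j][i] *= inv;
    }
    if (!std::isfinite(ll)) return fit;
    if (iter > 0 && std::fabs(ll - ll_old) < tol * (1.0 + std::fabs(ll))) {
      ll_old = ll;
      break;
    }
    ll_old = ll;
    // M-step
    for (int j = 0; j < k; ++j) {
      double sw = 0, smx = 0, smy = 0;
      for (int i = 0; i < n; ++i) { sw += resp[j][i]; smx += resp[j][i] * x[i]; smy += resp[j][i] * y[i]; }
      if (sw < 1e-10) sw = 1e-10;
      comps[j].w = sw / n; comps[j].mx = smx / sw; comps[j].my = smy / sw;
      double sa = 0, sb = 0, sc = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x[i] - comps[j].mx, dy = y[i] - comps[j].my;
        sa += resp[j][i] * dx * dx; sb += resp[j][i] * dx * dy; sc += resp[j][i] * dy * dy;
      }
      comps[j].a = sa / sw + reg; comps[j].b = sb / sw; comps[j].c = sc / sw + reg;
    }
  }
  fit.ok = std::isfinite(ll_old);
  fit.loglik = ll_old;
  fit.comps = comps;
  fit.resp = resp;
  return fit;
}

// [[Rcpp::export]]
List cpp_gmm_pair(NumericVector x, NumericVector y, int max_k, double seed,
                  double tol, int max_iter) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  NumericVector bic(max_k, NA_REAL);
  NumericVector loglik(max_k, NA_REAL);
  int best_k = 0;
  double best_bic = R_PosInf;
  EmFit best_fit;
  uint64_t sd = (uint64_t)seed;
  for (int k = 1; k <= max_k; ++k) {
    if (k > n) continue;
    XRng rng(sd * 1000003ULL + (uint64_t)k * 7919ULL + 12345ULL);
    EmFit fit = em_fit(xv, yv, k, rng, tol, max_iter);
    if (!fit.ok) continue; // EM non-convergence to finite loglik: skip k
    double npar = 6.0 * k - 1.0;
    double b = -2.0 * fit.loglik + npar * std::log((double)n);
    bic[k - 1] = b;
    loglik[k - 1] = fit.loglik;
    if (b < best_bic) { best_bic = b; best_k = k; best_fit = fit; }
  }
  IntegerVector labels(n, NA_INTEGER);
  if (best_k > 0) {
    for (int i = 0; i < n; ++i) {
      int bj = 0; double bv = -1.0;
      for (int j = 0; j < best_k; ++j)
        if (best_fit.resp[j][i] > bv) { bv = best_fit.resp[j][i]; bj = j; }
      labels[i] = bj + 1; // 1-based component index
    }
  }
  return List::create(_["k"] = best_k, _["labels"] = labels, _["bic"] = bic,
                      _["loglik"] = loglik);
}
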