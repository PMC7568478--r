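// Weighted quantile regression of y on (1, x) by linear programming.
//
// The fit minimizes sum_i w_i * rho_tau(y_i - a - b x_i) with the check loss
// rho_tau(r) = r * (tau - 1[r < 0]).  Since rho_tau is positively homogeneous,
// the weighted problem equals the unweighted problem on rows scaled by w_i,
// i.e. design columns (w_i, w_i x_i) and response w_i y_i.
//
// Solver: primal-dual interior point (Mehrotra predictor-corrector) on the
// bounded-variable dual
//     max Y'd   s.t.  A'd = (1 - tau) A'1,  0 <= d <= 1,
// whose KKT multipliers recover the coefficients, followed by a "vertex
// polish": an optimal basic solution passes through two data points, so the
// lines through pairs of the smallest-residual points are enumerated and the
// best exact check-loss objective is kept.  The polish set is intentionally
// small (k nearest residuals) so the solver never degenerates into the
// brute-force enumeration used as an independent oracle in the tests.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct RqResult {
  double a, b, obj;
  int iters;
  bool converged;
};

// exact weighted check loss in original coordinates
double check_loss(const std::vector<double> &x, const std::vector<double> &y,
                  const std::vector<double> &w, double tau, double a, double b) {
  double s = 0.0;
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    double r = y[i] - a - b * x[i];
    s += w[i] * (r >= 0 ? tau * r : (tau - 1.0) * r);
  }
  return s;
}

// scratch space reused across fits on the same data
struct RqWork {
  std::vector<double> c1, c2, Y, u, v, d, om, rp, iH, g, dd, du, dv, iom, id;
  void resize(int n) {
    c1.resize(n); c2.resize(n); Y.resize(n); u.resize(n); v.resize(n);
    d.resize(n); om.resize(n); rp.resize(n); iH.resize(n); g.resize(n);
    dd.resize(n); du.resize(n); dv.resize(n); iom.resize(n); id.resize(n);
  }
};

// interior point iterations on standardized, weight-scaled data.
// have_init: warm start from coefficients (in original coordinates).
RqResult rq_interior(const std::vector<double> &x, const std::vector<double> &y,
                     const std::vector<double> &w, double tau, RqWork &wk,
                     bool have_init = false, double a0 = 0, double b0 = 0) {
  const int n = (int)x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (x[i] - mx) * (x[i] - mx);
    sy += (y[i] - my) * (y[i] - my);
  }
  sx = std::sqrt(sx / std::max(1, n - 1));
  sy = std::sqrt(sy / std::max(1, n - 1));
  if (sx <= 0) stop("predictor is constant; quantile regression slope undefined");
  if (sy <= 0) sy = 1.0;

  wk.resize(n);
  std::vector<double> &c1 = wk.c1, &c2 = wk.c2, &Y = wk.Y, &u = wk.u, &v = wk.v,
                      &d = wk.d, &om = wk.om, &rp = wk.rp, &iH = wk.iH,
                      &g = wk.g, &dd = wk.dd, &du = wk.du, &dv = wk.dv,
                      &iom = wk.iom, &id = wk.id;
  for (int i = 0; i < n; ++i) {
    c1[i] = w[i];
    c2[i] = w[i] * (x[i] - mx) / sx;
    Y[i]  = w[i] * (y[i] - my) / sy;
  }

  double beta1, beta2;
  if (have_init) {
    beta2 = b0 * sx / sy;
    beta1 = (a0 - my + b0 * mx) / sy;
  } else {
    // weighted least squares start
    double s11 = 0, s12 = 0, s22 = 0, t1 = 0, t2 = 0;
    for (int i = 0; i < n; ++i) {
      s11 += c1[i] * c1[i]; s12 += c1[i] * c2[i]; s22 += c2[i] * c2[i];
      t1 += c1[i] * Y[i];   t2 += c2[i] * Y[i];
    }
    double det = s11 * s22 - s12 * s12;
    beta1 = beta2 = 0;
    if (std::fabs(det) > 1e-300) {
      beta1 = (s22 * t1 - s12 * t2) / det;
      beta2 = (s11 * t2 - s12 * t1) / det;
    }
  }

  double mabs = 0;
  for (int i = 0; i < n; ++i)
    mabs += std::fabs(Y[i] - c1[i] * beta1 - c2[i] * beta2);
  mabs /= n;
  double delta = 0.05 * mabs + 1e-4;
  for (int i = 0; i < n; ++i) {
    double r = Y[i] - c1[i] * beta1 - c2[i] * beta2;
    u[i] = (r > 0 ? r : 0.0) + delta;
    v[i] = (r < 0 ? -r : 0.0) + delta;
    d[i] = 1.0 - tau;
    om[i] = tau;
  }

  const int maxit = 60;
  const double bstep = 0.99995;
  const double gtol = 1e-9, ftol = 1e-7;
  bool converged = false;
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    // fused residual / objective pass
    double rd1 = 0, rd2 = 0, mu = 0, pobj = 0, dobj = 0, rpmax = 0;
    for (int i = 0; i < n; ++i) {
      double fit = c1[i] * beta1 + c2[i] * beta2;
      double r = Y[i] - fit;
      rp[i] = r - u[i] + v[i];
      double ar = std::fabs(rp[i]);
      if (ar > rpmax) rpmax = ar;
      rd1 += c1[i] * ((1.0 - tau) - d[i]);
      rd2 += c2[i] * ((1.0 - tau) - d[i]);
      mu += u[i] * om[i] + v[i] * d[i];
      pobj += (r >= 0 ? tau * r : (tau - 1.0) * r);
      dobj += Y[i] * (d[i] - (1.0 - tau));
    }
    mu /= 2.0 * n;
    double rdmax = std::max(std::fabs(rd1), std::fabs(rd2));
    if (pobj - dobj < gtol * (1.0 + std::fabs(pobj)) &&
        rpmax < ftol * (1.0 + mabs) && rdmax < ftol * (1.0 + mabs)) {
      converged = true;
      break;
    }

    // normal-equation matrix A' H^-1 A (shared by both Newton solves)
    double m11 = 0, m12 = 0, m22 = 0, q1 = 0, q2 = 0;
    for (int i = 0; i < n; ++i) {
      double io = 1.0 / om[i], idd = 1.0 / d[i];
      iom[i] = io; id[i] = idd;
      double ih = 1.0 / (u[i] * io + v[i] * idd);
      iH[i] = ih;
      double gi = rp[i] + u[i] - v[i];   // affine target (gamma = 0)
      g[i] = gi;
      m11 += c1[i] * ih * c1[i];
      m12 += c1[i] * ih * c2[i];
      m22 += c2[i] * ih * c2[i];
      q1 += c1[i] * ih * gi;
      q2 += c2[i] * ih * gi;
    }
    double mdet = m11 * m22 - m12 * m12;
    if (!std::isfinite(mdet) ||
        std::fabs(mdet) < 1e-14 * (std::fabs(m11 * m22) +
                                   std::fabs(m12 * m12) + 1e-300)) {
      // near-singular normal equations (degenerate active set): regularize;
      // if still unusable, accept the current iterate and let the vertex
      // polish finish the job
      double ridge = 1e-9 * (m11 + m22) + 1e-300;
      m11 += ridge;
      m22 += ridge;
      mdet = m11 * m22 - m12 * m12;
      if (!std::isfinite(mdet) || mdet <= 0) break;
    }

    // affine (predictor) direction, step lengths and mu_aff in one pass
    double b1rhs = q1 - rd1, b2rhs = q2 - rd2;
    double db1a = (m22 * b1rhs - m12 * b2rhs) / mdet;
    double db2a = (m11 * b2rhs - m12 * b1rhs) / mdet;
    double apa = 1.0, ada = 1.0;
    for (int i = 0; i < n; ++i) {
      double ddi = (g[i] - c1[i] * db1a - c2[i] * db2a) * iH[i];
      double dui = u[i] * (ddi * iom[i] - 1.0);
      double dvi = -v[i] * (1.0 + ddi * id[i]);
      dd[i] = ddi; du[i] = dui; dv[i] = dvi;
      if (ddi < 0) { double s = -d[i] / ddi; if (s < apa) apa = s; }
      else if (ddi > 0) { double s = om[i] / ddi; if (s < apa) apa = s; }
      if (dui < 0) { double s = -u[i] / dui; if (s < ada) ada = s; }
      if (dvi < 0) { double s = -v[i] / dvi; if (s < ada) ada = s; }
    }
    apa = std::min(1.0, bstep * apa);
    ada = std::min(1.0, bstep * ada);
    double mu_aff = 0;
    for (int i = 0; i < n; ++i)
      mu_aff += (u[i] + ada * du[i]) * (om[i] - apa * dd[i]) +
                (v[i] + ada * dv[i]) * (d[i] + apa * dd[i]);
    mu_aff /= 2.0 * n;
    double sig = mu > 0 ? std::pow(mu_aff / mu, 3.0) : 0.1;
    sig = std::min(1.0, std::max(0.0, sig));
    double gam = sig * mu;

    // corrector solve (same matrix, new right-hand side)
    q1 = 0; q2 = 0;
    for (int i = 0; i < n; ++i) {
      double gam1 = gam + du[i] * dd[i];   // d(omega) = -d(d)
      double gam2 = gam - dv[i] * dd[i];
      double gi = rp[i] + u[i] - gam1 * iom[i] - v[i] + gam2 * id[i];
      g[i] = gi;
      // store corrector complementarity targets in du/dv temporarily
      du[i] = gam1; dv[i] = gam2;
      q1 += c1[i] * iH[i] * gi;
      q2 += c2[i] * iH[i] * gi;
    }
    b1rhs = q1 - rd1; b2rhs = q2 - rd2;
    double db1 = (m22 * b1rhs - m12 * b2rhs) / mdet;
    double db2 = (m11 * b2rhs - m12 * b1rhs) / mdet;
    double ap = 1.0, ad = 1.0;
    for (int i = 0; i < n; ++i) {
      double ddi = (g[i] - c1[i] * db1 - c2[i] * db2) * iH[i];
      double dui = (du[i] + u[i] * ddi) * iom[i] - u[i];
      double dvi = (dv[i] - v[i] * ddi) * id[i] - v[i];
      dd[i] = ddi; du[i] = dui; dv[i] = dvi;
      if (ddi < 0) { double s = -d[i] / ddi; if (s < ap) ap = s; }
      else if (ddi > 0) { double s = om[i] / ddi; if (s < ap) ap = s; }
      if (dui < 0) { double s = -u[i] / dui; if (s < ad) ad = s; }
      if (dvi < 0) { double s = -v[i] / dvi; if (s < ad) ad = s; }
    }
    ap = std::min(1.0, bstep * ap);
    ad = std::min(1.0, bstep * ad);

    beta1 += ad * db1;
    beta2 += ad * db2;
    const double floor_uv = 1e-250, floor_d = 1e-14;
    for (int i = 0; i < n; ++i) {
      u[i] = std::max(u[i] + ad * du[i], floor_uv);
      v[i] = std::max(v[i] + ad * dv[i], floor_uv);
      double dn = d[i] + ap * dd[i];
      if (dn < floor_d) dn = floor_d;
      if (dn > 1.0 - floor_d) dn = 1.0 - floor_d;
      d[i] = dn;
      om[i] = 1.0 - dn;
    }
  }

  RqResult res;
  res.b = beta2 * sy / sx;
  res.a = my + beta1 * sy - res.b * mx;
  res.iters = it;
  res.converged = converged;
  res.obj = check_loss(x, y, w, tau, res.a, res.b);
  return res;
}

// enumerate lines through pairs of the k smallest-|residual| points and keep
// the best exact objective; an optimal basic LP solution interpolates two
// data points, which the interior-point iterate has already localized.
void rq_polish(const std::vector<double> &x, const std::vector<double> &y,
               const std::vector<double> &w, double tau, RqResult &fit) {
  const int n = (int)x.size();
  const int k = std::min(n, 8);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::partial_sort(idx.begin(), idx.begin() + k, idx.end(), [&](int i, int j) {
    double ri = std::fabs(y[i] - fit.a - fit.b * x[i]);
    double rj = std::fabs(y[j] - fit.a - fit.b * x[j]);
    if (ri != rj) return ri < rj;
    return i < j;
  });
  double xscale = 0;
  for (int i = 0; i < n; ++i) xscale = std::max(xscale, std::fabs(x[i]));
  for (int p = 0; p < k; ++p) {
    for (int q = p + 1; q < k; ++q) {
      int i = idx[p], j = idx[q];
      double dx = x[j] - x[i];
      if (std::fabs(dx) <= 1e-12 * (1.0 + xscale)) continue;
      double b = (y[j] - y[i]) / dx;
      double a = y[i] - b * x[i];
      double obj = check_loss(x, y, w, tau, a, b);
      if (obj < fit.obj) {   // first-encountered candidate wins ties
        fit.obj = obj; fit.a = a; fit.b = b;
      }
    }
  }
}

RqResult rq_solve(const std::vector<double> &x, const std::vector<double> &y,
                  const std::vector<double> &w, double tau, RqWork &wk,
                  bool polish = true, bool have_init = false,
                  double a0 = 0, double b0 = 0) {
  RqResult fit = rq_interior(x, y, w, tau, wk, have_init, a0, b0);
  if (polish) rq_polish(x, y, w, tau, fit);
  return fit;
}

} // namespace

// [[Rcpp::export]]
List rq_fit_cpp(NumericVector x, NumericVector y, NumericVector w, double tau) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 observations");
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end()), ws(w.begin(), w.end());
  RqWork wk;
  RqResult fit = rq_solve(xs, ys, ws, tau, wk);
  return List::create(_["intercept"] = fit.a, _["slope"] = fit.b,
                      _["objective"] = fit.obj, _["iterations"] = fit.iters,
                      _["converged"] = fit.converged);
}

// [[Rcpp::export]]
List rq_grid_cpp(NumericVector x, NumericVector y, NumericVector w,
                 NumericVector taus) {
  const int n = x.size(), K = taus.size();
  if (n < 3) stop("need at least 3 observations");
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end()), ws(w.begin(), w.end());
  NumericVector a(K), b(K), obj(K);
  RqWork wk;
  bool warm = false;
  double pa = 0, pb = 0;
  for (int k = 0; k < K; ++k) {
    RqResult fit = rq_solve(xs, ys, ws, taus[k], wk, true, warm, pa, pb);
    a[k] = fit.a; b[k] = fit.b; obj[k] = fit.obj;
    warm = true; pa = fit.a; pb = fit.b;
  }
  return List::create(_["intercept"] = a, _["slope"] = b, _["objective"] = obj);
}

// Family-cluster bootstrap: resample families with replacement (all pairs of a
// chosen family enter together, as often as the family is drawn) and refit the
// whole tau grid on every resample.  Uses R's RNG so results are reproducible
// from set.seed().  Resamples with a constant predictor are redrawn and
// counted.
// [[Rcpp::export]]
List rq_boot_cpp(NumericVector x, NumericVector y, NumericVector w,
                 IntegerVector fam, int nfam, NumericVector taus, int B) {
  const int n = x.size(), K = taus.size();
  std::vector<std::vector<int>> rows(nfam);
  for (int i = 0; i < n; ++i) {
    int f = fam[i];
    if (f < 0 || f >= nfam) stop("family index out of range");
    rows[f].push_back(i);
  }
  NumericMatrix slopes(B, K), intercepts(B, K);
  int redraws = 0;
  std::vector<double> xs, ys, ws;
  xs.reserve(2 * n); ys.reserve(2 * n); ws.reserve(2 * n);
  RqWork wk;
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    for (int attempt = 0; attempt < 200 && !ok; ++attempt) {
      xs.clear(); ys.clear(); ws.clear();
      for (int f = 0; f < nfam; ++f) {
        int pick = (int)std::floor(unif_rand() * nfam);
        if (pick >= nfam) pick = nfam - 1;
        for (int i : rows[pick]) {
          xs.push_back(x[i]); ys.push_back(y[i]); ws.push_back(w[i]);
        }
      }
      double mn = R_PosInf, mx = R_NegInf;
      for (double xi : xs) { mn = std::min(mn, xi); mx = std::max(mx, xi); }
      if (xs.size() >= 3 && mx > mn) ok = true; else ++redraws;
    }
    if (!ok) stop("bootstrap resampling failed: predictor constant in 200 consecutive draws");
    bool warm = false;
    double pa = 0, pb = 0;
    for (int k = 0; k < K; ++k) {
      // bootstrap replicates feed only variances; skip the vertex polish
      RqResult fit = rq_solve(xs, ys, ws, taus[k], wk, false, warm, pa, pb);
      slopes(b, k) = fit.b;
      intercepts(b, k) = fit.a;
      warm = true; pa = fit.a; pb = fit.b;
    }
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["slopes"] = slopes, _["intercepts"] = intercepts,
                      _["redraws"] = redraws);
}
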