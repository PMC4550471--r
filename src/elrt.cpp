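#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Per-locus likelihood machinery for the three-component genotype mixture
//   l(e, p) = sum_i log{ p^2 B(X,N,1-e) + 2p(1-p) B(X,N,0.5) + (1-p)^2 B(X,N,e) }
// Identical (N, X) pairs within a locus are collapsed to (pair, count) before
// evaluation; binomial pmfs are computed in log space and rescaled per pair so
// the mixture stays finite at any coverage.

// Brent's golden-section/parabolic minimizer on [ax, bx] (Brent 1973, localmin)
static double brent_fmin(double ax, double bx, double (*f)(double, void *),
                         void *info, double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(std::numeric_limits<double>::epsilon());
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  for (int it = 0; it < 200; ++it) {
    double xm = (a + b) * 0.5;
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - (b - a) * 0.5) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool golden = true;
    if (std::fabs(e) > tol1) {  // try a parabolic step
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double et = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * et) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x < xm) ? b - x : a - x;
      d = c * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw;
      w = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw;
        w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

struct Pair {
  int n, x, cnt;
  double lbe, lbh, lbv;  // log B at q = e, 0.5, 1 - e
  double lmax;           // per-pair rescaling constant
  double be, bh, bv;     // exp(lb* - lmax)
};

// log binomial pmf with the 0^0 = 1 convention so q = 0 and q = 1 are valid
static double log_binom(int x, int n, double q) {
  if (q <= 0.0) return (x == 0) ? 0.0 : R_NegInf;
  if (q >= 1.0) return (x == n) ? 0.0 : R_NegInf;
  return Rf_lchoose((double)n, (double)x) + x * std::log(q) + (n - x) * std::log1p(-q);
}

struct LocusData {
  std::vector<Pair> pairs;
  double const_term;  // sum of cnt * lmax over pairs
};

// profile log-likelihood at fixed e (already baked into pairs), as a function of p
static double loglik_p(const LocusData &d, double p) {
  double ll = d.const_term;
  const double w0 = (1.0 - p) * (1.0 - p), w1 = 2.0 * p * (1.0 - p), w2 = p * p;
  for (const Pair &pr : d.pairs) {
    double m = w0 * pr.be + w1 * pr.bh + w2 * pr.bv;
    if (m <= 0.0) return R_NegInf;
    ll += pr.cnt * std::log(m);
  }
  return ll;
}

static double neg_loglik_p(double p, void *info) {
  return -loglik_p(*static_cast<LocusData *>(info), p);
}

// collapse one locus's samples to unique (N, X) pairs; zero-coverage samples
// contribute log(1) = 0 and are dropped from the pair list
static void build_pairs(const int *N, const int *X, int n, int stride,
                        double e, LocusData &d) {
  std::vector<std::pair<int, int>> v;
  v.reserve(n);
  for (int i = 0; i < n; ++i) {
    int Ni = N[(R_xlen_t)i * stride], Xi = X[(R_xlen_t)i * stride];
    if (Ni > 0) v.push_back(std::make_pair(Ni, Xi));
  }
  std::sort(v.begin(), v.end());
  d.pairs.clear();
  d.const_term = 0.0;
  for (size_t i = 0; i < v.size();) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    Pair pr;
    pr.n = v[i].first;
    pr.x = v[i].second;
    pr.cnt = (int)(j - i);
    pr.lbe = log_binom(pr.x, pr.n, e);
    pr.lbh = log_binom(pr.x, pr.n, 0.5);
    pr.lbv = log_binom(pr.x, pr.n, 1.0 - e);
    pr.lmax = std::max(pr.lbe, std::max(pr.lbh, pr.lbv));
    pr.be = std::exp(pr.lbe - pr.lmax);
    pr.bh = std::exp(pr.lbh - pr.lmax);
    pr.bv = std::exp(pr.lbv - pr.lmax);
    d.const_term += pr.cnt * pr.lmax;
    d.pairs.push_back(pr);
    i = j;
  }
}

// warm-start grid over p: log-spaced over [1e-5, 0.02] then linear up to 1
static std::vector<double> warm_grid() {
  std::vector<double> g;
  const int n_log = 20, n_lin = 30;
  double l0 = std::log(1e-5), l1 = std::log(0.02);
  for (int i = 0; i < n_log; ++i)
    g.push_back(std::exp(l0 + (l1 - l0) * i / (n_log - 1)));
  for (int i = 1; i <= n_lin; ++i)
    g.push_back(0.02 + (1.0 - 0.02) * i / (double)n_lin);
  return g;
}

// maximize the profile log-likelihood over p in [0, 1] at fixed e;
// returns max value, sets *p_hat
static double profile_max(LocusData &d, double l0, double *p_hat) {
  static std::vector<double> grid = warm_grid();
  // score at p = 0: l'(0) = 2 * sum cnt * (B_h/B_e - 1); +Inf if any B_e = 0
  double score = 0.0;
  bool inf_score = false;
  for (const Pair &pr : d.pairs) {
    if (pr.be <= 0.0) { inf_score = true; break; }
    score += pr.cnt * (pr.bh / pr.be - 1.0);
  }
  double best = l0, pbest = 0.0;
  int best_idx = -1;
  for (size_t i = 0; i < grid.size(); ++i) {
    double ll = loglik_p(d, grid[i]);
    if (ll > best) { best = ll; pbest = grid[i]; best_idx = (int)i; }
  }
  if (!inf_score && score <= 0.0 && best_idx < 0) {
    *p_hat = 0.0;  // decreasing at the boundary, no interior grid improvement
    return l0;
  }
  double lo, hi;
  if (best_idx < 0) {         // positive score but grid never beat l(0)
    lo = 0.0; hi = grid[0];
  } else {
    lo = (best_idx == 0) ? 0.0 : grid[best_idx - 1];
    hi = (best_idx + 1 < (int)grid.size()) ? grid[best_idx + 1] : 1.0;
  }
  double popt = brent_fmin(lo, hi, neg_loglik_p, &d, 1e-8);
  double lopt = loglik_p(d, popt);
  if (lopt < best) { lopt = best; popt = pbest; }
  double l1 = loglik_p(d, 1.0);
  if (l1 > lopt) { lopt = l1; popt = 1.0; }
  *p_hat = popt;
  return lopt;
}

// [[Rcpp::export]]
List cpp_elrt_batch(IntegerMatrix N, IntegerMatrix X, double zero_eps) {
  const int J = N.nrow(), n = N.ncol();
  NumericVector stat(J), e_tilde(J), maf_hat(J);
  LogicalVector is_zero(J);
  IntegerVector warn_high_e(0);
  std::vector<int> high_e;
  LocusData d;
  for (int j = 0; j < J; ++j) {
    long long sn = 0, sx = 0;
    for (int i = 0; i < n; ++i) { sn += N(j, i); sx += X(j, i); }
    if (sn == 0) {
      stat[j] = NA_REAL; e_tilde[j] = NA_REAL; maf_hat[j] = NA_REAL;
      is_zero[j] = NA_LOGICAL;
      continue;
    }
    double e = (double)sx / (double)sn;
    e_tilde[j] = e;
    if (e >= 0.5) high_e.push_back(j + 1);
    if (sx == 0) {  // e~ = 0: p = 0 attains the maximum (all mass on reference)
      stat[j] = 0.0; maf_hat[j] = 0.0; is_zero[j] = true;
      continue;
    }
    build_pairs(&N(j, 0), &X(j, 0), n, J, e, d);
    double l0 = loglik_p(d, 0.0);
    double ph = 0.0;
    double lmax = profile_max(d, l0, &ph);
    double T = 2.0 * (lmax - l0);
    if (T < 0.0) T = 0.0;
    stat[j] = T;
    maf_hat[j] = ph;
    is_zero[j] = (T < zero_eps);
  }
  return List::create(_["statistic"] = stat, _["e_tilde"] = e_tilde,
                      _["maf_hat"] = maf_hat, _["is_zero"] = is_zero,
                      _["high_error_loci"] = wrap(high_e));
}

// profile maximization over p at an arbitrary fixed e (used by the full LRT)
// [[Rcpp::export]]
List cpp_profile_max(IntegerVector N, IntegerVector X, double e) {
  LocusData d;
  build_pairs(&N[0], &X[0], N.size(), 1, e, d);
  double l0 = loglik_p(d, 0.0);
  double ph = 0.0;
  double lmax = profile_max(d, l0, &ph);
  return List::create(_["value"] = lmax, _["maf_hat"] = ph, _["loglik0"] = l0);
}

// mixture log-likelihood at arbitrary (e, p) — fast route, cross-checked in R
// [[Rcpp::export]]
double cpp_mixture_loglik(IntegerVector N, IntegerVector X, double e, double p) {
  LocusData d;
  build_pairs(&N[0], &X[0], N.size(), 1, e, d);
  return loglik_p(d, p);
}
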