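#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic.
//
// dip(x) = min over unimodal CDFs G of sup_t |F_n(t) - G(t)|, where F_n is the
// empirical CDF. Computed by bisection on the band half-width eps.
//
// Reduction to knot constraints: let t_1 < ... < t_m be the unique order
// statistics with cumulative counts c_1 < ... < c_m (c_m = n). A unimodal G
// within sup-distance eps of the ecdf must satisfy, at every knot j,
//     G(t_j)   >= c_j/n     - eps   (lower band l_j)
//     G(t_j^-) <= c_{j-1}/n + eps   (upper band u_j)
// and conversely any nondecreasing G meeting the knot bands is within eps.
// G is convex left of its mode and concave right of it (open half-lines, so
// an atom at the mode is allowed: at the mode knot k the left limit v obeys
// only the upper band and the right value w only the lower band).
//
// Feasibility at fixed eps, for mode knot k, requires
//   (L) a nondecreasing convex chain through the bands at knots 1..k-1,
//       ending at some v <= u_k at t_k;
//   (R) a nondecreasing concave chain through the bands at knots k+1..m,
//       starting at some w in [l_k, min(u_{k+1}, 1)] at t_k;
//   (C) a compatible pair v <= w.
// The pointwise-minimal convex chain is the upper envelope of support lines
//   t -> l_q + (t - t_q) * sigma_q,   sigma_q = max(0, max_{p<q} (l_q-u_p)/(t_q-t_p)),
// (every feasible chain dominates each line by convexity + the bands, and the
// envelope itself is convex, nondecreasing and >= l, so it is feasible as soon
// as it clears the upper bands). Its value at t_k is the minimal attainable
// v = A_k; mirror symmetry (t -> -t, y -> 1-y swaps convex/concave and the
// band roles) gives the maximal attainable w = B_k. eps is feasible iff some
// mode knot k passes (L), (R) and A_k <= B_k.

static const double TOL = 1e-12;

// For bands (l, u) at knots t (all length m), computes for each mode knot k:
//   ok[k]  - prefix knots 1..k-1 admit a convex chain and A_k <= u_k
//   A[k]   - minimal attainable end value at t_k (>= 0)
// Envelope evaluated in O(m^2).
static void convex_min_end(const std::vector<double>& t,
                           const std::vector<double>& lo,
                           const std::vector<double>& up,
                           std::vector<bool>& ok, std::vector<double>& A) {
  int m = (int) t.size();
  std::vector<double> sigma(m, 0.0);
  for (int q = 1; q < m; ++q) {
    double s = 0.0;
    for (int p = 0; p < q; ++p) {
      double cand = (lo[q] - up[p]) / (t[q] - t[p]);
      if (cand > s) s = cand;
    }
    sigma[q] = s;
  }
  // envelope value at knot j using support lines from q <= j
  bool prefix_ok = true;
  for (int k = 0; k < m; ++k) {
    // A_k: lines from q <= k-1 evaluated at t_k
    double a = 0.0;
    for (int q = 0; q < k; ++q) {
      double v = lo[q] + (t[k] - t[q]) * sigma[q];
      if (v > a) a = v;
    }
    A[k] = a;
    ok[k] = prefix_ok && (a <= up[k] + TOL);
    // extend prefix check through knot k for subsequent modes: envelope at
    // t_k now includes its own support line (value >= l_k) and must clear u_k
    double mk = std::max(a, lo[k]);
    if (mk > up[k] + TOL) prefix_ok = false;
  }
}

static bool feasible(const std::vector<double>& t,
                     const std::vector<double>& lo,
                     const std::vector<double>& up,
                     std::vector<double>& mt, std::vector<double>& mlo,
                     std::vector<double>& mup, std::vector<bool>& okL,
                     std::vector<bool>& okR, std::vector<double>& A,
                     std::vector<double>& B) {
  int m = (int) t.size();
  convex_min_end(t, lo, up, okL, A);
  // mirrored problem: knot i~ = m-1-k, t~ = -t, bands swap roles
  for (int i = 0; i < m; ++i) {
    int j = m - 1 - i;
    mt[i] = -t[j];
    mlo[i] = 1.0 - up[j];
    mup[i] = 1.0 - lo[j];
  }
  std::vector<bool> mok(m);
  std::vector<double> mA(m);
  convex_min_end(mt, mlo, mup, mok, mA);
  for (int k = 0; k < m; ++k) {
    int kt = m - 1 - k;
    double b = 1.0 - mA[kt];             // maximal concave start value
    if (k + 1 < m && up[k + 1] < b) b = up[k + 1]; // w <= u_{k+1}
    if (b > 1.0) b = 1.0;
    B[k] = b;
    okR[k] = mok[kt] && (b >= lo[k] - TOL);
  }
  for (int k = 0; k < m; ++k) {
    if (okL[k] && okR[k] && A[k] <= B[k] + TOL) return true;
  }
  return false;
}

static double dip_sorted(const std::vector<double>& xs) {
  int n = (int) xs.size();
  std::vector<double> t;
  std::vector<int> cum;
  t.reserve(n); cum.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (t.empty() || xs[i] > t.back()) { t.push_back(xs[i]); cum.push_back(i + 1); }
    else cum.back() = i + 1;
  }
  int m = (int) t.size();
  if (m == 1) return 0.0;

  std::vector<double> lo(m), up(m), mt(m), mlo(m), mup(m), A(m), B(m);
  std::vector<bool> okL(m), okR(m);
  double lo_eps = 0.0, hi_eps = 0.25 + 1.0 / n;
  for (int it = 0; it < 60 && hi_eps - lo_eps > 1e-14; ++it) {
    double eps = 0.5 * (lo_eps + hi_eps);
    for (int j = 0; j < m; ++j) {
      lo[j] = std::max((double) cum[j] / n - eps, 0.0);
      up[j] = std::min((j == 0 ? 0.0 : (double) cum[j - 1] / n) + eps, 1.0);
    }
    if (feasible(t, lo, up, mt, mlo, mup, okL, okR, A, B)) hi_eps = eps;
    else lo_eps = eps;
  }
  return 0.5 * (lo_eps + hi_eps);
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// [[Rcpp::export(name = ".dip_uniform_null_cpp")]]
NumericVector dip_uniform_null_cpp(int n, int n_boot) {
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    NumericVector u = runif(n);
    std::vector<double> xs(u.begin(), u.end());
    std::sort(xs.begin(), xs.end());
    out[b] = dip_sorted(xs);
  }
  return out;
}
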