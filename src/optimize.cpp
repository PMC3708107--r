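// Exact optimization of interval-restricted (dis)similarity between two
// base pair probability matrices.
//
// For an interval [k,l] the profile-based scores compare the restricted
// marginals pi_i[k,l] = sum_{j in [k,l]} P_ij (or their upstream /
// downstream split), which row-wise cumulative sums deliver in O(1)
// per position -- the M/N bookkeeping.  Matrix-based scores restrict to
// pairs with both ends inside [k,l]; all required sums over such pairs
// satisfy the triangle recursion S(k,l) = S(k+1,l) + rowpart(k,l) and
// are tabulated in O(n^2).  Self-containedness compares the expected
// number of pairs inside the interval with the expected number of
// positions pairing across its boundary.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cum {
  int n;
  std::vector<double> r;   // r[i][t] = sum_{j<=t} P(i,j); t in 0..n
  std::vector<double> pi;  // pi[i] = r[i][n]
  std::vector<double> piPre; // prefix sums of pi, piPre[t] = sum_{i<=t}
  double R(int i, int t) const { return r[(size_t)(i - 1) * (n + 1) + t]; }
  void build(const NumericMatrix &P) {
    n = P.nrow();
    r.assign((size_t)n * (n + 1), 0.0);
    pi.assign(n + 1, 0.0);
    piPre.assign(n + 1, 0.0);
    for (int i = 1; i <= n; ++i) {
      double acc = 0.0;
      size_t base = (size_t)(i - 1) * (n + 1);
      for (int t = 1; t <= n; ++t) {
        acc += P(i - 1, t - 1);
        r[base + t] = acc;
      }
      pi[i] = acc;
      piPre[i] = piPre[i - 1] + acc;
    }
  }
};

// upper-triangular table with recursion S(k,l) = S(k+1,l) + row(k,l)
struct Tri {
  int n;
  std::vector<double> v;
  double &at(int k, int l) { return v[(size_t)(k - 1) * n + (l - 1)]; }
  double get(int k, int l) const {
    return (k > l) ? 0.0 : v[(size_t)(k - 1) * n + (l - 1)];
  }
};

// sum over pairs k <= i < j <= l of f(P1(i,j), P2(i,j)); rowTerm gives
// sum_{j=k+1..l} f(P1(k,j), P2(k,j)) incrementally.
template <typename F>
void buildTri(Tri &T, const NumericMatrix &P1, const NumericMatrix &P2,
              F f) {
  const int n = P1.nrow();
  T.n = n;
  T.v.assign((size_t)n * n, 0.0);
  for (int k = n; k >= 1; --k) {
    double row = 0.0;
    for (int l = k; l <= n; ++l) {
      if (l > k) row += f(P1(k - 1, l - 1), P2(k - 1, l - 1));
      T.at(k, l) = ((k < n && l > k) ? T.get(k + 1, l) : 0.0) + row;
    }
  }
}

} // namespace

// basis: 0 = pi profile, 1 = xi^<> profile, 2 = full matrix
// measure: 0 = Euclidean distance (maximized), 1 = Pearson (minimized)
// fixedK > 0 anchors the interval start (re-optimization mode);
// lMax > 0 caps the interval end.  Matrices must already be
// threshold-filtered by the caller.
// [[Rcpp::export(name = ".cppOptimizeInterval")]]
List cppOptimizeInterval(const NumericMatrix &P1, const NumericMatrix &P2,
                         int basis, int measure, int minLen, double alpha,
                         bool selfContain, int fixedK, int lMax) {
  const int n = P1.nrow();
  if (P2.nrow() != n || P1.ncol() != n || P2.ncol() != n)
    stop("matrices must be square and of equal size");
  Cum c1, c2;
  c1.build(P1);
  c2.build(P2);

  Tri win1, win2; // expected pairs fully inside [k,l]
  if (selfContain) {
    buildTri(win1, P1, P2, [](double a, double) { return a; });
    buildTri(win2, P1, P2, [](double, double b) { return b; });
  }

  Tri dU, s1, s2, q1, q2, x12; // matrix-basis tables
  if (basis == 2) {
    buildTri(dU, P1, P2, [](double a, double b) { return (a - b) * (a - b); });
    if (measure == 1) {
      buildTri(s1, P1, P2, [](double a, double) { return a; });
      buildTri(s2, P1, P2, [](double, double b) { return b; });
      buildTri(q1, P1, P2, [](double a, double) { return a * a; });
      buildTri(q2, P1, P2, [](double, double b) { return b * b; });
      buildTri(x12, P1, P2, [](double a, double b) { return a * b; });
    }
  }

  const int kLo = (fixedK > 0) ? fixedK : 1;
  const int kHi = (fixedK > 0) ? fixedK : n - minLen + 1;
  const int lCap = (lMax > 0) ? std::min(lMax, n) : n;

  double best = (measure == 0) ? -1.0 : 2.0;
  int bestK = 0, bestL = 0;
  bool found = false;

  for (int k = kLo; k <= kHi; ++k) {
    const int lStart = (fixedK > 0) ? k + 1 : k + minLen - 1;
    // running sums for the profile bases, extended as l grows
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; // unused for d
    for (int l = lStart; l <= lCap; ++l) {
      if (selfContain) {
        const double in1 = win1.get(k, l), in2 = win2.get(k, l);
        const double tot1 = c1.piPre[l] - c1.piPre[k - 1];
        const double tot2 = c2.piPre[l] - c2.piPre[k - 1];
        const bool ok1 = in1 >= alpha * (tot1 - 2.0 * in1);
        const bool ok2 = in2 >= alpha * (tot2 - 2.0 * in2);
        if (!ok1 && !ok2) continue;
      }
      double score;
      bool valid = true;
      if (basis == 2) {
        const double len = (double)(l - k + 1);
        const double m = len * (len - 1.0) / 2.0;
        if (measure == 0) {
          score = std::sqrt(std::max(0.0, dU.get(k, l)));
        } else {
          const double S1 = s1.get(k, l), S2 = s2.get(k, l);
          const double va = m * q1.get(k, l) - S1 * S1;
          const double vb = m * q2.get(k, l) - S2 * S2;
          if (m < 1.0 || va <= 1e-18 || vb <= 1e-18) valid = false;
          else score = (m * x12.get(k, l) - S1 * S2) / std::sqrt(va * vb);
        }
      } else {
        // profile bases: recompute the interval sums from the row
        // cumulants (restricted marginals change with both bounds, so
        // no simple incremental update in l exists for them)
        double ssd = 0;
        sa = sb = saa = sbb = sab = 0;
        double m = 0;
        for (int i = k; i <= l; ++i) {
          double a1, a2, b1, b2;
          if (basis == 0) {
            a1 = c1.R(i, l) - c1.R(i, k - 1);
            b1 = c2.R(i, l) - c2.R(i, k - 1);
            if (measure == 0) {
              const double d = a1 - b1;
              ssd += d * d;
            } else {
              sa += a1; sb += b1; saa += a1 * a1; sbb += b1 * b1;
              sab += a1 * b1;
            }
            m += 1;
          } else {
            a1 = c1.R(i, i - 1) - c1.R(i, k - 1); // upstream
            a2 = c1.R(i, l) - c1.R(i, i - 1);     // downstream
            b1 = c2.R(i, i - 1) - c2.R(i, k - 1);
            b2 = c2.R(i, l) - c2.R(i, i - 1);
            if (measure == 0) {
              const double d1 = a1 - b1, d2 = a2 - b2;
              ssd += d1 * d1 + d2 * d2;
            } else {
              sa += a1 + a2; sb += b1 + b2;
              saa += a1 * a1 + a2 * a2; sbb += b1 * b1 + b2 * b2;
              sab += a1 * b1 + a2 * b2;
            }
            m += 2;
          }
        }
        if (measure == 0) {
          score = std::sqrt(ssd);
        } else {
          const double va = m * saa - sa * sa;
          const double vb = m * sbb - sb * sb;
          if (va <= 1e-18 || vb <= 1e-18) valid = false;
          else score = (m * sab - sa * sb) / std::sqrt(va * vb);
        }
      }
      if (!valid) continue;
      if (measure == 1 && score > 1.0) score = 1.0;
      if (measure == 1 && score < -1.0) score = -1.0;
      const bool better = (measure == 0) ? (score > best) : (score < best);
      if (better) {
        best = score;
        bestK = k;
        bestL = l;
        found = true;
      }
    }
  }

  return List::create(_["k"] = bestK, _["l"] = bestL, _["score"] = best,
                      _["found"] = found);
}
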