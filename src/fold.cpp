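// Partition-function folding under a simple base-pair energy model.
//
// The model assigns each admissible pair (GC, AU, GU and reverses) a
// Boltzmann weight exp(-e/RT) and a structure the product of its pair
// weights; hairpin loops must enclose at least `minHairpin` unpaired
// bases.  Inside (McCaskill) recursions give the partition function,
// an outside pass gives base pair probabilities.  All recursions use
// per-nucleotide rescaling so that sequences of several hundred nt do
// not overflow double precision; probabilities are scale-invariant.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// q(i,j): scaled partition function of segment [i,j], 1-based; empty
// segments (j < i) have q = 1.  Dense (n+2)^2 storage keeps indexing
// simple at the sequence sizes this model targets.
struct Inside {
  int n;
  std::vector<double> q, qb, qt;
  double &Q(int i, int j) { return q[(size_t)i * (n + 2) + j]; }
  double &QB(int i, int j) { return qb[(size_t)i * (n + 2) + j]; }
  double getQ(int i, int j) const {
    return (j < i) ? 1.0 : q[(size_t)i * (n + 2) + j];
  }
  double getQB(int i, int j) const { return qb[(size_t)i * (n + 2) + j]; }
  // transposed copy qt[j][i] = q(i, j) for i <= j + 1 (1 on empties):
  // the outside recursions scan segments with a fixed right end, which
  // this layout serves with unit stride
  void fillTransposed() {
    qt.assign((size_t)(n + 2) * (n + 2), 0.0);
    for (int j = 0; j <= n; ++j)
      for (int i = 1; i <= j + 1; ++i)
        qt[(size_t)j * (n + 2) + i] = getQ(i, j);
  }
  const double *qtRow(int j) const { return &qt[(size_t)j * (n + 2)]; }
};

// Inside recursion over [1,n]: pairs limited to span <= maxSpan (0 =
// unlimited), segments to width <= maxSeg (0 = unlimited).  `pw` is
// the n x n matrix of pair Boltzmann weights (0 where not pairable),
// `s` the per-nucleotide rescaling base.
void insideFill(Inside &in, const NumericMatrix &pw, int minH, double s,
                int maxSpan, int maxSeg) {
  const int n = in.n;
  in.q.assign((size_t)(n + 2) * (n + 2), 0.0);
  in.qb.assign((size_t)(n + 2) * (n + 2), 0.0);
  const double invs = 1.0 / s, invs2 = invs * invs;
  const int segLim = (maxSeg > 0) ? maxSeg : n;
  const int spanLim = (maxSpan > 0) ? maxSpan : n;
  for (int span = 0; span < segLim; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      const int j = i + span;
      if (span >= minH + 1 && span <= spanLim && pw(i - 1, j - 1) > 0.0)
        in.QB(i, j) = pw(i - 1, j - 1) * invs2 * in.getQ(i + 1, j - 1);
      double v = (span == 0) ? invs : in.Q(i, j - 1) * invs;
      const int kmin = std::max(i, j - spanLim);
      for (int k = kmin; k <= j - minH - 1; ++k) {
        const double b = in.getQB(k, j);
        if (b > 0.0) v += in.getQ(i, k - 1) * b;
      }
      in.Q(i, j) = v;
    }
  }
}

// Choose the rescaling base adaptively: refill until the largest
// segment value is finite and away from the underflow floor.  On
// return `in` holds a valid fill for the returned base.
double calibrateScale(Inside &in, const NumericMatrix &pw, int minH,
                      int maxSpan, int maxSeg, double gcFrac) {
  const int n = in.n;
  const int segLim = (maxSeg > 0) ? maxSeg : n;
  double s = std::exp(0.35 + 1.3 * gcFrac); // heuristic start
  for (int iter = 0; iter < 10; ++iter) {
    insideFill(in, pw, minH, s, maxSpan, maxSeg);
    double zmax = 0.0;
    bool bad = false;
    for (int i = 1; i <= n && !bad; ++i) {
      const double z = in.getQ(i, std::min(n, i + segLim - 1));
      if (!std::isfinite(z)) bad = true;
      else if (z > zmax) zmax = z;
    }
    if (!bad && zmax > 1e-150 && zmax < 1e150) return s;
    const double width = (double)std::min(n, segLim);
    if (bad || zmax <= 0.0)
      s *= std::exp(bad ? 1.0 : -1.0);
    else
      s *= std::exp(std::log(zmax) / width);
  }
  stop("could not rescale partition function into double range");
}

} // namespace

// [[Rcpp::export(name = ".cppFoldGlobal")]]
NumericMatrix cppFoldGlobal(const NumericMatrix &pairWeights, int minHairpin,
                            double gcFrac) {
  const int n = pairWeights.nrow();
  Inside in;
  in.n = n;
  const double s = calibrateScale(in, pairWeights, minHairpin, 0, 0, gcFrac);
  const double Z = in.getQ(1, n);
  if (!(Z > 0.0) || !std::isfinite(Z))
    stop("partition function over/underflow (n=%d)", n);

  NumericMatrix P(n, n); // symmetric, zero diagonal
  const double invs2 = 1.0 / (s * s);
  // G[jp][h]: sum over l > jp of wb(h,l) * O(h,l) * q(jp+1, l-1),
  // accumulated while descending through pair spans; the enclosed-pair
  // part of the outside value is then D(i,j) = sum_h G[j][h]*q(h+1,i-1).
  // Pairs below probability `cut` are skipped as potential enclosures;
  // they can contribute at most their own probability to any enclosed
  // pair, bounding the total error by n^2 * cut.
  const double cut = 1e-14;
  in.fillTransposed();
  // G[j][h]: sum over l > j of wb(h,l) * O(h,l) * q(j+1, l-1)
  std::vector<double> G((size_t)(n + 2) * (n + 2), 0.0);
  for (int span = n - 1; span >= minHairpin + 1; --span) {
    for (int i = 1; i + span <= n; ++i) {
      const int j = i + span;
      const double qb = in.getQB(i, j);
      if (qb <= 0.0) continue;
      double D = 0.0;
      const double *gRow = &G[(size_t)j * (n + 2)];
      const double *qtI = in.qtRow(i - 1); // qtI[h+1] = q(h+1, i-1)
      for (int h = 1; h < i; ++h)
        D += gRow[h] * qtI[h + 1];
      const double O = in.getQ(1, i - 1) * in.getQ(j + 1, n) + D;
      double p = qb * O / Z;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
      if (p < cut) continue;
      const double C = pairWeights(i - 1, j - 1) * invs2 * O;
      const double *qtJ = in.qtRow(j - 1); // qtJ[jp+1] = q(jp+1, j-1)
      for (int jp = i + 1; jp <= j - 1; ++jp)
        G[(size_t)jp * (n + 2) + i] += C * qtJ[jp + 1];
    }
  }
  return P;
}

namespace {

// inside-only partition function in extended precision with an
// explicit per-nucleotide scale; weights passed as a flat n*n vector
long double insideZL(const std::vector<long double> &pw, int n, int minH,
                     long double s) {
  std::vector<long double> q((size_t)(n + 2) * (n + 2), 0.0L);
  std::vector<long double> qb((size_t)(n + 2) * (n + 2), 0.0L);
  const long double invs = 1.0L / s, invs2 = invs * invs;
  auto Q = [&](int i, int j) -> long double {
    return (j < i) ? 1.0L : q[(size_t)i * (n + 2) + j];
  };
  for (int span = 0; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      const int j = i + span;
      if (span >= minH + 1 && pw[(size_t)(i - 1) * n + (j - 1)] > 0.0L)
        qb[(size_t)i * (n + 2) + j] =
          pw[(size_t)(i - 1) * n + (j - 1)] * invs2 * Q(i + 1, j - 1);
      long double v = (span == 0) ? invs : Q(i, j - 1) * invs;
      for (int k = i; k <= j - minH - 1; ++k) {
        const long double b = qb[(size_t)k * (n + 2) + j];
        if (b > 0.0L) v += Q(i, k - 1) * b;
      }
      q[(size_t)i * (n + 2) + j] = v;
    }
  }
  return Q(1, n);
}

} // namespace

// Ensemble distance between the Boltzmann structure distributions of
// two equal-length sequences: delta^2 = Zh1/Z1^2 + Zh2/Z2^2
// - 2 Zx/(Z1 Z2), where Zh are partition functions with squared
// weights (thermal energy halved) and Zx uses the product of the two
// sequences' pair weights (pairs formable by both, energies averaged).
// All five partition functions share one scale and extended precision,
// so the heavily cancelling combination stays accurate near zero.
// [[Rcpp::export(name = ".cppEnsembleDistance")]]
double cppEnsembleDistance(const NumericMatrix &w1, const NumericMatrix &w2,
                           int minHairpin, double gcFrac) {
  const int n = w1.nrow();
  if (w2.nrow() != n) stop("weight matrices must agree in size");
  std::vector<long double> a((size_t)n * n), b((size_t)n * n),
    aa((size_t)n * n), bb((size_t)n * n), ab((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      const long double x = w1(i, j), y = w2(i, j);
      a[(size_t)i * n + j] = x;
      b[(size_t)i * n + j] = y;
      aa[(size_t)i * n + j] = x * x;
      bb[(size_t)i * n + j] = y * y;
      ab[(size_t)i * n + j] = x * y;
    }
  // common scale, calibrated on the largest system (squared weights)
  long double s = expl(0.7L + 2.6L * (long double)gcFrac);
  long double Zh1 = 0.0L;
  for (int iter = 0; iter < 12; ++iter) {
    Zh1 = insideZL(aa, n, minHairpin, s);
    if (Zh1 > 1e-280L && Zh1 < 1e280L) break;
    if (!(Zh1 > 0.0L))
      s *= expl(-2.0L);            // underflow: scale base too large
    else if (Zh1 > 1e280L || Zh1 != Zh1 || Zh1 == Zh1 * 2.0L)
      s *= expl(2.0L);             // overflow: scale base too small
    else
      s *= expl(logl(Zh1) / n);
  }
  const long double Z1 = insideZL(a, n, minHairpin, s);
  const long double Z2 = insideZL(b, n, minHairpin, s);
  const long double Zh2 = insideZL(bb, n, minHairpin, s);
  const long double Zx = insideZL(ab, n, minHairpin, s);
  if (!(Z1 > 0.0L) || !(Z2 > 0.0L))
    stop("partition function underflow in ensemble distance");
  const long double sn = powl(s, (long double)n);
  const long double A = Zh1 / (Z1 * Z1 * sn);
  const long double B = Zh2 / (Z2 * Z2 * sn);
  const long double C = Zx / (Z1 * Z2 * sn);
  long double d2 = A + B - 2.0L * C;
  if (d2 < 0.0L) d2 = 0.0L;
  return (double)sqrtl(d2);
}

// Scanning fold: arithmetic mean of per-window pair probabilities over
// all length-W windows fully inside the sequence that contain the
// pair.  Each window is folded globally (no in-model span limit); the
// span cap L only masks the averaged output.  The inside arrays do not
// depend on the window and are shared; each window gets its own
// outside pass restricted to [a, a+W-1].
// [[Rcpp::export(name = ".cppFoldScanning")]]
NumericMatrix cppFoldScanning(const NumericMatrix &pairWeights,
                              int minHairpin, int W, int L, double gcFrac) {
  const int n = pairWeights.nrow();
  if (L > W) stop("maximal pair span L must not exceed window size W");
  if (W > n) W = n;
  const int nWin = n - W + 1;
  Inside in;
  in.n = n;
  const double s = calibrateScale(in, pairWeights, minHairpin, 0, W, gcFrac);
  const double invs2 = 1.0 / (s * s);

  NumericMatrix acc(n, n);
  const double cut = 1e-14; // see cppFoldGlobal
  in.fillTransposed();
  std::vector<double> G((size_t)(n + 2) * (W + 2), 0.0); // [j][h - a + 1]
  for (int a = 1; a <= nWin; ++a) {
    const int b = a + W - 1;
    const double Zw = in.getQ(a, b);
    if (!(Zw > 0.0) || !std::isfinite(Zw))
      stop("window partition function over/underflow (window at %d)", a);
    std::fill(G.begin(), G.end(), 0.0);
    for (int span = W - 1; span >= minHairpin + 1; --span) {
      for (int i = a; i + span <= b; ++i) {
        const int j = i + span;
        const double qb = in.getQB(i, j);
        if (qb <= 0.0) continue;
        double D = 0.0;
        const double *gRow = &G[(size_t)j * (W + 2) + 1 - a];
        const double *qtI = in.qtRow(i - 1);
        for (int h = a; h < i; ++h)
          D += gRow[h] * qtI[h + 1];
        const double O = in.getQ(a, i - 1) * in.getQ(j + 1, b) + D;
        double p = qb * O / Zw;
        if (p < 0.0) p = 0.0;
        if (p > 1.0) p = 1.0;
        acc(i - 1, j - 1) += p;
        if (p < cut) continue;
        const double C = pairWeights(i - 1, j - 1) * invs2 * O;
        const double *qtJ = in.qtRow(j - 1);
        for (int jp = i + 1; jp <= j - 1; ++jp)
          G[(size_t)jp * (W + 2) + (i - a + 1)] += C * qtJ[jp + 1];
      }
    }
  }

  NumericMatrix P(n, n);
  for (int i = 1; i < n; ++i) {
    for (int j = i + 1; j <= std::min(n, i + L); ++j) {
      const int cnt = std::min(i, nWin) - std::max(1, j - W + 1) + 1;
      if (cnt <= 0) continue;
      const double p = acc(i - 1, j - 1) / cnt;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  }
  return P;
}
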