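#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance between object x (row ox of X) and neuron row n
// of W. Summation runs in feature order so results are bit-comparable with a
// plain left-to-right sum in R.
static inline double sqdist_row(const NumericMatrix& W, int n,
                                const NumericMatrix& X, int ox, int nf) {
  double d2 = 0.0;
  for (int k = 0; k < nf; ++k) {
    double diff = X(ox, k) - W(n, k);
    d2 += diff * diff;
  }
  return d2;
}

// Winner search: strict '<' keeps the smallest row-major neuron index on ties.
static inline int find_winner(const NumericMatrix& W, const NumericMatrix& X,
                              int ox, int nf, double* best_out) {
  int nn = W.nrow();
  int best = 0;
  double bestd = sqdist_row(W, 0, X, ox, nf);
  for (int n = 1; n < nn; ++n) {
    double d2 = sqdist_row(W, n, X, ox, nf);
    if (d2 < bestd) { bestd = d2; best = n; }
  }
  if (best_out) *best_out = bestd;
  return best;
}

// [[Rcpp::export]]
List cpp_map_objects(NumericMatrix W, NumericMatrix X) {
  int nObj = X.nrow(), nf = X.ncol();
  IntegerVector winner(nObj);
  NumericVector dist(nObj);
  for (int o = 0; o < nObj; ++o) {
    double d2;
    winner[o] = find_winner(W, X, o, nf, &d2) + 1;  // 1-based for R
    dist[o] = std::sqrt(d2);
  }
  return List::create(_["winner"] = winner, _["distance"] = dist);
}

// Sequential Kohonen / counter-propagation training.
//  X: objects x features (normalized), Y: objects x targets (may be 0 cols)
//  W0x, W0y: initial weights, neurons x {features, targets}, row-major neuron
//  order (neuron (i, j), 0-based, has row i * ny + j)
//  orders: epochs x nObj presentation order (1-based indices)
//  etas, radii: per-epoch schedules
// The winner is chosen from the input layer only; both layers receive the
// same triangular-neighborhood update a = max(0, 1 - d_topo / (r + 1)).
// [[Rcpp::export]]
List cpp_train_cpann(NumericMatrix X, NumericMatrix Y,
                     NumericMatrix W0x, NumericMatrix W0y,
                     IntegerMatrix orders, NumericVector etas,
                     NumericVector radii, int nx, int ny) {
  int nf = X.ncol(), nt = Y.ncol();
  int epochs = orders.nrow();
  NumericMatrix Wx = clone(W0x);
  NumericMatrix Wy = clone(W0y);

  for (int e = 0; e < epochs; ++e) {
    double eta = etas[e];
    double r = radii[e];
    // largest integer topological distance with positive weight: d < r + 1
    int dmax = (int)std::ceil(r + 1.0) - 1;
    if (dmax < 0) dmax = 0;
    for (int p = 0; p < orders.ncol(); ++p) {
      int o = orders(e, p) - 1;
      double d2;
      int win = find_winner(Wx, X, o, nf, &d2);
      int wi = win / ny, wj = win % ny;
      int ilo = wi - dmax > 0 ? wi - dmax : 0;
      int ihi = wi + dmax < nx - 1 ? wi + dmax : nx - 1;
      int jlo = wj - dmax > 0 ? wj - dmax : 0;
      int jhi = wj + dmax < ny - 1 ? wj + dmax : ny - 1;
      for (int i = ilo; i <= ihi; ++i) {
        for (int j = jlo; j <= jhi; ++j) {
          int di = i > wi ? i - wi : wi - i;
          int dj = j > wj ? j - wj : wj - j;
          int dt = di > dj ? di : dj;  // Chebyshev grid distance
          double a = 1.0 - (double)dt / (r + 1.0);
          if (a <= 0.0) continue;
          double f = eta * a;
          int n = i * ny + j;
          for (int k = 0; k < nf; ++k)
            Wx(n, k) += f * (X(o, k) - Wx(n, k));
          for (int k = 0; k < nt; ++k)
            Wy(n, k) += f * (Y(o, k) - Wy(n, k));
        }
      }
    }
  }
  return List::create(_["Wx"] = Wx, _["Wy"] = Wy);
}
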