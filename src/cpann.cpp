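// Counter-propagation ANN training core.
//
// A square Kohonen lattice of g x g neurons carries an input-weight layer
// (one p-vector per neuron) and a congruent output-weight layer (one
// r-vector per neuron). Each epoch presents the training objects in a
// freshly shuffled order; the best-matching unit (BMU) is the neuron whose
// input weights are closest (Euclidean) to the object, ties broken by the
// lowest row-major index; all neurons within the current neighbourhood
// radius move their input AND output weights toward the object's input and
// target vectors, scaled by a triangular kernel and the current learning
// rate. Learning rate decays linearly lr_max -> lr_min and the radius
// g/2 -> 0 over the epochs. All randomness comes from R's RNG so that
// set.seed() in R makes training deterministic.

#include <Rcpp.h>
using namespace Rcpp;

static inline int find_bmu(const NumericMatrix &W, const NumericMatrix &X,
                           int obj, int n_neurons, int p, double *dist_out) {
  int best = 0;
  double best_d = R_PosInf;
  for (int k = 0; k < n_neurons; ++k) {
    double d = 0.0;
    for (int j = 0; j < p; ++j) {
      double diff = W(k, j) - X(obj, j);
      d += diff * diff;
    }
    if (d < best_d) {  // strict: keeps lowest row-major index on ties
      best_d = d;
      best = k;
    }
  }
  if (dist_out) *dist_out = std::sqrt(best_d);
  return best;
}

// [[Rcpp::export(name = ".cpann_train_cpp")]]
List cpann_train_cpp(NumericMatrix X, NumericMatrix Y, int grid_n,
                     int n_epochs, double lr_max, double lr_min) {
  const int n = X.nrow(), p = X.ncol(), r = Y.ncol();
  const int nn = grid_n * grid_n;

  NumericMatrix W(nn, p), U(nn, r);
  for (int k = 0; k < nn; ++k) {
    for (int j = 0; j < p; ++j) W(k, j) = unif_rand();
    for (int j = 0; j < r; ++j) U(k, j) = unif_rand();
  }

  NumericVector qe(n_epochs);
  const double r_max = grid_n / 2.0;
  IntegerVector idx = seq(0, n - 1);

  for (int e = 0; e < n_epochs; ++e) {
    const double frac = (n_epochs > 1) ? (double)e / (n_epochs - 1) : 0.0;
    const double lr = lr_max + (lr_min - lr_max) * frac;
    const double radius = r_max * (1.0 - frac);

    IntegerVector ord = sample(idx, n, false);
    double qe_sum = 0.0;

    for (int t = 0; t < n; ++t) {
      const int obj = ord[t];
      double bmu_dist;
      const int bmu = find_bmu(W, X, obj, nn, p, &bmu_dist);
      qe_sum += bmu_dist;
      const int bi = bmu / grid_n, bj = bmu % grid_n;

      const int reach = (int)std::floor(radius);
      const int ilo = std::max(0, bi - reach), ihi = std::min(grid_n - 1, bi + reach);
      const int jlo = std::max(0, bj - reach), jhi = std::min(grid_n - 1, bj + reach);
      for (int i = ilo; i <= ihi; ++i) {
        for (int j = jlo; j <= jhi; ++j) {
          const double d = std::sqrt((double)((i - bi) * (i - bi) +
                                              (j - bj) * (j - bj)));
          if (d > radius) continue;
          const double h = lr * (1.0 - d / (radius + 1.0));
          const int k = i * grid_n + j;
          for (int c = 0; c < p; ++c) W(k, c) += h * (X(obj, c) - W(k, c));
          for (int c = 0; c < r; ++c) U(k, c) += h * (Y(obj, c) - U(k, c));
        }
      }
    }
    qe[e] = qe_sum / n;
  }

  return List::create(_["input_weights"] = W, _["output_weights"] = U,
                      _["qe"] = qe);
}

// [[Rcpp::export(name = ".cpann_bmu_cpp")]]
IntegerVector cpann_bmu_cpp(NumericMatrix W, NumericMatrix Xq, int grid_n) {
  const int nq = Xq.nrow(), p = Xq.ncol();
  const int nn = W.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i)
    out[i] = find_bmu(W, Xq, i, nn, p, nullptr) + 1;  // 1-based
  return out;
}
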