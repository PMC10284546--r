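#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inner training loop for the 2D self-organizing map.
//
// Matrices arrive transposed (feature-major) so each sample's and each
// unit's feature vector is a contiguous column:
//   xt  : F x n input matrix (column i = sample i)
//   cbt : F x U initial codebook (column k = unit k, units in row-major
//         grid order: unit k sits at row w = k / H, col h = k % H, 0-based)
// order : n x T matrix of 1-based presentation orders, one column per epoch
// Schedules: L_t = L0 * (1 - t/T);
//            linear sigma_t = max(sigma0 * (1 - t/T), floor_eps);
//            exponential sigma_t = max(sigma0 * (min(1,sigma0)/sigma0)^(t/T), floor_eps).
// Within a batch, BMUs are found against the codebook state at the start of
// the batch; updates are then applied one image at a time in batch order.
// Every unit is updated (no neighborhood cutoff): the Gaussian weight
// exp(-d^2 / (2 sigma_t^2)) decays smoothly with grid distance.

static int find_bmu_col(const double *cb, int U, int F, const double *x) {
  int best = 0;
  double best_d2 = R_PosInf;
  for (int k = 0; k < U; ++k) {
    const double *ck = cb + (size_t)k * F;
    double d2 = 0.0;
    for (int f = 0; f < F; ++f) {
      const double diff = x[f] - ck[f];
      d2 += diff * diff;
    }
    if (d2 < best_d2) { best_d2 = d2; best = k; }  // strict <: row-major tie-break
  }
  return best;
}

static double qe_cols(const double *cb, int U, int F, const double *x, int n) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *xi = x + (size_t)i * F;
    double best_d2 = R_PosInf;
    for (int k = 0; k < U; ++k) {
      const double *ck = cb + (size_t)k * F;
      double d2 = 0.0;
      for (int f = 0; f < F; ++f) {
        const double diff = xi[f] - ck[f];
        d2 += diff * diff;
      }
      if (d2 < best_d2) best_d2 = d2;
    }
    total += std::sqrt(best_d2);
  }
  return total / n;
}

// [[Rcpp::export(name = ".som_train_cpp")]]
List som_train_cpp(NumericMatrix xt, NumericMatrix cbt_init,
                   int grid_w, int grid_h, IntegerMatrix order,
                   int batch_size, double L0, double sigma0,
                   int radius_exponential, double floor_eps) {
  const int F = xt.nrow(), n = xt.ncol();
  const int U = grid_w * grid_h;
  const int T = order.ncol();
  if (cbt_init.ncol() != U || cbt_init.nrow() != F)
    stop("codebook shape does not match grid and feature dimension");
  if (order.nrow() != n)
    stop("presentation order does not match sample count");

  NumericMatrix cbt = clone(cbt_init);
  double *cb = cbt.begin();
  const double *x = xt.begin();
  NumericVector qe(T), lr_trace(T), sigma_trace(T);
  const double qe_initial = qe_cols(cb, U, F, x, n);

  std::vector<int> wcoord(U), hcoord(U);
  for (int k = 0; k < U; ++k) { wcoord[k] = k / grid_h; hcoord[k] = k % grid_h; }

  const double sigma_end = sigma0 < 1.0 ? sigma0 : 1.0;
  std::vector<int> bmu(batch_size);

  for (int t = 0; t < T; ++t) {
    const double Lt = L0 * (1.0 - (double)t / T);
    double sigma;
    if (radius_exponential)
      sigma = sigma0 * std::pow(sigma_end / sigma0, (double)t / T);
    else
      sigma = sigma0 * (1.0 - (double)t / T);
    if (sigma < floor_eps) sigma = floor_eps;
    lr_trace[t] = Lt;
    sigma_trace[t] = sigma;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

    for (int start = 0; start < n; start += batch_size) {
      const int bsz = std::min(batch_size, n - start);
      // BMUs against the codebook state at the start of the batch
      for (int b = 0; b < bsz; ++b)
        bmu[b] = find_bmu_col(cb, U, F, x + (size_t)(order(start + b, t) - 1) * F);
      // sequential per-image updates in batch order
      for (int b = 0; b < bsz; ++b) {
        const double *xi = x + (size_t)(order(start + b, t) - 1) * F;
        const int wb = wcoord[bmu[b]], hb = hcoord[bmu[b]];
        for (int k = 0; k < U; ++k) {
          const double dw = wcoord[k] - wb, dh = hcoord[k] - hb;
          const double step = Lt * std::exp(-(dw * dw + dh * dh) * inv2s2);
          double *ck = cb + (size_t)k * F;
          for (int f = 0; f < F; ++f)
            ck[f] += step * (xi[f] - ck[f]);
        }
      }
    }
    qe[t] = qe_cols(cb, U, F, x, n);
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["codebook_t"] = cbt, _["qe"] = qe,
                      _["qe_initial"] = qe_initial,
                      _["learning_rate"] = lr_trace,
                      _["radius"] = sigma_trace);
}

// [[Rcpp::export(name = ".som_qe_cpp")]]
double som_qe_cpp(NumericMatrix cbt, NumericMatrix xt) {
  if (cbt.nrow() != xt.nrow())
    stop("feature dimension mismatch between codebook and data");
  return qe_cols(cbt.begin(), cbt.ncol(), cbt.nrow(), xt.begin(), xt.ncol());
}
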