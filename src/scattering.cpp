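// Order-2 scattering engine.
//
// All filtering is done in the frequency domain. Each band-pass filter is
// stored as its non-negligible spectral support (start bin `a`, real gain
// vector `h` on consecutive bins of the global grid). After multiplying
// the input spectrum by `h`, the product is folded modulo M (a divisor of
// the transform length), which is an exact time-domain subsampling of the
// analytic filter output to M samples; the modulus (envelope) is then
// averaged. M is chosen by the R side large enough that the envelope mean
// is unaffected by the subsampling (margin over the filter bandwidth).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// envelope of (spectrum-restricted) filter output, subsampled to M points.
// Y: spectrum of the signal on the grid of length n_grid (only bins
// [a, a+h.size) are touched); scale: 1/n_grid of the originating FFT.
static arma::vec env_fold(const arma::cx_vec& Y, int a, const arma::vec& h,
                          int M, double inv_n) {
  arma::cx_vec z(M, arma::fill::zeros);
  const int s = h.n_elem;
  for (int i = 0; i < s; i++) {
    z[(a + i) % M] += Y[a + i] * h[i];
  }
  arma::cx_vec y = arma::ifft(z);          // includes 1/M
  return arma::abs(y) * (inv_n * M);       // exact subsample of full ifft
}

// [[Rcpp::export]]
List scatter_window_cpp(const arma::vec& x, List bank1, List bank2,
                        int max_order) {
  const int n = x.n_elem;
  const double inv_n = 1.0 / n;
  arma::cx_vec X = arma::fft(x);

  const int K = bank1.size();
  arma::vec S1(K);
  std::vector<arma::vec> U1(K);
  for (int k = 0; k < K; k++) {
    List f = bank1[k];
    const int a = f["a"];
    const arma::vec h = as<arma::vec>(f["h"]);
    const int M = f["M"];
    arma::vec u = env_fold(X, a, h, M, inv_n);
    S1[k] = arma::mean(u);
    if (max_order >= 2) U1[k] = u;
  }

  std::vector<double> S2;
  if (max_order >= 2) {
    for (int k = 0; k < K; k++) {
      List l2 = bank2[k];                  // second-layer filters for this λ1
      const int P = l2.size();
      if (P == 0) continue;
      const int M1 = U1[k].n_elem;
      arma::cx_vec V = arma::fft(U1[k]);
      for (int j = 0; j < P; j++) {
        List g = l2[j];
        const arma::vec h2 = as<arma::vec>(g["h"]);
        if (h2.n_elem == 0) {              // support above the envelope grid
          S2.push_back(0.0);
          continue;
        }
        const int a2 = g["a"];
        const int M2 = g["M"];
        arma::vec u2 = env_fold(V, a2, h2, M2, 1.0 / M1);
        S2.push_back(arma::mean(u2));
      }
    }
  }
  return List::create(_["S1"] = S1, _["S2"] = S2);
}
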