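// Hot loops of the 1D CNN: direct (non-materializing) valid convolution
// along time, forward and backward. Activations are (T, F, B2) arrays:
// time x filters x sequences, where the two probe rows of each window are
// independent sequences until flattening. Weights are (k*C, F) matrices with
// rows ordered shift-within-input-channel. Per-sequence output blocks stay
// cache-resident, so throughput is bounded by the multiply-accumulate work,
// not by an im2col copy.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward: Z(t, f, s) = relu(bias_f + sum_{c,j} A(t+j, c, s) * W(j + c*k, f))
// [[Rcpp::export]]
NumericVector conv1d_forward(const NumericVector& A, const arma::mat& W,
                             const arma::vec& bias, int k) {
  IntegerVector dims = A.attr("dim");
  const int T = dims[0], C = dims[1], B2 = dims[2];
  const int T_out = T - k + 1;
  const int F = W.n_cols;
  NumericVector out(static_cast<R_xlen_t>(T_out) * F * B2);
  out.attr("dim") = IntegerVector::create(T_out, F, B2);
  const double* a = A.begin();
  double* o = out.begin();
  for (int s = 0; s < B2; ++s) {
    double* Zs = o + static_cast<size_t>(s) * T_out * F;
    for (int f = 0; f < F; ++f)
      std::fill(Zs + static_cast<size_t>(f) * T_out,
                Zs + static_cast<size_t>(f + 1) * T_out, bias[f]);
    for (int c = 0; c < C; ++c) {
      const double* Ac = a + (static_cast<size_t>(s) * C + c) * T;
      for (int j = 0; j < k; ++j) {
        const double* as = Ac + j;
        for (int f = 0; f < F; ++f) {
          const double wf = W(c * k + j, f);
          if (wf == 0.0) continue;
          double* z = Zs + static_cast<size_t>(f) * T_out;
          for (int t = 0; t < T_out; ++t) z[t] += as[t] * wf;
        }
      }
    }
    const size_t n = static_cast<size_t>(T_out) * F;
    for (size_t i = 0; i < n; ++i)
      if (Zs[i] < 0.0) Zs[i] = 0.0;
  }
  return out;
}

// Backward: masks the upstream gradient by the ReLU derivative (A_out > 0),
// accumulates weight/bias gradients, and (unless this is the input layer)
// the gradient w.r.t. the layer input.
// [[Rcpp::export]]
List conv1d_backward(const NumericVector& dOut, const NumericVector& A_out,
                     const NumericVector& A_in, const arma::mat& W, int k,
                     bool input_grad) {
  IntegerVector odim = dOut.attr("dim");
  IntegerVector idim = A_in.attr("dim");
  const int T_out = odim[0], F = odim[1], B2 = odim[2];
  const int T = idim[0], C = idim[1];
  arma::mat dW(k * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dA;
  double* dain = nullptr;
  if (input_grad) {
    dA = NumericVector(static_cast<R_xlen_t>(T) * C * B2);
    dA.attr("dim") = idim;
    dain = dA.begin();
  }
  const double* dout = dOut.begin();
  const double* aout = A_out.begin();
  const double* ain = A_in.begin();
  std::vector<double> dz(static_cast<size_t>(T_out) * F);
  for (int s = 0; s < B2; ++s) {
    const size_t off = static_cast<size_t>(s) * T_out * F;
    for (int f = 0; f < F; ++f) {
      double acc = 0.0;
      const size_t fo = off + static_cast<size_t>(f) * T_out;
      double* dzf = dz.data() + static_cast<size_t>(f) * T_out;
      for (int t = 0; t < T_out; ++t) {
        const double g = aout[fo + t] > 0.0 ? dout[fo + t] : 0.0;
        dzf[t] = g;
        acc += g;
      }
      db[f] += acc;
    }
    for (int c = 0; c < C; ++c) {
      const double* Ac = ain + (static_cast<size_t>(s) * C + c) * T;
      double* dAc = input_grad
        ? dain + (static_cast<size_t>(s) * C + c) * T : nullptr;
      for (int j = 0; j < k; ++j) {
        const double* as = Ac + j;
        for (int f = 0; f < F; ++f) {
          const double* dzf = dz.data() + static_cast<size_t>(f) * T_out;
          double acc = 0.0;
          for (int t = 0; t < T_out; ++t) acc += as[t] * dzf[t];
          dW(c * k + j, f) += acc;
        }
        if (input_grad) {
          double* dac = dAc + j;
          for (int f = 0; f < F; ++f) {
            const double wf = W(c * k + j, f);
            if (wf == 0.0) continue;
            const double* dzf = dz.data() + static_cast<size_t>(f) * T_out;
            for (int t = 0; t < T_out; ++t) dac[t] += dzf[t] * wf;
          }
        }
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dA") = input_grad ? dA : NumericVector(0));
}
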