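// 1-D convolution kernels for the U-Net GAN.
//
// Layout: activations are cubes (channels, length, batch); a conv weight is
// a matrix (C_out, C_in * k) whose column index is ci * k + kk (kk fastest).
// im2col turns each sample into a (C_in * k, L_out) patch matrix so the
// convolution is one BLAS gemm per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat im2col(const mat& xs, int k, int stride, int pad,
                         int Lout) {
  const int Cin = xs.n_rows;
  const int Lin = xs.n_cols;
  mat P(Cin * k, Lout, fill::zeros);
  for (int t = 0; t < Lout; ++t) {
    const int base = t * stride - pad;
    for (int kk = 0; kk < k; ++kk) {
      const int src = base + kk;
      if (src < 0 || src >= Lin) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        P(ci * k + kk, t) = xs(ci, src);
      }
    }
  }
  return P;
}

static inline void col2im_add(mat& xs, const mat& G, int k, int stride,
                              int pad) {
  const int Cin = xs.n_rows;
  const int Lin = xs.n_cols;
  const int Lout = G.n_cols;
  for (int t = 0; t < Lout; ++t) {
    const int base = t * stride - pad;
    for (int kk = 0; kk < k; ++kk) {
      const int dst = base + kk;
      if (dst < 0 || dst >= Lin) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        xs(ci, dst) += G(ci * k + kk, t);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fw_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int k, int stride, int pad) {
  const int Lin = x.n_cols;
  const int B = x.n_slices;
  const int Cout = W.n_rows;
  const int Lout = (Lin + 2 * pad - k) / stride + 1;
  cube y(Cout, Lout, B);
  for (int s = 0; s < B; ++s) {
    mat P = im2col(x.slice(s), k, stride, pad, Lout);
    y.slice(s) = W * P;
    y.slice(s).each_col() += b;
  }
  return y;
}

// gradient w.r.t. the conv input (also the transposed-conv forward map)
// [[Rcpp::export]]
arma::cube conv1d_bw_input_cpp(const arma::mat& W, const arma::cube& gout,
                               int Lin, int k, int stride, int pad) {
  const int B = gout.n_slices;
  const int Cin = W.n_cols / k;
  cube gx(Cin, Lin, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat G = W.t() * gout.slice(s);   // (Cin*k, Lout)
    mat acc(Cin, Lin, fill::zeros);
    col2im_add(acc, G, k, stride, pad);
    gx.slice(s) = acc;
  }
  return gx;
}

// gradient w.r.t. the conv weight matrix
// [[Rcpp::export]]
arma::mat conv1d_bw_weight_cpp(const arma::cube& x, const arma::cube& gout,
                               int k, int stride, int pad) {
  const int B = x.n_slices;
  const int Cin = x.n_rows;
  const int Cout = gout.n_rows;
  const int Lout = gout.n_cols;
  mat gW(Cout, Cin * k, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat P = im2col(x.slice(s), k, stride, pad, Lout);
    gW += gout.slice(s) * P.t();
  }
  return gW;
}
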