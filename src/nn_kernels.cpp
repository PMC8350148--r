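// Compiled inner loops of the network: 'same' 1-D convolution (stride 1)
// and max-pooling (kernel 2, stride 2) over (channels, length, batch) cubes.
// Kernel layout matches the R side: W is (c_out, c_in * k) with the input
// channel running fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_slice(const arma::mat& Apad, int k, int Lout) {
  const int C = Apad.n_rows;
  arma::mat M(C * k, Lout);
  for (int t = 0; t < Lout; ++t) {
    for (int kk = 0; kk < k; ++kk) {
      M.submat(C * kk, t, C * kk + C - 1, t) = Apad.col(t + kk);
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& A, const arma::mat& W,
                      const arma::vec& b, int k, int pad) {
  const int C = A.n_rows, L = A.n_cols, B = A.n_slices;
  const int Lout = L + 2 * pad - k + 1;
  const int Cout = W.n_rows;
  arma::cube Y(Cout, Lout, B);
  arma::mat Apad(C, L + 2 * pad, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    Apad.cols(pad, pad + L - 1) = A.slice(s);
    arma::mat M = im2col_slice(Apad, k, Lout);
    Y.slice(s) = W * M;
    Y.slice(s).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(const arma::cube& dY, const arma::cube& A,
                const arma::mat& W, int k, int pad) {
  const int C = A.n_rows, L = A.n_cols, B = A.n_slices;
  const int Lout = dY.n_cols;
  arma::cube dA(C, L, B, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::mat Apad(C, L + 2 * pad, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    Apad.cols(pad, pad + L - 1) = A.slice(s);
    arma::mat M = im2col_slice(Apad, k, Lout);
    const arma::mat& dYs = dY.slice(s);
    dW += dYs * M.t();
    db += arma::sum(dYs, 1);
    arma::mat dM = W.t() * dYs;                 // (C*k, Lout)
    arma::mat dApad(C, L + 2 * pad, arma::fill::zeros);
    for (int t = 0; t < Lout; ++t) {
      for (int kk = 0; kk < k; ++kk) {
        dApad.col(t + kk) += dM.submat(C * kk, t, C * kk + C - 1, t);
      }
    }
    dA.slice(s) = dApad.cols(pad, pad + L - 1);
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".pool2_fwd")]]
List pool2_fwd(const arma::cube& A) {
  const int C = A.n_rows, L = A.n_cols, B = A.n_slices;
  const int Lo = L / 2;
  arma::cube Y(C, Lo, B);
  arma::ucube take1(C, Lo, B);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c) {
        double a1 = A(c, 2 * t, s), a2 = A(c, 2 * t + 1, s);
        bool first = a1 >= a2;           // ties to the earlier position
        Y(c, t, s) = first ? a1 : a2;
        take1(c, t, s) = first ? 1 : 0;
      }
    }
  }
  return List::create(_["out"] = Y, _["take1"] = take1);
}

// [[Rcpp::export(name = ".pool2_bwd")]]
arma::cube pool2_bwd(const arma::cube& dY, const arma::ucube& take1,
                     int L) {
  const int C = dY.n_rows, Lo = dY.n_cols, B = dY.n_slices;
  arma::cube dA(C, L, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c) {
        dA(c, take1(c, t, s) ? 2 * t : 2 * t + 1, s) = dY(c, t, s);
      }
    }
  }
  return dA;
}
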