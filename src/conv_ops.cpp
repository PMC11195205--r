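// 3x3 convolution forward/backward via im2col + BLAS gemm.
// Tensors are (H, W, C) cubes; weights are (9*Cin) x Cout matrices whose row
// order matches the column-major flattening of an R array of dim
// (3, 3, Cin, Cout). Padding is fixed at 1 (same-size output at stride 1).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const cube& x, int stride, mat& cols, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cols.zeros(9 * C, (uword)Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int row = c * 9 + kj * 3 + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - 1;
          if (ij < 0 || ij >= W) continue;
          if (stride == 1) {
            // contiguous strip over oi
            int oi0 = std::max(0, 1 - ki);          // ii = oi + ki - 1 >= 0
            int oi1 = std::min(Ho - 1, H - ki);      // ii <= H - 1
            if (oi1 < oi0) continue;
            const double* src = xc.colptr(ij) + (oi0 + ki - 1);
            double* dst = cols.colptr((uword)oj * Ho + oi0) + row;
            // cols is column-major: consecutive oi are a stride of 9*C
            for (int oi = oi0; oi <= oi1; ++oi) {
              *dst = *src++;
              dst += 9 * C;
            }
          } else {
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ki - 1;
              if (ii < 0 || ii >= H) continue;
              cols(row, (uword)oj * Ho + oi) = xc(ii, ij);
            }
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, int stride, cube& dx, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    mat& xc = dx.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int row = c * 9 + kj * 3 + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - 1;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - 1;
            if (ii < 0 || ii >= H) continue;
            xc(ii, ij) += cols(row, (uword)oj * Ho + oi);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3x3_forward(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 - 3) / stride + 1;
  const int Wo = (W + 2 - 3) / stride + 1;
  const int Cout = w.n_cols;
  mat cols;
  im2col(x, stride, cols, Ho, Wo);
  mat out = w.t() * cols;            // Cout x (Ho*Wo)
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co) = reshape(out.row(co) + b(co), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(const arma::cube& x, const arma::mat& w,
                            const arma::cube& gy, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const int Cout = w.n_cols;
  mat cols;
  im2col(x, stride, cols, Ho, Wo);
  mat gmat(Cout, (uword)Ho * Wo);
  for (int co = 0; co < Cout; ++co) {
    gmat.row(co) = vectorise(gy.slice(co)).t();
  }
  mat dw = cols * gmat.t();          // (9*Cin) x Cout
  vec db = sum(gmat, 1);
  mat dcols = w * gmat;              // (9*Cin) x (Ho*Wo)
  cube dx(H, W, x.n_slices);
  col2im(dcols, stride, dx, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}
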