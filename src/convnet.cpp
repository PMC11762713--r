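// Convolution primitives for the hand-written networks.
//
// Layout conventions (shared with the R side):
//   * feature maps are arma::cube (H, W, C), column-major as in R arrays;
//   * a conv layer's weights are one matrix of shape (Cout, k*k*Cin) whose
//     column index encodes (u, v, ci) as u + k*(v + k*ci), 0-based, with
//     (u, v) the kernel offset in (row, col);
//   * "conv" means cross-correlation with zero padding ("same", odd k).
//
// Everything is expressed through im2col + BLAS gemm so the backward pass
// can reuse the same building blocks, including the double-backprop needed
// by the W-GAN gradient penalty.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;

// patch matrix in (H*W, k*k*C) layout: column r = u + k*(v + k*c) holds the
// (u, v) shifted copy of channel c, so writes run down contiguous memory
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < k; ++v) {
      for (int u = 0; u < k; ++u) {
        const int r = u + k * (v + k * c);
        double* col = out.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + v - p;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, p - u), i1 = H + std::min(0, p - u);
          const double* src = x.slice_colptr(c, jj) + (i0 + u - p);
          std::memcpy(col + H * j + i0, src, sizeof(double) * (i1 - i0));
        }
      }
    }
  }
  return out;
}

// adjoint of im2col: scatter-add patch columns back into an (H, W, C) cube
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = k / 2;
  cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < k; ++v) {
      for (int u = 0; u < k; ++u) {
        const int r = u + k * (v + k * c);
        const double* col = cols.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + v - p;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, p - u), i1 = H + std::min(0, p - u);
          double* dst = out.slice_colptr(c, jj) + (i0 + u - p);
          const double* src = col + H * j + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return out;
}

// cube (H,W,C) viewed as (H*W, C) without copy semantics issues
static mat cube_as_mat(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols, x.n_slices,
             true, true);
}

static cube mat_as_cube(const mat& m, const int H, const int W) {
  cube out(H, W, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), sizeof(double) * m.n_elem);
  return out;
}

// [[Rcpp::export(name = ".nn_conv_fw")]]
arma::cube nn_conv_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& bias, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  mat y = im2col(x, k) * w.t();         // (H*W, Cout)
  y.each_row() += bias.t();
  return mat_as_cube(y, H, W);
}

// gradient w.r.t. the conv input; adjoint of nn_conv_fw (no bias)
// [[Rcpp::export(name = ".nn_conv_bw_input")]]
arma::cube nn_conv_bw_input(const arma::cube& dy, const arma::mat& w,
                            const int k, const int cin) {
  const int H = dy.n_rows, W = dy.n_cols;
  mat dym = cube_as_mat(dy);            // (H*W, Cout)
  mat dcols = dym * w;                  // (H*W, k*k*Cin)
  return col2im(dcols, H, W, cin, k);
}

// gradient w.r.t. the conv weights given input x and output-gradient dy
// [[Rcpp::export(name = ".nn_conv_bw_weights")]]
arma::mat nn_conv_bw_weights(const arma::cube& x, const arma::cube& dy,
                             const int k) {
  mat dym = cube_as_mat(dy);            // (H*W, Cout)
  return dym.t() * im2col(x, k);        // (Cout, k*k*Cin)
}

// 8-connected component labeling of a binary matrix (0 background).
// Labels are assigned in raster-scan discovery order, so the result is
// deterministic. Returns an integer matrix of labels.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
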