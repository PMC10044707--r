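// Compiled kernels: exact non-uniform DFT (multichannel spiral encoding)
// and 3x3 same-padding convolution primitives (im2col + BLAS gemm).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Centered grid coordinates: -n/2 ... n/2-1 (DC at index n/2, 0-based).
static vec centered(int n) {
  vec x(n);
  for (int i = 0; i < n; i++) x[i] = i - n / 2;
  return x;
}

// n_s x n matrix exp(-2*pi*i * k * x^T)
static cx_mat expmat(const vec& k, const vec& x) {
  mat ph = -2.0 * datum::pi * (k * x.t());
  return cx_mat(cos(ph), sin(ph));
}

// Forward multichannel non-uniform DFT.
// image: nx x ny complex; smaps: nx x ny x ncoil; kx, ky: length ns in
// cycles/pixel. Returns ncoil x ns samples of sum_r S_c(r) x(r) e^{-i2pi k.r}.
// [[Rcpp::export]]
arma::cx_mat nudft_forward_cpp(const arma::cx_mat& image,
                               const arma::cx_cube& smaps,
                               const arma::vec& kx, const arma::vec& ky) {
  const int nx = image.n_rows, ny = image.n_cols;
  const int nc = smaps.n_slices, ns = kx.n_elem;
  cx_mat Ex = expmat(kx, centered(nx));  // ns x nx
  cx_mat Ey = expmat(ky, centered(ny));  // ns x ny
  cx_mat ExT = Ex.st();                  // nx x ns (no conj)
  cx_mat EyT = Ey.st();                  // ny x ns
  cx_mat out(nc, ns);
  for (int c = 0; c < nc; c++) {
    cx_mat M = smaps.slice(c) % image;   // nx x ny
    cx_mat C = M * EyT;                  // nx x ns
    out.row(c) = sum(ExT % C, 0);        // sum over x
  }
  return out;
}

// Exact adjoint of nudft_forward_cpp, with optional real sample weights w
// (all ones gives the plain adjoint; a dcf gives gridding reconstruction).
// [[Rcpp::export]]
arma::cx_mat nudft_adjoint_cpp(const arma::cx_mat& samples,
                               const arma::cx_cube& smaps,
                               const arma::vec& kx, const arma::vec& ky,
                               const arma::vec& w) {
  const int nx = smaps.n_rows, ny = smaps.n_cols;
  const int nc = smaps.n_slices, ns = kx.n_elem;
  cx_mat Ex = expmat(kx, centered(nx));
  cx_mat Ey = expmat(ky, centered(ny));
  cx_mat Eyc = conj(Ey);                 // ns x ny
  cx_mat img(nx, ny, fill::zeros);
  cx_vec wc(w, vec(ns, fill::zeros));
  for (int c = 0; c < nc; c++) {
    cx_vec y = samples.row(c).st();      // ns
    y %= wc;
    cx_mat Z = Eyc.each_col() % y;       // ns x ny
    cx_mat G = Ex.t() * Z;               // (conj transpose) nx x ny
    img += conj(smaps.slice(c)) % G;
  }
  return img;
}

// ---- 3x3 same-padding convolution primitives ----------------------------
// Column layout: column index = c*9 + j, j = (dx+1)*3 + (dy+1),
// dy/dx in {-1,0,1} applied to row/col indices (zero padding).

// x: H x W x Cin -> (H*W) x (9*Cin); contiguous memcpy per column stripe
// [[Rcpp::export]]
arma::mat im2col3_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; c++) {
    const double* xc = x.slice_memptr(c);
    for (int dx = -1; dx <= 1; dx++) {
      for (int dy = -1; dy <= 1; dy++) {
        double* cj = col.colptr(c * 9 + (dx + 1) * 3 + (dy + 1));
        int h0 = (dy < 0) ? 1 : 0;            // first valid output row
        int h1 = (dy > 0) ? H - 1 : H;        // one past last valid
        int len = h1 - h0;
        for (int w = 0; w < W; w++) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          std::memcpy(cj + w * H + h0, xc + ws * H + h0 + dy,
                      len * sizeof(double));
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3_cpp: scatter-add columns back to an H x W x C cube.
// [[Rcpp::export]]
arma::cube col2im3_cpp(const arma::mat& col, int H, int W, int C) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; c++) {
    double* xc = x.slice_memptr(c);
    for (int dx = -1; dx <= 1; dx++) {
      for (int dy = -1; dy <= 1; dy++) {
        const double* cj = col.colptr(c * 9 + (dx + 1) * 3 + (dy + 1));
        int h0 = (dy < 0) ? 1 : 0;
        int h1 = (dy > 0) ? H - 1 : H;
        for (int w = 0; w < W; w++) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          double* dst = xc + ws * H + h0 + dy;
          const double* src = cj + w * H + h0;
          for (int h = h0; h < h1; h++) *dst++ += *src++;
        }
      }
    }
  }
  return x;
}

// Forward conv: returns (H*W) x Cout activation matrix (caller reshapes).
// Wmat: (9*Cin) x Cout, b: Cout.
// [[Rcpp::export]]
arma::mat conv3_forward_cpp(const arma::cube& x, const arma::mat& Wmat,
                            const arma::vec& b) {
  mat col = im2col3_cpp(x);
  mat out = col * Wmat;
  out.each_row() += b.t();
  return out;
}

// Gradient of loss wrt conv input given grad at output (as (H*W) x Cout).
// [[Rcpp::export]]
arma::cube conv3_backward_input_cpp(const arma::mat& gout, const arma::mat& Wmat,
                                    int H, int W, int Cin) {
  mat colgrad = gout * Wmat.t();
  return col2im3_cpp(colgrad, H, W, Cin);
}

// Gradient of loss wrt conv weights.
// [[Rcpp::export]]
arma::mat conv3_backward_weight_cpp(const arma::cube& x, const arma::mat& gout) {
  mat col = im2col3_cpp(x);
  return col.t() * gout;
}
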