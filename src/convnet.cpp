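// 3D convolution layers with circular (periodic) padding, built on
// im2col + BLAS GEMM. 3x3x3 kernels, optional stride for the encoder
// stages of the property predictor. Used by the surrogate models.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cstring>

using namespace arma;

// Column index map: for each output voxel (stride-decimated) and each of the
// 27 neighbour offsets, the linear index of the wrapped input voxel.
static void build_offsets(const Rcpp::IntegerVector& dims, int stride,
                          std::vector<uword>& map, int& nout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / stride, oy = ny / stride, oz = nz / stride;
  nout = ox * oy * oz;
  map.resize((size_t)27 * nout);
  size_t p = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        for (int k = 0; k < oz; ++k) {
          int z = (k * stride + dz + nz) % nz;
          for (int j = 0; j < oy; ++j) {
            int y = (j * stride + dy + ny) % ny;
            for (int i = 0; i < ox; ++i) {
              int x = (i * stride + dx + nx) % nx;
              map[p++] = (uword)x + (uword)nx * ((uword)y + (uword)ny * z);
            }
          }
        }
}

static mat im2col(const mat& x, const std::vector<uword>& map, int nout) {
  const uword cin = x.n_rows;
  mat cols(27 * cin, nout);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  const size_t blk = sizeof(double) * cin;
  for (int n = 0; n < nout; ++n) {
    double* dst = cp + (size_t)n * 27 * cin;
    for (int o = 0; o < 27; ++o) {
      std::memcpy(dst + (size_t)o * cin, xp + map[(size_t)o * nout + n] * cin, blk);
    }
  }
  return cols;
}

// Forward: y = W * im2col(x) + b. x is (C_in x Nvox), W is
// (C_out x 27*C_in) with neighbour-major, channel-minor row layout,
// matching im2col above.
// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const Rcpp::IntegerVector& dims,
                        const arma::mat& W, const arma::vec& b, int stride) {
  std::vector<uword> map;
  int nout;
  build_offsets(dims, stride, map, nout);
  mat cols = im2col(x, map, nout);
  mat y = W * cols;
  y.each_col() += b;
  return y;
}

// Backward: given upstream gradient dy (C_out x Nout), returns
// dW, db and dx (C_in x Nvox). im2col is recomputed from x.
// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat& x, const Rcpp::IntegerVector& dims,
                         const arma::mat& W, const arma::mat& dy, int stride) {
  std::vector<uword> map;
  int nout;
  build_offsets(dims, stride, map, nout);
  mat cols = im2col(x, map, nout);
  mat dW = dy * cols.t();
  vec db = sum(dy, 1);
  mat dcols = W.t() * dy;              // (27*C_in x Nout)
  const uword cin = x.n_rows;
  mat dx(cin, x.n_cols, fill::zeros);
  const double* dp = dcols.memptr();
  double* xp = dx.memptr();
  for (int n = 0; n < nout; ++n) {
    const double* src = dp + (size_t)n * 27 * cin;
    for (int o = 0; o < 27; ++o) {
      double* dst = xp + map[(size_t)o * nout + n] * cin;
      const double* s = src + (size_t)o * cin;
      for (uword c = 0; c < cin; ++c) dst[c] += s[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Nearest-neighbour 2x upsampling of a (C x n_coarse) field to (C x 8*n_coarse).
// [[Rcpp::export]]
arma::mat cpp_upsample2(const arma::mat& x, const Rcpp::IntegerVector& dims_coarse) {
  const int cx = dims_coarse[0], cy = dims_coarse[1], cz = dims_coarse[2];
  const int fx = 2 * cx, fy = 2 * cy;
  const uword C = x.n_rows;
  mat y(C, (uword)8 * x.n_cols);
  const double* xp = x.memptr();
  double* yp = y.memptr();
  for (int z = 0; z < 2 * cz; ++z)
    for (int j = 0; j < fy; ++j)
      for (int i = 0; i < fx; ++i) {
        size_t src = (size_t)(i / 2) + (size_t)cx * ((j / 2) + (size_t)cy * (z / 2));
        size_t dst = (size_t)i + (size_t)fx * (j + (size_t)fy * z);
        std::memcpy(yp + dst * C, xp + src * C, sizeof(double) * C);
      }
  return y;
}

// Adjoint of cpp_upsample2: sums each 2x2x2 block of the fine field.
// [[Rcpp::export]]
arma::mat cpp_downsum2(const arma::mat& dy, const Rcpp::IntegerVector& dims_coarse) {
  const int cx = dims_coarse[0], cy = dims_coarse[1], cz = dims_coarse[2];
  const int fx = 2 * cx, fy = 2 * cy;
  const uword C = dy.n_rows;
  mat dx(C, (uword)cx * cy * cz, fill::zeros);
  const double* yp = dy.memptr();
  double* xp = dx.memptr();
  for (int z = 0; z < 2 * cz; ++z)
    for (int j = 0; j < fy; ++j)
      for (int i = 0; i < fx; ++i) {
        size_t src = (size_t)(i / 2) + (size_t)cx * ((j / 2) + (size_t)cy * (z / 2));
        size_t dst = (size_t)i + (size_t)fx * (j + (size_t)fy * z);
        const double* s = yp + dst * C;
        double* d = xp + src * C;
        for (uword c = 0; c < C; ++c) d[c] += s[c];
      }
  return dx;
}

// Green-operator application for the FFT homogenization scheme.
// tauh: 6 x n complex polarization spectra (rows 11,22,33,23,13,12),
// xi: 3 x n real frequencies, xisq: n (zeros replaced by 1).
// Returns the 6 x n spectral strain correction sym(xi (x) Ghat t).
// [[Rcpp::export]]
arma::cx_mat cpp_green_apply(const arma::cx_mat& tauh, const arma::mat& xi,
                             const arma::vec& xisq, double mu0, double gfac) {
  const uword n = tauh.n_cols;
  arma::cx_mat corr(6, n);
  for (uword k = 0; k < n; ++k) {
    const double x1 = xi(0, k), x2 = xi(1, k), x3 = xi(2, k);
    const std::complex<double> t1 = tauh(0, k) * x1 + tauh(5, k) * x2 + tauh(4, k) * x3;
    const std::complex<double> t2 = tauh(5, k) * x1 + tauh(1, k) * x2 + tauh(3, k) * x3;
    const std::complex<double> t3 = tauh(4, k) * x1 + tauh(3, k) * x2 + tauh(2, k) * x3;
    const double q = xisq(k);
    const std::complex<double> nt = (x1 * t1 + x2 * t2 + x3 * t3) / q;
    const double inv = 1.0 / (mu0 * q);
    const std::complex<double> b1 = (t1 - gfac * x1 * nt) * inv;
    const std::complex<double> b2 = (t2 - gfac * x2 * nt) * inv;
    const std::complex<double> b3 = (t3 - gfac * x3 * nt) * inv;
    corr(0, k) = x1 * b1;
    corr(1, k) = x2 * b2;
    corr(2, k) = x3 * b3;
    corr(3, k) = 0.5 * (x2 * b3 + x3 * b2);
    corr(4, k) = 0.5 * (x1 * b3 + x3 * b1);
    corr(5, k) = 0.5 * (x1 * b2 + x2 * b1);
  }
  return corr;
}

// Equilibrium residual: || xi . sigma-hat ||_2 over all frequencies,
// normalized by the norm of the zero-frequency (mean) stress.
// [[Rcpp::export]]
double cpp_div_residual(const arma::cx_mat& sigh, const arma::mat& xi) {
  const uword n = sigh.n_cols;
  double acc = 0.0, smean = 0.0;
  for (uword r = 0; r < 6; ++r) smean += std::norm(sigh(r, 0));
  for (uword k = 0; k < n; ++k) {
    const double x1 = xi(0, k), x2 = xi(1, k), x3 = xi(2, k);
    const std::complex<double> d1 = sigh(0, k) * x1 + sigh(5, k) * x2 + sigh(4, k) * x3;
    const std::complex<double> d2 = sigh(5, k) * x1 + sigh(1, k) * x2 + sigh(3, k) * x3;
    const std::complex<double> d3 = sigh(4, k) * x1 + sigh(3, k) * x2 + sigh(2, k) * x3;
    acc += std::norm(d1) + std::norm(d2) + std::norm(d3);
  }
  return std::sqrt(acc) / std::max(std::sqrt(smean), 1e-300);
}
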