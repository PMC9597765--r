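// Forward pass of a VGG19-style convolutional stack on a single image.
// 3x3 kernels, zero padding 1 (spatial size preserved within a block),
// ReLU after every convolution, 2x2/stride-2 max pooling after each block.
// Implemented as im2col + GEMM so the heavy lifting goes through BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <set>
using namespace Rcpp;

// Shifted-copy im2col for a 3x3 kernel with zero padding 1.
// x: H x W x C input. Returns (H*W) x (9*C); row index r = i + j*H
// (arma column-major over the spatial grid), column index c*9 + ky*3 + kx
// with ky,kx in 0..2 addressing input offset (ky-1, kx-1).
static arma::mat im2col3x3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat P(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int dy = ky - 1, dx = kx - 1;
        arma::mat view(P.colptr(c * 9 + ky * 3 + kx), H, W, false, true);
        const arma::uword ri0 = dy < 0 ? 1 : 0, ri1 = dy > 0 ? H - 2 : H - 1;
        const arma::uword ci0 = dx < 0 ? 1 : 0, ci1 = dx > 0 ? W - 2 : W - 1;
        view.submat(ri0, ci0, ri1, ci1) =
          s.submat(ri0 + dy, ci0 + dx, ri1 + dy, ci1 + dx);
      }
    }
  }
  return P;
}

static arma::cube maxpool2(const arma::cube& x) {
  const arma::uword H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube y(H, W, C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    arma::mat& t = y.slice(c);
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i)
        t(i, j) = std::max(std::max(s(2 * i, 2 * j), s(2 * i + 1, 2 * j)),
                           std::max(s(2 * i, 2 * j + 1), s(2 * i + 1, 2 * j + 1)));
  }
  return y;
}

static NumericVector cube_to_array(const arma::cube& x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_vgg_forward")]]
List cpp_vgg_forward(NumericVector img, List weights, List biases,
                     IntegerVector pool_after, IntegerVector keep,
                     bool final_pool) {
  IntegerVector d = img.attr("dim");
  arma::cube x(img.begin(), d[0], d[1], d[2]);
  std::set<int> keepset(keep.begin(), keep.end());
  std::set<int> poolset(pool_after.begin(), pool_after.end());
  const int n_keep = keep.size() + (final_pool ? 1 : 0);
  List out(n_keep);
  CharacterVector names(n_keep);
  int slot = 0;
  const int L = weights.size();
  const int deepest = keepset.empty() ? (final_pool ? L : 0)
                                      : std::max(final_pool ? L : 0, *keepset.rbegin());
  for (int l = 1; l <= deepest; ++l) {
    arma::mat Wm = as<arma::mat>(weights[l - 1]);
    arma::vec b = as<arma::vec>(biases[l - 1]);
    arma::mat P = im2col3x3(x);
    arma::mat O = P * Wm;
    O.each_row() += b.t();
    O.transform([](double v) { return v > 0.0 ? v : 0.0; });
    x = arma::cube(O.memptr(), x.n_rows, x.n_cols, Wm.n_cols);
    if (keepset.count(l)) {
      out[slot] = cube_to_array(x);
      names[slot] = "conv" + std::to_string(l);
      ++slot;
    }
    if (poolset.count(l)) x = maxpool2(x);
  }
  if (final_pool) {
    out[slot] = cube_to_array(x);
    names[slot] = "final_pool";
    ++slot;
  }
  out.attr("names") = names;
  return out;
}
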