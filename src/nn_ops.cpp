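// Batched 1-D convolution / pooling primitives for the MT-MSPCNN encoder.
// Data layout: arrays are (channels, length, batch), column-major, viewed
// in place (no copies of the large activations). Convolution weights are
// packed as (out_channels, in_channels * kernel) with row blocks ordered by
// kernel tap first, input channel second (tap ki, channel c -> ki * C + c).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube view_cube(Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static mat im2col(const cube& X, int k, int pad) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lout = L + 2 * pad - k + 1;
  mat Xcol(C * k, (size_t)Lout * B);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lout; ++t) {
      double* col = Xcol.colptr((size_t)b * Lout + t);
      for (int ki = 0; ki < k; ++ki) {
        int src = t + ki - pad;
        if (src < 0 || src >= L)
          std::memset(col + ki * C, 0, C * sizeof(double));
        else
          std::memcpy(col + ki * C, X.slice_colptr(b, src),
                      C * sizeof(double));
      }
    }
  }
  return Xcol;
}

// convolution (stride 1) with optional fused ReLU
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv1d_fw(Rcpp::NumericVector Xs, const arma::mat& W,
                                  const arma::vec& bias, int k, int pad,
                                  bool relu) {
  cube X = view_cube(Xs);
  const int L = X.n_cols, B = X.n_slices;
  const int Lout = L + 2 * pad - k + 1;
  const int Cout = W.n_rows;
  Rcpp::NumericVector out((size_t)Cout * Lout * B);
  out.attr("dim") = Rcpp::Dimension(Cout, Lout, B);
  mat Y(out.begin(), Cout, (size_t)Lout * B, false, true);
  Y = W * im2col(X, k, pad);
  Y.each_col() += bias;
  if (relu) Y.for_each([](double& v) { if (v < 0) v = 0; });
  return out;
}

// gradients of the convolution; dX omitted unless want_dx
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(Rcpp::NumericVector Xs, const arma::mat& W,
                         Rcpp::NumericVector dYs, int k, int pad,
                         bool want_dx) {
  cube X = view_cube(Xs);
  cube dY = view_cube(dYs);
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lout = dY.n_cols;
  mat dYmat(dY.memptr(), dY.n_rows, (size_t)Lout * B, false, true);
  mat Xcol = im2col(X, k, pad);
  mat dW = dYmat * Xcol.t();
  vec db = sum(dYmat, 1);
  Rcpp::NumericVector dXs;
  if (want_dx) {
    mat dXcol = W.t() * dYmat;  // (C*k, Lout*B)
    dXs = Rcpp::NumericVector((size_t)C * L * B);
    dXs.attr("dim") = Rcpp::Dimension(C, L, B);
    cube dX = view_cube(dXs);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < Lout; ++t) {
        const double* col = dXcol.colptr((size_t)b * Lout + t);
        for (int ki = 0; ki < k; ++ki) {
          int src = t + ki - pad;
          if (src < 0 || src >= L) continue;
          double* dcol = dX.slice_colptr(b, src);
          for (int c = 0; c < C; ++c) dcol[c] += col[ki * C + c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dXs);
}

// max pooling with kernel = stride = k; returns pooled values and argmax
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(Rcpp::NumericVector Xs, int k) {
  cube X = view_cube(Xs);
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lp = L / k;
  Rcpp::NumericVector Ys((size_t)C * Lp * B);
  Ys.attr("dim") = Rcpp::Dimension(C, Lp, B);
  Rcpp::IntegerVector idx((size_t)C * Lp * B);
  idx.attr("dim") = Rcpp::Dimension(C, Lp, B);
  cube Y = view_cube(Ys);
  int* ip = idx.begin();
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lp; ++t) {
      double* yc = Y.slice_colptr(b, t);
      for (int c = 0; c < C; ++c) {
        double best = X(c, t * k, b);
        int bi = 0;
        for (int j = 1; j < k; ++j) {
          double v = X(c, t * k + j, b);
          if (v > best) { best = v; bi = j; }
        }
        yc[c] = best;
        ip[((size_t)b * Lp + t) * C + c] = t * k + bi;
      }
    }
  return Rcpp::List::create(Rcpp::Named("Y") = Ys, Rcpp::Named("idx") = idx);
}

// scatter pooled gradients back, zeroing where the pooled activation was
// non-positive (fused ReLU backward for the rectified pre-pool layer)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool_bw(Rcpp::NumericVector dYs,
                                   Rcpp::IntegerVector idx,
                                   Rcpp::NumericVector Ys, int L) {
  cube dY = view_cube(dYs);
  cube Y = view_cube(Ys);
  const int C = dY.n_rows, Lp = dY.n_cols, B = dY.n_slices;
  Rcpp::NumericVector dXs((size_t)C * L * B);
  dXs.attr("dim") = Rcpp::Dimension(C, L, B);
  cube dX = view_cube(dXs);
  const int* ip = idx.begin();
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lp; ++t)
      for (int c = 0; c < C; ++c) {
        if (Y(c, t, b) <= 0) continue;
        dX(c, ip[((size_t)b * Lp + t) * C + c], b) += dY(c, t, b);
      }
  return dXs;
}

// global average pooling over time: (C, Lp, B) -> (C, B)
// [[Rcpp::export]]
arma::mat cpp_gap_fw(Rcpp::NumericVector Ys) {
  cube Y = view_cube(Ys);
  const int C = Y.n_rows, Lp = Y.n_cols, B = Y.n_slices;
  mat z(C, B);
  for (int b = 0; b < B; ++b)
    z.col(b) = sum(Y.slice(b), 1) / Lp;
  return z;
}

// backward of GAP with fused ReLU mask from the rectified activations
// [[Rcpp::export]]
Rcpp::NumericVector cpp_gap_bw(const arma::mat& dz, Rcpp::NumericVector Ys) {
  cube Y = view_cube(Ys);
  const int C = Y.n_rows, Lp = Y.n_cols, B = Y.n_slices;
  Rcpp::NumericVector out((size_t)C * Lp * B);
  out.attr("dim") = Rcpp::Dimension(C, Lp, B);
  cube dY = view_cube(out);
  for (int b = 0; b < B; ++b) {
    const double* dzc = dz.colptr(b);
    for (int t = 0; t < Lp; ++t) {
      double* o = dY.slice_colptr(b, t);
      const double* yc = Y.slice_colptr(b, t);
      for (int c = 0; c < C; ++c)
        o[c] = yc[c] > 0 ? dzc[c] / Lp : 0.0;
    }
  }
  return out;
}
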