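// Convolution, transposed-convolution and max-pooling kernels.
// Tensor layout throughout: column-major R arrays dim = (H, W, C, N).
// Convolutions are stride-1 "same" with odd kernels; pooling is 2x2 stride 2;
// transposed convolution is 3x3 stride 2 (pad 1, output pad 1), i.e. the
// adjoint of a stride-2 3x3 convolution, so spatial size exactly doubles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for one image: x is (H, W, C); returns (H*W) x (k*k*C) with column
// order (dh fastest, then dw, then c) to match reshaping of a (k,k,C,Cout)
// weight array into a (k*k*C, Cout) matrix.
static arma::mat im2col_same(const double* x, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        double* o = out.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (size_t)sw * H;
          double* dst = o + (size_t)w * H;
          int h0 = std::max(0, pad - dh);
          int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dh - pad];
        }
      }
    }
  }
  return out;
}

// scatter-add adjoint of im2col_same
static void col2im_add(const arma::mat& cols, double* x, int H, int W, int C,
                       int k) {
  int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        const double* o = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)sw * H;
          const double* src = o + (size_t)w * H;
          int h0 = std::max(0, pad - dh);
          int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) dst[h + dh - pad] += src[h];
        }
      }
    }
  }
}


static NumericVector arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static IntegerVector iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k || Cin != C) stop("kernel/channel mismatch in conv2d");
  arma::mat wm(w.begin(), k * k * Cin, Cout, false, true);
  NumericVector y = arr4(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat A = im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                true);
    Y = A * wm;
    for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx = dims4(x), dw = w.attr("dim"), dd = dims4(dy);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[3];
  arma::mat wm(w.begin(), k * k * C, Cout, false, true);
  NumericVector gx = arr4(H, W, C, N);
  NumericVector gw = arr4(k, k, C, Cout);
  NumericVector gb(Cout);
  arma::mat gwm(gw.begin(), k * k * C, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat A = im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat DY(dy.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                 true);
    gwm += A.t() * DY;
    gbv += arma::sum(DY, 0).t();
    arma::mat DX = DY * wm.t();
    col2im_add(DX, gx.begin() + (size_t)n * H * W * C, H, W, C, k);
  }
  return List::create(_["dx"] = gx, _["dw"] = gw, _["db"] = gb);
}

// 3x3 stride-2 transposed convolution; w dim (3, 3, Cin, Cout)
// y[2i+a-1, 2j+b-1] += sum_cin x[i,j,cin] * w[a,b,cin,cout]
// [[Rcpp::export(name = ".convt2d_fw")]]
NumericVector convt2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C)
    stop("transposed conv expects a (3,3,Cin,Cout) kernel");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = arr4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)co * Ho * Wo;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)ci * H * W;
        const double* wk = w.begin() + 9 * ((size_t)ci + (size_t)C * co);
        for (int j = 0; j < W; ++j) {
          for (int bb = 0; bb < 3; ++bb) {
            int q = 2 * j + bb - 1;
            if (q < 0 || q >= Wo) continue;
            double* ycol = yc + (size_t)q * Ho;
            const double* xcol = xc + (size_t)j * H;
            for (int aa = 0; aa < 3; ++aa) {
              double wv = wk[aa + 3 * bb];
              if (wv == 0) continue;
              for (int i = 0; i < H; ++i) {
                int p = 2 * i + aa - 1;
                if (p < 0 || p >= Ho) continue;
                ycol[p] += wv * xcol[i];
              }
            }
          }
        }
      }
      if (b[co] != 0) {
        double* yc2 = yn + (size_t)co * Ho * Wo;
        for (int t = 0; t < Ho * Wo; ++t) yc2[t] += b[co];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bw")]]
List convt2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Cout = dw[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = arr4(H, W, C, N);
  NumericVector gw = arr4(3, 3, C, Cout);
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)co * Ho * Wo;
      for (int t = 0; t < Ho * Wo; ++t) gb[co] += dyc[t];
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)ci * H * W;
        double* gxc = gxn + (size_t)ci * H * W;
        const double* wk = w.begin() + 9 * ((size_t)ci + (size_t)C * co);
        double* gwk = gw.begin() + 9 * ((size_t)ci + (size_t)C * co);
        for (int j = 0; j < W; ++j) {
          for (int bb = 0; bb < 3; ++bb) {
            int q = 2 * j + bb - 1;
            if (q < 0 || q >= Wo) continue;
            const double* dycol = dyc + (size_t)q * Ho;
            const double* xcol = xc + (size_t)j * H;
            double* gxcol = gxc + (size_t)j * H;
            for (int aa = 0; aa < 3; ++aa) {
              double wv = wk[aa + 3 * bb];
              double acc = 0.0;
              for (int i = 0; i < H; ++i) {
                int p = 2 * i + aa - 1;
                if (p < 0 || p >= Ho) continue;
                double d = dycol[p];
                gxcol[i] += wv * d;
                acc += xcol[i] * d;
              }
              gwk[aa + 3 * bb] += acc;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = gx, _["dw"] = gw, _["db"] = gb);
}

// 2x2 stride-2 max pooling (floor semantics on odd sizes)
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  IntegerVector dx = dims4(x);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = arr4(Ho, Wo, C, N);
  IntegerVector idx = iarr4(Ho, Wo, C, N);  // linear index into x
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      size_t off = plane * (c + (size_t)C * n);
      size_t oo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int h = 2 * i, w = 2 * j;
          size_t i00 = h + (size_t)H * w, i10 = i00 + 1, i01 = i00 + H,
                 i11 = i01 + 1;
          size_t best = i00;
          if (xc[i10] > xc[best]) best = i10;
          if (xc[i01] > xc[best]) best = i01;
          if (xc[i11] > xc[best]) best = i11;
          y[oo + i + (size_t)Ho * j] = xc[best];
          idx[oo + i + (size_t)Ho * j] = (int)(off + best);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim) {
  NumericVector gx = arr4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t t = 0; t < dy.size(); ++t) gx[idx[t]] += dy[t];
  return gx;
}
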