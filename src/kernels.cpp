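// Dense array kernels for the segmentation networks.
//
// Feature maps are R arrays with dim = (H, W, C, N), column-major, so each
// channel plane of H*W doubles is contiguous.  Convolutions are stride-1 with
// symmetric zero padding (down/up-sampling is done by the pooling / bilinear
// kernels), which is all the architectures here require.  Weights have
// dim = (kh, kw, cin/groups, cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the padded input slice group into the im2col matrix M
// (oH*oW rows, kh*kw*cing columns; column order kh fastest, then kw, then c,
// matching the column-major layout of the weight array).
static void im2col(const double* xs, int H, int W, int cing,
                   int kh, int kw, int ph, int pw,
                   int oH, int oW, arma::mat& P, arma::mat& M) {
  for (int c = 0; c < cing; ++c) {
    P.zeros();
    const double* src = xs + (size_t)c * H * W;
    for (int w = 0; w < W; ++w)
      std::memcpy(P.colptr(w + pw) + ph, src + (size_t)w * H,
                  (size_t)H * sizeof(double));
    for (int kwi = 0; kwi < kw; ++kwi)
      for (int khi = 0; khi < kh; ++khi) {
        int col = khi + kh * (kwi + kw * c);
        M.col(col) = arma::vectorise(
            P.submat(khi, kwi, khi + oH - 1, kwi + oW - 1));
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int ph, int pw, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  if (cing * groups != C) stop("conv2d: input channels do not match weights");
  if (cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  if (oH < 1 || oW < 1) stop("conv2d: kernel larger than padded input");
  const int coutg = cout / groups;

  NumericVector out((R_xlen_t)oH * oW * cout * N);
  out.attr("dim") = IntegerVector::create(oH, oW, cout, N);

  arma::mat P(H + 2 * ph, W + 2 * pw);
  arma::mat M(oH * oW, kh * kw * cing);
  const double* xp = x.begin();
  double* op = out.begin();

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xs = xp + (size_t)H * W * ((size_t)g * cing + (size_t)C * n);
      im2col(xs, H, W, cing, kh, kw, ph, pw, oH, oW, P, M);
      arma::mat Wg(const_cast<double*>(w.begin()) +
                       (size_t)kh * kw * cing * (size_t)g * coutg,
                   kh * kw * cing, coutg, false, true);
      arma::mat O = M * Wg;
      std::memcpy(op + (size_t)oH * oW * ((size_t)g * coutg + (size_t)cout * n),
                  O.memptr(), O.n_elem * sizeof(double));
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double bc = b[c];
        double* o = op + (size_t)oH * oW * (c + (size_t)cout * n);
        for (int i = 0; i < oH * oW; ++i) o[i] += bc;
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int ph, int pw, int groups, bool need_gx, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  const int coutg = cout / groups;

  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gx(need_gx ? (R_xlen_t)x.size() : 0);
  if (need_gx) gx.attr("dim") = x.attr("dim");
  NumericVector gb(has_bias ? cout : 0);

  arma::mat P(H + 2 * ph, W + 2 * pw);
  arma::mat M(oH * oW, kh * kw * cing);
  const double* xp = x.begin();
  const double* gp = gout.begin();

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xs = xp + (size_t)H * W * ((size_t)g * cing + (size_t)C * n);
      im2col(xs, H, W, cing, kh, kw, ph, pw, oH, oW, P, M);
      arma::mat G(const_cast<double*>(gp) +
                      (size_t)oH * oW * ((size_t)g * coutg + (size_t)cout * n),
                  oH * oW, coutg, false, true);
      arma::mat GW(gw.begin() + (size_t)kh * kw * cing * (size_t)g * coutg,
                   kh * kw * cing, coutg, false, true);
      GW += M.t() * G;
      if (need_gx) {
        arma::mat Wg(const_cast<double*>(w.begin()) +
                         (size_t)kh * kw * cing * (size_t)g * coutg,
                     kh * kw * cing, coutg, false, true);
        arma::mat Gcols = G * Wg.t();  // oH*oW x kh*kw*cing
        for (int c = 0; c < cing; ++c) {
          P.zeros();
          for (int kwi = 0; kwi < kw; ++kwi)
            for (int khi = 0; khi < kh; ++khi) {
              int col = khi + kh * (kwi + kw * c);
              P.submat(khi, kwi, khi + oH - 1, kwi + oW - 1) +=
                  arma::reshape(Gcols.col(col), oH, oW);
            }
          double* dst = gx.begin() +
                        (size_t)H * W * ((size_t)g * cing + c + (size_t)C * n);
          for (int w2 = 0; w2 < W; ++w2)
            for (int h2 = 0; h2 < H; ++h2)
              dst[h2 + (size_t)w2 * H] += P(h2 + ph, w2 + pw);
        }
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double* o = gp + (size_t)oH * oW * (c + (size_t)cout * n);
        double s = 0;
        for (int i = 0; i < oH * oW; ++i) s += o[i];
        gb[c] += s;
      }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw,
                      _["gb"] = has_bias ? (SEXP)gb : R_NilValue);
}

// Max pooling with implicit -Inf padding; argmax stores the linear index
// (h + w*H) of the winning input pixel inside its channel plane.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int kh, int kw, int sh, int sw,
                     int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  if (oH < 1 || oW < 1) stop("maxpool: window larger than padded input");

  NumericVector out((R_xlen_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector amx((R_xlen_t)oH * oW * C * N);

  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = xp + cn * H * W;
    double* os = op + cn * oH * oW;
    int* as = ap + cn * oH * oW;
    for (int ow = 0; ow < oW; ++ow)
      for (int oh = 0; oh < oH; ++oh) {
        double best = R_NegInf;
        int bidx = -1;
        for (int kwi = 0; kwi < kw; ++kwi) {
          int w2 = ow * sw - pw + kwi;
          if (w2 < 0 || w2 >= W) continue;
          for (int khi = 0; khi < kh; ++khi) {
            int h2 = oh * sh - ph + khi;
            if (h2 < 0 || h2 >= H) continue;
            double v = xs[h2 + (size_t)w2 * H];
            if (v > best) { best = v; bidx = h2 + w2 * H; }
          }
        }
        os[oh + (size_t)ow * oH] = best;
        as[oh + (size_t)ow * oH] = bidx;
      }
  }
  return List::create(_["out"] = out, _["argmax"] = amx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector argmax,
                              IntegerVector xdim) {
  IntegerVector gd = gout.attr("dim");
  const int oH = gd[0], oW = gd[1], C = gd[2], N = gd[3];
  const int H = xdim[0], W = xdim[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double* gp = gout.begin();
  const int* ap = argmax.begin();
  double* xp = gx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* xs = xp + cn * H * W;
    const double* gs = gp + cn * oH * oW;
    const int* as = ap + cn * oH * oW;
    for (R_xlen_t i = 0; i < (R_xlen_t)oH * oW; ++i) xs[as[i]] += gs[i];
  }
  return gx;
}

// 2x2 stride-2 average pooling (floor semantics: trailing odd row/col dropped).
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = H / 2, oW = W / 2;
  if (oH < 1 || oW < 1) stop("avgpool: input smaller than 2x2");
  NumericVector out((R_xlen_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = xp + cn * H * W;
    double* os = op + cn * oH * oW;
    for (int ow = 0; ow < oW; ++ow)
      for (int oh = 0; oh < oH; ++oh) {
        const double* c0 = xs + (size_t)(2 * ow) * H + 2 * oh;
        const double* c1 = c0 + H;
        os[oh + (size_t)ow * oH] = 0.25 * (c0[0] + c0[1] + c1[0] + c1[1]);
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector gout, IntegerVector xdim) {
  IntegerVector gd = gout.attr("dim");
  const int oH = gd[0], oW = gd[1], C = gd[2], N = gd[3];
  const int H = xdim[0], W = xdim[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* xs = xp + cn * H * W;
    const double* gs = gp + cn * oH * oW;
    for (int ow = 0; ow < oW; ++ow)
      for (int oh = 0; oh < oH; ++oh) {
        const double v = 0.25 * gs[oh + (size_t)ow * oH];
        double* c0 = xs + (size_t)(2 * ow) * H + 2 * oh;
        double* c1 = c0 + H;
        c0[0] += v; c0[1] += v; c1[0] += v; c1[1] += v;
      }
  }
  return gx;
}

struct BilinAxis {
  std::vector<int> i0, i1;
  std::vector<double> f;
};

// Half-pixel (align_corners = FALSE) source coordinates, clamped to the edge.
static BilinAxis bilin_axis(int in, int out) {
  BilinAxis a;
  a.i0.resize(out); a.i1.resize(out); a.f.resize(out);
  const double scale = (double)in / out;
  for (int i = 0; i < out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    a.i0[i] = lo;
    a.i1[i] = std::min(lo + 1, in - 1);
    a.f[i] = src - lo;
  }
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int oH, int oW) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  BilinAxis ah = bilin_axis(H, oH), aw = bilin_axis(W, oW);
  NumericVector out((R_xlen_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = xp + cn * H * W;
    double* os = op + cn * oH * oW;
    for (int ow = 0; ow < oW; ++ow) {
      const double fw = aw.f[ow];
      const double* cA = xs + (size_t)aw.i0[ow] * H;
      const double* cB = xs + (size_t)aw.i1[ow] * H;
      for (int oh = 0; oh < oH; ++oh) {
        const double fh = ah.f[oh];
        const int h0 = ah.i0[oh], h1 = ah.i1[oh];
        os[oh + (size_t)ow * oH] =
            (1 - fh) * (1 - fw) * cA[h0] + fh * (1 - fw) * cA[h1] +
            (1 - fh) * fw * cB[h0] + fh * fw * cB[h1];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gout, int H, int W) {
  IntegerVector gd = gout.attr("dim");
  const int oH = gd[0], oW = gd[1], C = gd[2], N = gd[3];
  BilinAxis ah = bilin_axis(H, oH), aw = bilin_axis(W, oW);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* xs = xp + cn * H * W;
    const double* gs = gp + cn * oH * oW;
    for (int ow = 0; ow < oW; ++ow) {
      const double fw = aw.f[ow];
      double* cA = xs + (size_t)aw.i0[ow] * H;
      double* cB = xs + (size_t)aw.i1[ow] * H;
      for (int oh = 0; oh < oH; ++oh) {
        const double g = gs[oh + (size_t)ow * oH];
        const double fh = ah.f[oh];
        const int h0 = ah.i0[oh], h1 = ah.i1[oh];
        cA[h0] += (1 - fh) * (1 - fw) * g;
        cA[h1] += fh * (1 - fw) * g;
        cB[h0] += (1 - fh) * fw * g;
        cB[h1] += fh * fw * g;
      }
    }
  }
  return gx;
}

// ---- fast paths for depthwise convolutions ----
// groups == C and one input channel per group: direct accumulation avoids
// the per-group im2col/GEMM round trip.

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  NumericVector out((R_xlen_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* ws = wp + (size_t)kh * kw * c;
      double* os = op + (size_t)oH * oW * (c + (size_t)C * n);
      for (int kwi = 0; kwi < kw; ++kwi)
        for (int khi = 0; khi < kh; ++khi) {
          const double wv = ws[khi + kh * kwi];
          if (wv == 0) continue;
          // input offset for output (oh, ow): (oh - ph + khi, ow - pw + kwi)
          int h_lo = std::max(0, ph - khi), h_hi = std::min(oH, H + ph - khi);
          int w_lo = std::max(0, pw - kwi), w_hi = std::min(oW, W + pw - kwi);
          for (int ow = w_lo; ow < w_hi; ++ow) {
            const double* xcol = xs + (size_t)(ow - pw + kwi) * H - ph + khi;
            double* ocol = os + (size_t)ow * oH;
            for (int oh = h_lo; oh < h_hi; ++oh) ocol[oh] += wv * xcol[oh];
          }
        }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int ph, int pw, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gx(need_gx ? (R_xlen_t)x.size() : 0);
  if (need_gx) gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gs = gp + (size_t)oH * oW * (c + (size_t)C * n);
      const double* ws = wp + (size_t)kh * kw * c;
      double* gws = gw.begin() + (size_t)kh * kw * c;
      double* gxs = need_gx ? gx.begin() + (size_t)H * W * (c + (size_t)C * n)
                            : (double*)nullptr;
      for (int kwi = 0; kwi < kw; ++kwi)
        for (int khi = 0; khi < kh; ++khi) {
          int h_lo = std::max(0, ph - khi), h_hi = std::min(oH, H + ph - khi);
          int w_lo = std::max(0, pw - kwi), w_hi = std::min(oW, W + pw - kwi);
          double acc = 0;
          const double wv = ws[khi + kh * kwi];
          for (int ow = w_lo; ow < w_hi; ++ow) {
            const double* xcol = xs + (size_t)(ow - pw + kwi) * H - ph + khi;
            const double* gcol = gs + (size_t)ow * oH;
            if (need_gx) {
              double* gxcol = gxs + (size_t)(ow - pw + kwi) * H - ph + khi;
              for (int oh = h_lo; oh < h_hi; ++oh) {
                acc += gcol[oh] * xcol[oh];
                gxcol[oh] += wv * gcol[oh];
              }
            } else {
              for (int oh = h_lo; oh < h_hi; ++oh) acc += gcol[oh] * xcol[oh];
            }
          }
          gws[khi + kh * kwi] += acc;
        }
    }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw);
}

// ---- per-channel reductions and affine maps (batch norm support) ----

// per-channel sum and sum of squares over (H, W, N)
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector s(C), q(C);
  const double* xp = x.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)HW * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (int i = 0; i < HW; ++i) { a += xs[i]; b += xs[i] * xs[i]; }
      s[c] += a; q[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = q);
}

// per-channel sum only
// [[Rcpp::export]]
NumericVector cpp_channel_sums(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector s(C);
  const double* xp = x.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)HW * (c + (size_t)C * n);
      double a = 0;
      for (int i = 0; i < HW; ++i) a += xs[i];
      s[c] += a;
    }
  return s;
}

// out = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_affine_c(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out((R_xlen_t)x.size());
  out.attr("dim") = xd;
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const double* xs = xp + (size_t)HW * (c + (size_t)C * n);
      double* os = op + (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) os[i] = xs[i] * ac + bc;
    }
  return out;
}

// Training-mode batch-norm backward in one pass:
// dx = istd[c] * gamma[c] * (g - mean_c(g) - xhat * mean_c(g * xhat)),
// with xhat recomputed from x, mu, istd.  Also returns dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector x, NumericVector mu,
                NumericVector istd, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* gp = g.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)HW * (c + (size_t)C * n);
      const double* gs = gp + (size_t)HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = istd[c];
      double a = 0, b = 0;
      for (int i = 0; i < HW; ++i) {
        a += gs[i] * (xs[i] - mc) * ic;
        b += gs[i];
      }
      dgamma[c] += a; dbeta[c] += b;
    }
  NumericVector dx((R_xlen_t)x.size());
  dx.attr("dim") = xd;
  double* dp = dx.begin();
  for (R_xlen_t n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)HW * (c + (size_t)C * n);
      const double* gs = gp + (size_t)HW * (c + (size_t)C * n);
      double* ds = dp + (size_t)HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = istd[c], gc = gamma[c];
      const double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
      for (int i = 0; i < HW; ++i) {
        const double xh = (xs[i] - mc) * ic;
        ds[i] = ic * gc * (gs[i] - t1 - xh * t2);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- broadcast multiplications and axis reductions for the gates ----

// x (H,W,C,N) * yh (H,1,C,N), broadcast over width
// [[Rcpp::export]]
NumericVector cpp_mul_h(NumericVector x, NumericVector yh) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const R_xlen_t CN = (R_xlen_t)xd[2] * xd[3];
  NumericVector out((R_xlen_t)x.size());
  out.attr("dim") = xd;
  const double* xp = x.begin();
  const double* yp = yh.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    const double* ys = yp + cn * H;
    for (int w = 0; w < W; ++w) {
      const double* xs = xp + (cn * W + w) * H;
      double* os = op + (cn * W + w) * H;
      for (int h = 0; h < H; ++h) os[h] = xs[h] * ys[h];
    }
  }
  return out;
}

// sum over width: (H,W,C,N) -> (H,1,C,N)
// [[Rcpp::export]]
NumericVector cpp_sum_w(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const R_xlen_t CN = (R_xlen_t)xd[2] * xd[3];
  NumericVector out(H * CN);
  out.attr("dim") = IntegerVector::create(H, 1, xd[2], xd[3]);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    double* os = op + cn * H;
    for (int w = 0; w < W; ++w) {
      const double* xs = xp + (cn * W + w) * H;
      for (int h = 0; h < H; ++h) os[h] += xs[h];
    }
  }
  return out;
}

// x (H,W,C,N) * yw (W,1,C,N), broadcast over height
// [[Rcpp::export]]
NumericVector cpp_mul_w(NumericVector x, NumericVector yw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const R_xlen_t CN = (R_xlen_t)xd[2] * xd[3];
  NumericVector out((R_xlen_t)x.size());
  out.attr("dim") = xd;
  const double* xp = x.begin();
  const double* yp = yw.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    const double* ys = yp + cn * W;
    for (int w = 0; w < W; ++w) {
      const double yv = ys[w];
      const double* xs = xp + (cn * W + w) * H;
      double* os = op + (cn * W + w) * H;
      for (int h = 0; h < H; ++h) os[h] = xs[h] * yv;
    }
  }
  return out;
}

// sum over height: (H,W,C,N) -> (W,1,C,N)
// [[Rcpp::export]]
NumericVector cpp_sum_h(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const R_xlen_t CN = (R_xlen_t)xd[2] * xd[3];
  NumericVector out(W * CN);
  out.attr("dim") = IntegerVector::create(W, 1, xd[2], xd[3]);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t cn = 0; cn < CN; ++cn) {
    double* os = op + cn * W;
    for (int w = 0; w < W; ++w) {
      const double* xs = xp + (cn * W + w) * H;
      double a = 0;
      for (int h = 0; h < H; ++h) a += xs[h];
      os[w] = a;
    }
  }
  return out;
}

// x (H,W,C,N) * gate (H,W,1,N), broadcast over channels
// [[Rcpp::export]]
NumericVector cpp_mul_c(NumericVector x, NumericVector gate) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out((R_xlen_t)x.size());
  out.attr("dim") = xd;
  const double* xp = x.begin();
  const double* gp = gate.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* gs = gp + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + HW * (c + (R_xlen_t)C * n);
      double* os = op + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) os[i] = xs[i] * gs[i];
    }
  }
  return out;
}

// sum over channels: (H,W,C,N) -> (H,W,1,N)
// [[Rcpp::export]]
NumericVector cpp_sum_c(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(HW * N);
  out.attr("dim") = IntegerVector::create(xd[0], xd[1], 1, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    double* os = op + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) os[i] += xs[i];
    }
  }
  return out;
}

// channel concatenation and its slicing backward
// [[Rcpp::export]]
NumericVector cpp_concat_c(NumericVector a, NumericVector b) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  const R_xlen_t HW = (R_xlen_t)ad[0] * ad[1];
  const int Ca = ad[2], Cb = bd[2], N = ad[3];
  NumericVector out(HW * (Ca + Cb) * N);
  out.attr("dim") = IntegerVector::create(ad[0], ad[1], Ca + Cb, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    std::memcpy(op + HW * ((R_xlen_t)(Ca + Cb) * n), a.begin() + HW * ((R_xlen_t)Ca * n),
                HW * Ca * sizeof(double));
    std::memcpy(op + HW * (Ca + (R_xlen_t)(Ca + Cb) * n), b.begin() + HW * ((R_xlen_t)Cb * n),
                HW * Cb * sizeof(double));
  }
  return out;
}

// channels [from, from+len) of x
// [[Rcpp::export]]
NumericVector cpp_slice_c(NumericVector x, int from, int len) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(HW * len * N);
  out.attr("dim") = IntegerVector::create(xd[0], xd[1], len, N);
  for (int n = 0; n < N; ++n)
    std::memcpy(out.begin() + HW * ((R_xlen_t)len * n),
                x.begin() + HW * (from + (R_xlen_t)C * n),
                HW * len * sizeof(double));
  return out;
}
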