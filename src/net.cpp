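// Dual-head multi-scale patch CNN: forward and backward passes.
//
// Activations are stored as (channels x H*W*batch) matrices; the column index
// is b*H*W + p with p = r + H*c (column-major pixel order, matching R arrays).
// Convolutions are im2col + GEMM; gradients are exact reverse-mode.
//
// Architecture (patch_side = 25, S input channels, widths w1,w2,w3):
//   block 1: conv3x3 same -> conv3x3 same -> maxpool2            25 -> 12
//   block 2: conv3x3 same -> conv3x3 same -> maxpool2, plus an
//            additive skip (1x1 conv + maxpool2) from its input  12 -> 6
//   block 3: conv3x3 valid -> conv3x3 same -> maxpool2, plus an
//            additive skip (1x1 conv + maxpool3/stride3)          6 -> 2
//   flatten (2*2*w3) -> 4 dense (ReLU) -> heads: sigmoid class, linear dist.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::umat;

// im2col for a 3x3 convolution. 'same': zero padding, output H*W per sample.
// 'valid': output (H-2)*(W-2) per sample, output pixel (r,c) centered at
// input (r+1, c+1). Row index of K: k*C + cin with k = (dc+1)*3 + (dr+1),
// so each (neighbor, pixel) pair is one contiguous channel block.
static mat im2col3(const mat& A, int H, int W, int B, bool same) {
  const int C = A.n_rows;
  const int Ho = same ? H : H - 2, Wo = same ? W : W - 2;
  mat K(C * 9, (size_t)Ho * Wo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t icol0 = (size_t)b * H * W, ocol0 = (size_t)b * Ho * Wo;
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        const size_t ocol = ocol0 + r + (size_t)Ho * c;
        double* Kp = K.colptr(ocol);
        const int rc = same ? r : r + 1, cc = same ? c : c + 1;
        for (int dc = -1; dc <= 1; ++dc) {
          const int nc = cc + dc;
          if (nc < 0 || nc >= W) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = rc + dr;
            if (nr < 0 || nr >= H) continue;
            const int k = (dc + 1) * 3 + (dr + 1);
            const double* Ap = A.colptr(icol0 + nr + (size_t)H * nc);
            std::copy(Ap, Ap + C, Kp + (size_t)k * C);
          }
        }
      }
  }
  return K;
}

// reverse of im2col3: accumulate dK into dA
static mat col2im3(const mat& dK, int C, int H, int W, int B, bool same) {
  const int Ho = same ? H : H - 2, Wo = same ? W : W - 2;
  mat dA(C, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t icol0 = (size_t)b * H * W, ocol0 = (size_t)b * Ho * Wo;
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        const size_t ocol = ocol0 + r + (size_t)Ho * c;
        const double* Kp = dK.colptr(ocol);
        const int rc = same ? r : r + 1, cc = same ? c : c + 1;
        for (int dc = -1; dc <= 1; ++dc) {
          const int nc = cc + dc;
          if (nc < 0 || nc >= W) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = rc + dr;
            if (nr < 0 || nr >= H) continue;
            const int k = (dc + 1) * 3 + (dr + 1);
            double* Ap = dA.colptr(icol0 + nr + (size_t)H * nc);
            const double* src = Kp + (size_t)k * C;
            for (int ch = 0; ch < C; ++ch) Ap[ch] += src[ch];
          }
        }
      }
  }
  return dA;
}

// max pooling window x window, stride = window, floor semantics
static void maxpool(const mat& A, int H, int W, int B, int win,
                    mat& out, umat& argcol) {
  const int C = A.n_rows;
  const int Ho = H / win, Wo = W / win;
  out.set_size(C, (size_t)Ho * Wo * B);
  argcol.set_size(C, (size_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b) {
    const size_t icol0 = (size_t)b * H * W, ocol0 = (size_t)b * Ho * Wo;
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        const size_t ocol = ocol0 + r + (size_t)Ho * c;
        double* op = out.colptr(ocol);
        arma::uword* gp = argcol.colptr(ocol);
        bool first = true;
        for (int dc = 0; dc < win; ++dc)
          for (int dr = 0; dr < win; ++dr) {
            const size_t icol =
                icol0 + (r * win + dr) + (size_t)H * (c * win + dc);
            const double* Ap = A.colptr(icol);
            if (first) {
              for (int ch = 0; ch < C; ++ch) { op[ch] = Ap[ch]; gp[ch] = icol; }
              first = false;
            } else {
              for (int ch = 0; ch < C; ++ch)
                if (Ap[ch] > op[ch]) { op[ch] = Ap[ch]; gp[ch] = icol; }
            }
          }
      }
  }
}

static mat maxpool_bwd(const mat& dOut, const umat& argcol, int C,
                       size_t incols) {
  mat dA(C, incols, arma::fill::zeros);
  for (size_t j = 0; j < dOut.n_cols; ++j)
    for (int ch = 0; ch < C; ++ch)
      dA(ch, argcol(ch, j)) += dOut(ch, j);
  return dA;
}

static inline mat getW(const List& L, const char* nm) {
  return as<mat>(L[nm]);
}
static inline vec getb(const List& L, const char* nm) {
  return as<vec>(L[nm]);
}

// Forward (and optionally backward) pass over a batch.
// X: (patch_side^2 * S) x B matrix, column-major (r, c, channel) per column.
// Returns class probabilities, raw distance outputs, the two loss terms
// (means over the batch), and, if backward, gradients for every weight.
// [[Rcpp::export]]
List cpp_net_pass(List Wts, const arma::mat& X, int patch_side, int S,
                  int w1, int w2, int w3,
                  const arma::rowvec& y_class, const arma::rowvec& y_dist,
                  bool backward) {
  const int P = patch_side;
  const int HW = P * P;
  if ((int)X.n_rows != HW * S) stop("input rows do not match patch_side^2 * S");
  const int B = X.n_cols;
  if (B < 1) stop("empty batch");
  const int h1 = P / 2;            // after pool 1
  const int h2 = h1 / 2;           // after pool 2
  const int h3 = h2 - 2;           // after valid conv
  const int h4 = h3 / 2;           // after pool 3
  if (h3 < 1) stop("patch_side too small: block 3 valid convolution underflows");
  if (h2 % 3 != 0 || h2 / 3 != h4)
    stop("patch_side incompatible with block-3 skip pooling");

  // input channels-first layout
  mat A0(S, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    for (int s = 0; s < S; ++s)
      for (int p = 0; p < HW; ++p)
        A0(s, (size_t)b * HW + p) = X(p + (size_t)HW * s, b);

  const mat c1a_W = getW(Wts, "c1a_W"); const vec c1a_b = getb(Wts, "c1a_b");
  const mat c1b_W = getW(Wts, "c1b_W"); const vec c1b_b = getb(Wts, "c1b_b");
  const mat c2a_W = getW(Wts, "c2a_W"); const vec c2a_b = getb(Wts, "c2a_b");
  const mat c2b_W = getW(Wts, "c2b_W"); const vec c2b_b = getb(Wts, "c2b_b");
  const mat s2_W  = getW(Wts, "s2_W");  const vec s2_b  = getb(Wts, "s2_b");
  const mat c3a_W = getW(Wts, "c3a_W"); const vec c3a_b = getb(Wts, "c3a_b");
  const mat c3b_W = getW(Wts, "c3b_W"); const vec c3b_b = getb(Wts, "c3b_b");
  const mat s3_W  = getW(Wts, "s3_W");  const vec s3_b  = getb(Wts, "s3_b");
  const mat d1_W = getW(Wts, "d1_W"); const vec d1_b = getb(Wts, "d1_b");
  const mat d2_W = getW(Wts, "d2_W"); const vec d2_b = getb(Wts, "d2_b");
  const mat d3_W = getW(Wts, "d3_W"); const vec d3_b = getb(Wts, "d3_b");
  const mat d4_W = getW(Wts, "d4_W"); const vec d4_b = getb(Wts, "d4_b");
  const mat hc_W = getW(Wts, "hc_W"); const vec hc_b = getb(Wts, "hc_b");
  const mat hd_W = getW(Wts, "hd_W"); const vec hd_b = getb(Wts, "hd_b");

  // ---- block 1 (25 -> 12)
  mat K1 = im2col3(A0, P, P, B, true);
  mat A1 = c1a_W * K1; A1.each_col() += c1a_b; A1.transform([](double v){ return v > 0 ? v : 0.0; });
  mat K2 = im2col3(A1, P, P, B, true);
  mat A2 = c1b_W * K2; A2.each_col() += c1b_b; A2.transform([](double v){ return v > 0 ? v : 0.0; });
  mat P1; umat i1; maxpool(A2, P, P, B, 2, P1, i1);

  // ---- block 2 (12 -> 6), skip from P1
  mat K3 = im2col3(P1, h1, h1, B, true);
  mat A3 = c2a_W * K3; A3.each_col() += c2a_b; A3.transform([](double v){ return v > 0 ? v : 0.0; });
  mat K4 = im2col3(A3, h1, h1, B, true);
  mat A4 = c2b_W * K4; A4.each_col() += c2b_b; A4.transform([](double v){ return v > 0 ? v : 0.0; });
  mat P2; umat i2; maxpool(A4, h1, h1, B, 2, P2, i2);
  mat S2 = s2_W * P1; S2.each_col() += s2_b;
  mat PS2; umat is2; maxpool(S2, h1, h1, B, 2, PS2, is2);
  mat B2 = P2 + PS2;

  // ---- block 3 (6 -> 2), skip from B2
  mat K5 = im2col3(B2, h2, h2, B, false); // valid: 6 -> 4
  mat A5 = c3a_W * K5; A5.each_col() += c3a_b; A5.transform([](double v){ return v > 0 ? v : 0.0; });
  mat K6 = im2col3(A5, h3, h3, B, true);
  mat A6 = c3b_W * K6; A6.each_col() += c3b_b; A6.transform([](double v){ return v > 0 ? v : 0.0; });
  mat P3; umat i3; maxpool(A6, h3, h3, B, 2, P3, i3);
  mat S3 = s3_W * B2; S3.each_col() += s3_b;
  mat PS3; umat is3; maxpool(S3, h2, h2, B, 3, PS3, is3);
  mat B3 = P3 + PS3;

  // ---- flatten: F(ch + C*p, b) = B3(ch, b*npix + p)
  const int npix = h4 * h4;
  const int nflat = w3 * npix;
  if ((int)d1_W.n_cols != nflat) stop("dense input width does not match flatten size");
  mat F(nflat, B);
  for (int b = 0; b < B; ++b)
    std::copy(B3.colptr((size_t)b * npix),
              B3.colptr((size_t)b * npix) + nflat, F.colptr(b));

  // ---- dense stack + heads
  mat D1 = d1_W * F;  D1.each_col() += d1_b; D1.transform([](double v){ return v > 0 ? v : 0.0; });
  mat D2 = d2_W * D1; D2.each_col() += d2_b; D2.transform([](double v){ return v > 0 ? v : 0.0; });
  mat D3 = d3_W * D2; D3.each_col() += d3_b; D3.transform([](double v){ return v > 0 ? v : 0.0; });
  mat D4 = d4_W * D3; D4.each_col() += d4_b; D4.transform([](double v){ return v > 0 ? v : 0.0; });
  rowvec zc = hc_W * D4 + hc_b(0) * rowvec(B, arma::fill::ones);
  rowvec zd = hd_W * D4 + hd_b(0) * rowvec(B, arma::fill::ones);
  rowvec prob = 1.0 / (1.0 + arma::exp(-zc));

  double bce = NA_REAL, mae = NA_REAL;
  const bool have_y = ((int)y_class.n_elem == B) && ((int)y_dist.n_elem == B);
  if (have_y) {
    rowvec pc = arma::clamp(prob, 1e-7, 1.0 - 1e-7);
    bce = arma::mean(-y_class % arma::log(pc) -
                     (1.0 - y_class) % arma::log(1.0 - pc));
    mae = arma::mean(arma::abs(zd - y_dist));
  }

  List out = List::create(_["prob"] = prob, _["dist"] = zd,
                          _["bce"] = bce, _["mae"] = mae);
  if (!backward) return out;
  if (!have_y) stop("labels required for the backward pass");

  // ---- backward
  rowvec dzc = (prob - y_class) / B;
  rowvec dzd = arma::sign(zd - y_dist) / B;

  mat g_hc_W = dzc * D4.t(); vec g_hc_b(1); g_hc_b(0) = arma::accu(dzc);
  mat g_hd_W = dzd * D4.t(); vec g_hd_b(1); g_hd_b(0) = arma::accu(dzd);
  mat dD4 = hc_W.t() * dzc + hd_W.t() * dzd;
  dD4 %= arma::conv_to<mat>::from(D4 > 0);
  mat g_d4_W = dD4 * D3.t(); vec g_d4_b = arma::sum(dD4, 1);
  mat dD3 = d4_W.t() * dD4; dD3 %= arma::conv_to<mat>::from(D3 > 0);
  mat g_d3_W = dD3 * D2.t(); vec g_d3_b = arma::sum(dD3, 1);
  mat dD2 = d3_W.t() * dD3; dD2 %= arma::conv_to<mat>::from(D2 > 0);
  mat g_d2_W = dD2 * D1.t(); vec g_d2_b = arma::sum(dD2, 1);
  mat dD1 = d2_W.t() * dD2; dD1 %= arma::conv_to<mat>::from(D1 > 0);
  mat g_d1_W = dD1 * F.t(); vec g_d1_b = arma::sum(dD1, 1);
  mat dF = d1_W.t() * dD1;

  // unflatten
  mat dB3(w3, (size_t)npix * B);
  for (int b = 0; b < B; ++b)
    std::copy(dF.colptr(b), dF.colptr(b) + nflat,
              dB3.colptr((size_t)b * npix));

  // block 3 backward
  mat dS3 = maxpool_bwd(dB3, is3, w3, S3.n_cols);
  mat g_s3_W = dS3 * B2.t(); vec g_s3_b = arma::sum(dS3, 1);
  mat dB2 = s3_W.t() * dS3;
  mat dA6 = maxpool_bwd(dB3, i3, w3, A6.n_cols);
  dA6 %= arma::conv_to<mat>::from(A6 > 0);
  mat g_c3b_W = dA6 * K6.t(); vec g_c3b_b = arma::sum(dA6, 1);
  mat dA5 = col2im3(c3b_W.t() * dA6, w3, h3, h3, B, true);
  dA5 %= arma::conv_to<mat>::from(A5 > 0);
  mat g_c3a_W = dA5 * K5.t(); vec g_c3a_b = arma::sum(dA5, 1);
  dB2 += col2im3(c3a_W.t() * dA5, w2, h2, h2, B, false);

  // block 2 backward
  mat dS2 = maxpool_bwd(dB2, is2, w2, S2.n_cols);
  mat g_s2_W = dS2 * P1.t(); vec g_s2_b = arma::sum(dS2, 1);
  mat dP1 = s2_W.t() * dS2;
  mat dA4 = maxpool_bwd(dB2, i2, w2, A4.n_cols);
  dA4 %= arma::conv_to<mat>::from(A4 > 0);
  mat g_c2b_W = dA4 * K4.t(); vec g_c2b_b = arma::sum(dA4, 1);
  mat dA3 = col2im3(c2b_W.t() * dA4, w2, h1, h1, B, true);
  dA3 %= arma::conv_to<mat>::from(A3 > 0);
  mat g_c2a_W = dA3 * K3.t(); vec g_c2a_b = arma::sum(dA3, 1);
  dP1 += col2im3(c2a_W.t() * dA3, w1, h1, h1, B, true);

  // block 1 backward
  mat dA2 = maxpool_bwd(dP1, i1, w1, A2.n_cols);
  dA2 %= arma::conv_to<mat>::from(A2 > 0);
  mat g_c1b_W = dA2 * K2.t(); vec g_c1b_b = arma::sum(dA2, 1);
  mat dA1 = col2im3(c1b_W.t() * dA2, w1, P, P, B, true);
  dA1 %= arma::conv_to<mat>::from(A1 > 0);
  mat g_c1a_W = dA1 * K1.t(); vec g_c1a_b = arma::sum(dA1, 1);

  List g(30);
  CharacterVector nm(30);
  int i = 0;
  auto put = [&](const char* name, SEXP val) { nm[i] = name; g[i] = val; ++i; };
  put("c1a_W", wrap(g_c1a_W)); put("c1a_b", wrap(g_c1a_b));
  put("c1b_W", wrap(g_c1b_W)); put("c1b_b", wrap(g_c1b_b));
  put("c2a_W", wrap(g_c2a_W)); put("c2a_b", wrap(g_c2a_b));
  put("c2b_W", wrap(g_c2b_W)); put("c2b_b", wrap(g_c2b_b));
  put("s2_W", wrap(g_s2_W));   put("s2_b", wrap(g_s2_b));
  put("c3a_W", wrap(g_c3a_W)); put("c3a_b", wrap(g_c3a_b));
  put("c3b_W", wrap(g_c3b_W)); put("c3b_b", wrap(g_c3b_b));
  put("s3_W", wrap(g_s3_W));   put("s3_b", wrap(g_s3_b));
  put("d1_W", wrap(g_d1_W));   put("d1_b", wrap(g_d1_b));
  put("d2_W", wrap(g_d2_W));   put("d2_b", wrap(g_d2_b));
  put("d3_W", wrap(g_d3_W));   put("d3_b", wrap(g_d3_b));
  put("d4_W", wrap(g_d4_W));   put("d4_b", wrap(g_d4_b));
  put("hc_W", wrap(g_hc_W));   put("hc_b", wrap(g_hc_b));
  put("hd_W", wrap(g_hd_W));   put("hd_b", wrap(g_hd_b));
  g.attr("names") = nm;
  out["grads"] = g;
  return out;
}
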