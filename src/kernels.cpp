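#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are (P x C) matrices; row r (0-based) encodes the
// position (n, t, h, w) as r = ((n*T + t)*H + h)*W + w.  Channels are
// columns so that per-channel operations (batch norm, GEMM) vectorize.

static inline int out_len(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Unfold a batched 3D volume into the convolution matrix: one row per
// output position, one column per (channel, kt, kh, kw) kernel tap.
// Out-of-range taps read zero (zero padding).
// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericMatrix x, int N, int T, int H, int W,
                       int kt, int kh, int kw,
                       int st, int sh, int sw,
                       int pt, int ph, int pw) {
  const int C = x.ncol();
  const int To = out_len(T, kt, st, pt);
  const int Ho = out_len(H, kh, sh, ph);
  const int Wo = out_len(W, kw, sw, pw);
  const int P = N * To * Ho * Wo;
  const int K = C * kt * kh * kw;
  NumericMatrix col(P, K);
  const double *xp = x.begin();
  double *cp = col.begin();
  const int Pin = x.nrow();

  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * Pin;
    for (int dt = 0; dt < kt; ++dt)
      for (int dh = 0; dh < kh; ++dh)
        for (int dw = 0; dw < kw; ++dw) {
          const int k = ((c * kt + dt) * kh + dh) * kw + dw;
          double *ck = cp + (R_xlen_t)k * P;
          for (int n = 0; n < N; ++n)
            for (int to = 0; to < To; ++to) {
              const int ti = to * st - pt + dt;
              const bool tok = (ti >= 0 && ti < T);
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * sh - ph + dh;
                const bool hok = tok && (hi >= 0 && hi < H);
                const R_xlen_t rbase = (((R_xlen_t)n * To + to) * Ho + ho) * Wo;
                const R_xlen_t ibase = (((R_xlen_t)n * T + ti) * H + hi) * W;
                for (int wo = 0; wo < Wo; ++wo) {
                  const int wi = wo * sw - pw + dw;
                  if (hok && wi >= 0 && wi < W)
                    ck[rbase + wo] = xc[ibase + wi];
                }
              }
            }
        }
  }
  return col;
}

// Scatter-add the gradient of the convolution matrix back onto the input
// layout (adjoint of im2col3d).
// [[Rcpp::export(name = ".col2im3d")]]
NumericMatrix col2im3d(NumericMatrix dcol, int C, int N, int T, int H, int W,
                       int kt, int kh, int kw,
                       int st, int sh, int sw,
                       int pt, int ph, int pw) {
  const int To = out_len(T, kt, st, pt);
  const int Ho = out_len(H, kh, sh, ph);
  const int Wo = out_len(W, kw, sw, pw);
  const int P = N * To * Ho * Wo;
  const int Pin = N * T * H * W;
  NumericMatrix dx(Pin, C);
  const double *cp = dcol.begin();
  double *xp = dx.begin();

  for (int c = 0; c < C; ++c) {
    double *xc = xp + (R_xlen_t)c * Pin;
    for (int dt = 0; dt < kt; ++dt)
      for (int dh = 0; dh < kh; ++dh)
        for (int dw = 0; dw < kw; ++dw) {
          const int k = ((c * kt + dt) * kh + dh) * kw + dw;
          const double *ck = cp + (R_xlen_t)k * P;
          for (int n = 0; n < N; ++n)
            for (int to = 0; to < To; ++to) {
              const int ti = to * st - pt + dt;
              if (ti < 0 || ti >= T) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * sh - ph + dh;
                if (hi < 0 || hi >= H) continue;
                const R_xlen_t rbase = (((R_xlen_t)n * To + to) * Ho + ho) * Wo;
                const R_xlen_t ibase = (((R_xlen_t)n * T + ti) * H + hi) * W;
                for (int wo = 0; wo < Wo; ++wo) {
                  const int wi = wo * sw - pw + dw;
                  if (wi >= 0 && wi < W)
                    xc[ibase + wi] += ck[rbase + wo];
                }
              }
            }
        }
  }
  return dx;
}

// Max pooling over (t, h, w) windows; returns pooled values and the
// 1-based flat row index of each window maximum for the backward pass.
// [[Rcpp::export(name = ".maxpool3d")]]
List maxpool3d(NumericMatrix x, int N, int T, int H, int W,
               int kt, int kh, int kw,
               int st, int sh, int sw,
               int pt, int ph, int pw) {
  const int C = x.ncol();
  const int To = out_len(T, kt, st, pt);
  const int Ho = out_len(H, kh, sh, ph);
  const int Wo = out_len(W, kw, sw, pw);
  const int P = N * To * Ho * Wo;
  NumericMatrix y(P, C);
  IntegerMatrix amax(P, C);
  const int Pin = x.nrow();
  const double *xp = x.begin();

  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * Pin;
    for (int n = 0; n < N; ++n)
      for (int to = 0; to < To; ++to)
        for (int ho = 0; ho < Ho; ++ho)
          for (int wo = 0; wo < Wo; ++wo) {
            double best = R_NegInf;
            R_xlen_t besti = -1;
            for (int dt = 0; dt < kt; ++dt) {
              const int ti = to * st - pt + dt;
              if (ti < 0 || ti >= T) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hi = ho * sh - ph + dh;
                if (hi < 0 || hi >= H) continue;
                for (int dw = 0; dw < kw; ++dw) {
                  const int wi = wo * sw - pw + dw;
                  if (wi < 0 || wi >= W) continue;
                  const R_xlen_t i = (((R_xlen_t)n * T + ti) * H + hi) * W + wi;
                  if (xc[i] > best) { best = xc[i]; besti = i; }
                }
              }
            }
            const R_xlen_t r = (((R_xlen_t)n * To + to) * Ho + ho) * Wo + wo;
            y(r, c) = best;
            amax(r, c) = (int)(besti + 1);
          }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericMatrix maxpool3d_backward(NumericMatrix dy, IntegerMatrix amax,
                                 int Pin) {
  const int C = dy.ncol();
  const int P = dy.nrow();
  NumericMatrix dx(Pin, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < P; ++r)
      dx(amax(r, c) - 1, c) += dy(r, c);
  return dx;
}
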