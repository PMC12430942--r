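#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution with odd kernel size k, stride 1, "same" padding.
// Arrays are channel-major, column-major as in R: x has dim (Cin, D, H, W),
// weights have dim (Cout, Cin, k, k, k), output has dim (Cout, D, H, W).
// pad_mode: 0 = zero padding, 1 = edge replication.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector b, int pad_mode) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], k = wdim[2], r = (k - 1) / 2;
  if (wdim[1] != Cin) stop("weight/input channel mismatch");
  NumericVector y(static_cast<R_xlen_t>(Cout) * D * H * W);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();

  for (int iw = 0; iw < W; ++iw) {
    for (int ih = 0; ih < H; ++ih) {
      for (int id = 0; id < D; ++id) {
        const R_xlen_t oybase = (R_xlen_t)Cout * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * iw));
        for (int co = 0; co < Cout; ++co) py[oybase + co] = pb[co];
        for (int kw = -r; kw <= r; ++kw) {
          int sw = iw + kw;
          if (pad_mode == 1) sw = clampi(sw, 0, W - 1);
          else if (sw < 0 || sw >= W) continue;
          for (int kh = -r; kh <= r; ++kh) {
            int sh = ih + kh;
            if (pad_mode == 1) sh = clampi(sh, 0, H - 1);
            else if (sh < 0 || sh >= H) continue;
            for (int kd = -r; kd <= r; ++kd) {
              int sd = id + kd;
              if (pad_mode == 1) sd = clampi(sd, 0, D - 1);
              else if (sd < 0 || sd >= D) continue;
              const R_xlen_t xbase = (R_xlen_t)Cin * (sd + (R_xlen_t)D * (sh + (R_xlen_t)H * sw));
              const R_xlen_t wbase = (R_xlen_t)Cout * Cin *
                ((kd + r) + (R_xlen_t)k * ((kh + r) + (R_xlen_t)k * (kw + r)));
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = px[xbase + ci];
                const double *pwc = pw + wbase + (R_xlen_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) py[oybase + co] += pwc[co] * xv;
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, D, H, W);
  return y;
}

// Backward pass: given grad wrt output, return grads wrt input, weights, bias.
// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gy, int pad_mode) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], k = wdim[2], r = (k - 1) / 2;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int iw = 0; iw < W; ++iw) {
    for (int ih = 0; ih < H; ++ih) {
      for (int id = 0; id < D; ++id) {
        const R_xlen_t oybase = (R_xlen_t)Cout * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * iw));
        for (int co = 0; co < Cout; ++co) pgb[co] += pgy[oybase + co];
        for (int kw = -r; kw <= r; ++kw) {
          int sw = iw + kw;
          if (pad_mode == 1) sw = clampi(sw, 0, W - 1);
          else if (sw < 0 || sw >= W) continue;
          for (int kh = -r; kh <= r; ++kh) {
            int sh = ih + kh;
            if (pad_mode == 1) sh = clampi(sh, 0, H - 1);
            else if (sh < 0 || sh >= H) continue;
            for (int kd = -r; kd <= r; ++kd) {
              int sd = id + kd;
              if (pad_mode == 1) sd = clampi(sd, 0, D - 1);
              else if (sd < 0 || sd >= D) continue;
              const R_xlen_t xbase = (R_xlen_t)Cin * (sd + (R_xlen_t)D * (sh + (R_xlen_t)H * sw));
              const R_xlen_t wbase = (R_xlen_t)Cout * Cin *
                ((kd + r) + (R_xlen_t)k * ((kh + r) + (R_xlen_t)k * (kw + r)));
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = px[xbase + ci];
                const R_xlen_t wci = wbase + (R_xlen_t)Cout * ci;
                double acc = 0.0;
                for (int co = 0; co < Cout; ++co) {
                  const double g = pgy[oybase + co];
                  pgw[wci + co] += g * xv;
                  acc += pw[wci + co] * g;
                }
                pgx[xbase + ci] += acc;
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
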