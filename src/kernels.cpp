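// Low-level network kernels: 2-D convolution (stride 1, zero padding),
// 2x2 max pooling, bilinear interpolation, and the spatial histogram layer.
// Layout convention matches R arrays: cube(H, W, C); convolution weights
// arrive flattened to a (kh*kw*cin) x cout matrix in R's column-major order
// (dy fastest, then dx, then cin).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col for stride-1 zero-padded convolution: row per output pixel
// (column-major over (r, c)), column j = dy + kh*dx + kh*kw*ci. Each column
// of the result, reshaped H x W, is the input slice shifted by (dy-pad,
// dx-pad) with a zero border, so it is filled with block copies.
static arma::mat im2col(const arma::cube& x, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, kh * kw * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& xs = x.slice(ci);
    for (int dx = 0; dx < kw; ++dx) {
      const int oc = dx - pad;
      const int c0 = std::max(0, -oc), c1 = std::min(W - 1, W - 1 - oc);
      for (int dy = 0; dy < kh; ++dy) {
        const int orr = dy - pad;
        const int r0 = std::max(0, -orr), r1 = std::min(H - 1, H - 1 - orr);
        if (r0 > r1 || c0 > c1) continue;
        const int j = dy + kh * dx + kh * kw * ci;
        arma::mat view(out.colptr(j), H, W, false, true);
        view.submat(r0, c0, r1, c1) =
          xs.submat(r0 + orr, c0 + oc, r1 + orr, c1 + oc);
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col
static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int kh, int kw, int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& xs = x.slice(ci);
    for (int dx = 0; dx < kw; ++dx) {
      const int oc = dx - pad;
      const int c0 = std::max(0, -oc), c1 = std::min(W - 1, W - 1 - oc);
      for (int dy = 0; dy < kh; ++dy) {
        const int orr = dy - pad;
        const int r0 = std::max(0, -orr), r1 = std::min(H - 1, H - 1 - orr);
        if (r0 > r1 || c0 > c1) continue;
        const int j = dy + kh * dx + kh * kw * ci;
        const arma::mat view(const_cast<double*>(cols.colptr(j)), H, W,
                             false, true);
        xs.submat(r0 + orr, c0 + oc, r1 + orr, c1 + oc) +=
          view.submat(r0, c0, r1, c1);
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& wmat,
                          const arma::vec& bias, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = wmat.n_cols;
  arma::mat cols = im2col(x, kh, kw, pad);
  arma::mat o = cols * wmat;               // (H*W) x cout
  o.each_row() += bias.t();
  arma::cube out(o.memptr(), H, W, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& wmat,
                    const arma::cube& gout, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int cout = wmat.n_cols;
  arma::mat gom(const_cast<double*>(gout.memptr()), H * W, cout, false);
  arma::mat cols = im2col(x, kh, kw, pad);
  arma::mat gw = cols.t() * gom;           // (kh*kw*cin) x cout
  arma::vec gb = arma::sum(gom, 0).t();
  arma::mat gcols = gom * wmat.t();
  arma::cube gx = col2im(gcols, H, W, C, kh, kw, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);              // linear index within slice
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& xs = x.slice(ci);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc = 2 * c + dc;
            const double v = xs(rr, cc);
            if (v > best) { best = v; bi = rr + H * cc; }
          }
        }
        out(r, c, ci) = best;
        idx(r, c, ci) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gout,
                            int H, int W) {
  const int C = gout.n_slices, Ho = gout.n_rows, Wo = gout.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& gs = gx.slice(ci);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        gs(idx(r, c, ci)) += gout(r, c, ci);
  }
  return gx;
}

struct BilinWt { int i0, i1; double w0, w1; };

static std::vector<BilinWt> bilin_axis(int n_in, int n_out) {
  // half-pixel-centre mapping (align_corners = FALSE)
  std::vector<BilinWt> w(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = clampi(i0 + 1, 0, n_in - 1);
    double f = s - i0;
    w[i] = {i0, i1, 1.0 - f, f};
  }
  return w;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_fwd(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<BilinWt> wr = bilin_axis(H, oh), wc = bilin_axis(W, ow);
  arma::cube out(oh, ow, C);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& xs = x.slice(ci);
    for (int c = 0; c < ow; ++c) {
      const BilinWt& bc = wc[c];
      for (int r = 0; r < oh; ++r) {
        const BilinWt& br = wr[r];
        out(r, c, ci) =
          br.w0 * (bc.w0 * xs(br.i0, bc.i0) + bc.w1 * xs(br.i0, bc.i1)) +
          br.w1 * (bc.w0 * xs(br.i1, bc.i0) + bc.w1 * xs(br.i1, bc.i1));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_bwd(const arma::cube& gout, int ih, int iw) {
  const int oh = gout.n_rows, ow = gout.n_cols, C = gout.n_slices;
  std::vector<BilinWt> wr = bilin_axis(ih, oh), wc = bilin_axis(iw, ow);
  arma::cube gx(ih, iw, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& gs = gx.slice(ci);
    for (int c = 0; c < ow; ++c) {
      const BilinWt& bc = wc[c];
      for (int r = 0; r < oh; ++r) {
        const BilinWt& br = wr[r];
        const double g = gout(r, c, ci);
        gs(br.i0, bc.i0) += br.w0 * bc.w0 * g;
        gs(br.i0, bc.i1) += br.w0 * bc.w1 * g;
        gs(br.i1, bc.i0) += br.w1 * bc.w0 * g;
        gs(br.i1, bc.i1) += br.w1 * bc.w1 * g;
      }
    }
  }
  return gx;
}

// Spatial histogram layer. Radial-basis bin response
//   phi_bk(x) = exp(-gamma_bk^2 (x - mu_bk)^2)
// averaged over an S x T window. stride1 = true keeps the input resolution
// (window anchored as rows r .. r+S-1 with replicate clamping, matching the
// summation index x[r+s]); stride1 = false tiles non-overlapping windows.
// Output slice (k*B + b) holds bin b of reduced channel k (bin-major).

// [[Rcpp::export]]
arma::cube cpp_hist_fwd(const arma::cube& x, const arma::mat& mu,
                        const arma::mat& gam, int S, int T, bool stride1) {
  const int H = x.n_rows, W = x.n_cols, K = x.n_slices, B = mu.n_rows;
  const int lo_r = (S - 1) / 2, lo_c = (T - 1) / 2;
  const int Ho = stride1 ? H : (H + S - 1) / S;
  const int Wo = stride1 ? W : (W + T - 1) / T;
  const double inv = 1.0 / (S * T);
  arma::cube out(Ho, Wo, B * K);
  arma::mat phi(H, W);
  for (int k = 0; k < K; ++k) {
    const arma::mat& xs = x.slice(k);
    for (int b = 0; b < B; ++b) {
      const double m = mu(b, k), g2 = gam(b, k) * gam(b, k);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          const double d = xs(r, c) - m;
          phi(r, c) = std::exp(-g2 * d * d);
        }
      arma::mat& os = out.slice(k * B + b);
      for (int c = 0; c < Wo; ++c) {
        for (int r = 0; r < Ho; ++r) {
          double acc = 0.0;
          const int r0 = stride1 ? r - lo_r : r * S;
          const int c0 = stride1 ? c - lo_c : c * T;
          for (int t = 0; t < T; ++t) {
            const int cc = clampi(c0 + t, 0, W - 1);
            for (int s = 0; s < S; ++s)
              acc += phi(clampi(r0 + s, 0, H - 1), cc);
          }
          os(r, c) = acc * inv;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hist_bwd(const arma::cube& x, const arma::mat& mu,
                  const arma::mat& gam, int S, int T, bool stride1,
                  const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, K = x.n_slices, B = mu.n_rows;
  const int lo_r = (S - 1) / 2, lo_c = (T - 1) / 2;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  const double inv = 1.0 / (S * T);
  arma::cube gx(H, W, K, arma::fill::zeros);
  arma::mat gmu(B, K, arma::fill::zeros), ggam(B, K, arma::fill::zeros);
  arma::mat gphi(H, W);
  for (int k = 0; k < K; ++k) {
    const arma::mat& xs = x.slice(k);
    arma::mat& gxs = gx.slice(k);
    for (int b = 0; b < B; ++b) {
      const double m = mu(b, k), g = gam(b, k), g2 = g * g;
      gphi.zeros();
      const arma::mat& gos = gout.slice(k * B + b);
      for (int c = 0; c < Wo; ++c) {
        for (int r = 0; r < Ho; ++r) {
          const double gv = gos(r, c) * inv;
          const int r0 = stride1 ? r - lo_r : r * S;
          const int c0 = stride1 ? c - lo_c : c * T;
          for (int t = 0; t < T; ++t) {
            const int cc = clampi(c0 + t, 0, W - 1);
            for (int s = 0; s < S; ++s)
              gphi(clampi(r0 + s, 0, H - 1), cc) += gv;
          }
        }
      }
      double acc_mu = 0.0, acc_gam = 0.0;
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          const double d = xs(r, c) - m;
          const double phi = std::exp(-g2 * d * d);
          const double gp = gphi(r, c) * phi;
          gxs(r, c) += gp * (-2.0 * g2 * d);
          acc_mu += gp * (2.0 * g2 * d);
          acc_gam += gp * (-2.0 * g * d * d);
        }
      }
      gmu(b, k) += acc_mu;
      ggam(b, k) += acc_gam;
    }
  }
  return List::create(_["gx"] = gx, _["gmu"] = gmu, _["ggam"] = ggam);
}
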