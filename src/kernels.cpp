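// Compiled numeric kernels for the CPU network core.
//
// Feature grids are stored as V x C matrices where V = h*w*d and the linear
// voxel index runs h-fastest (identical to an R array of dim c(h, w, d, C)
// with its dim attribute set to c(V, C)). All kernels are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::sword lin3(arma::sword h, arma::sword w, arma::sword d,
                               arma::sword H, arma::sword W) {
  return h + H * (w + W * d);
}

// Scatter-add X shifted by (dh,dw,dd): Acc[v + disp] += X[v].
static void shifted_add(const arma::mat& X, arma::mat& Acc,
                        arma::sword H, arma::sword W, arma::sword D,
                        arma::sword dh, arma::sword dw, arma::sword dd) {
  const arma::sword h0 = std::max<arma::sword>(0, -dh);
  const arma::sword h1 = std::min<arma::sword>(H, H - dh);
  if (h1 <= h0) return;
  for (arma::sword d = 0; d < D; ++d) {
    arma::sword sd = d + dd;
    if (sd < 0 || sd >= D) continue;
    for (arma::sword w = 0; w < W; ++w) {
      arma::sword sw = w + dw;
      if (sw < 0 || sw >= W) continue;
      arma::sword dst0 = lin3(h0 + dh, sw, sd, H, W);
      arma::sword src0 = lin3(h0, w, d, H, W);
      Acc.rows(dst0, dst0 + (h1 - h0) - 1) += X.rows(src0, src0 + (h1 - h0) - 1);
    }
  }
}

// Copy X shifted by (dh, dw, dd) into S (zero outside). S[v] = X[v + disp].
static void shifted_copy(const arma::mat& X, arma::mat& S,
                         arma::sword H, arma::sword W, arma::sword D,
                         arma::sword dh, arma::sword dw, arma::sword dd) {
  S.zeros();
  const arma::sword h0 = std::max<arma::sword>(0, -dh);
  const arma::sword h1 = std::min<arma::sword>(H, H - dh);
  if (h1 <= h0) return;
  for (arma::sword d = 0; d < D; ++d) {
    arma::sword sd = d + dd;
    if (sd < 0 || sd >= D) continue;
    for (arma::sword w = 0; w < W; ++w) {
      arma::sword sw = w + dw;
      if (sw < 0 || sw >= W) continue;
      // contiguous along h
      arma::sword dst0 = lin3(h0, w, d, H, W);
      arma::sword src0 = lin3(h0 + dh, sw, sd, H, W);
      S.rows(dst0, dst0 + (h1 - h0) - 1) = X.rows(src0, src0 + (h1 - h0) - 1);
    }
  }
}

// 3D "same" convolution (cross-correlation), odd kernel k, dilation dil,
// computed as one GEMM per kernel offset on a shifted copy of the input
// (keeps the working set cache-resident; faster here than im2col).
// W is a cube (Cin, Cout, k^3); offset o maps to (o % k, (o/k) % k, o/k^2).
// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& X, const arma::ivec& dims,
                         const arma::cube& W, const arma::vec& bias,
                         int k, int dil) {
  const arma::sword H = dims(0), Wd = dims(1), D = dims(2);
  const arma::uword V = X.n_rows, Cout = W.slice(0).n_cols;
  const int c = (k - 1) / 2;
  arma::mat out(V, Cout, arma::fill::zeros);
  arma::mat S(V, X.n_cols);
  for (int o = 0; o < k * k * k; ++o) {
    arma::sword dh = (arma::sword)(o % k - c) * dil;
    arma::sword dw = (arma::sword)((o / k) % k - c) * dil;
    arma::sword dd = (arma::sword)(o / (k * k) - c) * dil;
    if (dh == 0 && dw == 0 && dd == 0) {
      out += X * W.slice(o);
    } else {
      shifted_copy(X, S, H, Wd, D, dh, dw, dd);
      out += S * W.slice(o);
    }
  }
  out.each_row() += bias.t();
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& X, const arma::ivec& dims,
                    const arma::cube& W, const arma::mat& G,
                    int k, int dil) {
  const arma::sword H = dims(0), Wd = dims(1), D = dims(2);
  const int c = (k - 1) / 2;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::cube dW(W.n_rows, W.n_cols, W.n_slices, arma::fill::zeros);
  arma::vec db = arma::sum(G, 0).t();
  arma::mat S(X.n_rows, X.n_cols);
  for (int o = 0; o < k * k * k; ++o) {
    arma::sword dh = (arma::sword)(o % k - c) * dil;
    arma::sword dw = (arma::sword)((o / k) % k - c) * dil;
    arma::sword dd = (arma::sword)(o / (k * k) - c) * dil;
    arma::mat Gw = G * W.slice(o).t();  // V x Cin, contribution to dX at src
    if (dh == 0 && dw == 0 && dd == 0) {
      dW.slice(o) = X.t() * G;
      dX += Gw;
    } else {
      shifted_copy(X, S, H, Wd, D, dh, dw, dd);
      dW.slice(o) = S.t() * G;
      shifted_add(Gw, dX, H, Wd, D, dh, dw, dd);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Transposed convolution, kernel 2, stride 2: out(2h+a, 2w+b, 2d+c) =
// X(h,w,d) * W.slice(o) + bias, o = a + 2b + 4c.
// [[Rcpp::export]]
arma::mat cpp_convtrans2_fwd(const arma::mat& X, const arma::ivec& dims,
                             const arma::cube& W, const arma::vec& bias) {
  const arma::sword H = dims(0), Wd = dims(1), D = dims(2);
  const arma::sword H2 = 2 * H, W2 = 2 * Wd, D2 = 2 * D;
  const arma::uword Cout = W.slice(0).n_cols;
  arma::mat out(H2 * W2 * D2, Cout);
  out.each_row() = bias.t();
  for (int o = 0; o < 8; ++o) {
    int a = o % 2, b = (o / 2) % 2, c = o / 4;
    arma::mat M = X * W.slice(o);
    for (arma::sword d = 0; d < D; ++d)
      for (arma::sword w = 0; w < Wd; ++w)
        for (arma::sword h = 0; h < H; ++h)
          out.row(lin3(2 * h + a, 2 * w + b, 2 * d + c, H2, W2)) +=
              M.row(lin3(h, w, d, H, Wd));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convtrans2_bwd(const arma::mat& X, const arma::ivec& dims,
                        const arma::cube& W, const arma::mat& G) {
  const arma::sword H = dims(0), Wd = dims(1), D = dims(2);
  const arma::sword H2 = 2 * H, W2 = 2 * Wd;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::cube dW(W.n_rows, W.n_cols, 8, arma::fill::zeros);
  arma::vec db = arma::sum(G, 0).t();
  arma::mat Gsub(X.n_rows, G.n_cols);
  for (int o = 0; o < 8; ++o) {
    int a = o % 2, b = (o / 2) % 2, c = o / 4;
    for (arma::sword d = 0; d < D; ++d)
      for (arma::sword w = 0; w < Wd; ++w)
        for (arma::sword h = 0; h < H; ++h)
          Gsub.row(lin3(h, w, d, H, Wd)) =
              G.row(lin3(2 * h + a, 2 * w + b, 2 * d + c, H2, W2));
    dW.slice(o) = X.t() * Gsub;
    dX += Gsub * W.slice(o).t();
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling, stride 2, ceil extents (odd borders padded with -inf).
// Returns pooled values and 1-based argmax row indices into X.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::mat& X, const arma::ivec& dims) {
  const arma::sword H = dims(0), W = dims(1), D = dims(2);
  const arma::sword Ho = (H + 1) / 2, Wo = (W + 1) / 2, Do = (D + 1) / 2;
  const arma::uword C = X.n_cols;
  arma::mat out(Ho * Wo * Do, C);
  arma::imat idx(Ho * Wo * Do, C);
  for (arma::sword d = 0; d < Do; ++d)
    for (arma::sword w = 0; w < Wo; ++w)
      for (arma::sword h = 0; h < Ho; ++h) {
        arma::sword vo = lin3(h, w, d, Ho, Wo);
        for (arma::uword ch = 0; ch < C; ++ch) {
          double best = -arma::datum::inf;
          arma::sword bi = -1;
          for (int c3 = 0; c3 < 8; ++c3) {
            arma::sword hh = 2 * h + (c3 % 2), ww = 2 * w + ((c3 / 2) % 2),
                        dd = 2 * d + (c3 / 4);
            if (hh >= H || ww >= W || dd >= D) continue;
            arma::sword v = lin3(hh, ww, dd, H, W);
            if (X(v, ch) > best) { best = X(v, ch); bi = v; }
          }
          out(vo, ch) = best;
          idx(vo, ch) = bi + 1;
        }
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::imat& idx, const arma::mat& G,
                           int nrow_in) {
  arma::mat dX(nrow_in, G.n_cols, arma::fill::zeros);
  for (arma::uword ch = 0; ch < G.n_cols; ++ch)
    for (arma::uword v = 0; v < G.n_rows; ++v)
      dX(idx(v, ch) - 1, ch) += G(v, ch);
  return dX;
}

struct AxisMap {
  arma::ivec i0, i1;
  arma::vec w1;  // weight of i1; weight of i0 is 1 - w1
};

static AxisMap axis_map(arma::sword n_in, arma::sword n_out, bool nearest) {
  AxisMap m;
  m.i0.set_size(n_out); m.i1.set_size(n_out); m.w1.set_size(n_out);
  double scale = (double)n_in / (double)n_out;
  for (arma::sword i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (nearest) {
      arma::sword s = (arma::sword)std::floor((i + 0.5) * scale);
      s = std::min(std::max<arma::sword>(s, 0), n_in - 1);
      m.i0(i) = s; m.i1(i) = s; m.w1(i) = 0.0;
    } else {
      double f = std::floor(src);
      arma::sword s0 = (arma::sword)f, s1 = s0 + 1;
      double w1 = src - f;
      if (s0 < 0) { s0 = 0; s1 = 0; w1 = 0.0; }
      if (s1 > n_in - 1) { s1 = n_in - 1; if (s0 > n_in - 1) s0 = n_in - 1; }
      if (s0 == s1) w1 = 0.0;
      m.i0(i) = s0; m.i1(i) = s1; m.w1(i) = w1;
    }
  }
  return m;
}

// Separable trilinear (or nearest) resize with half-pixel centers.
// [[Rcpp::export]]
arma::mat cpp_resize3_fwd(const arma::mat& X, const arma::ivec& din,
                          const arma::ivec& dout, bool nearest) {
  const arma::sword H = din(0), W = din(1), D = din(2);
  const arma::sword Ho = dout(0), Wo = dout(1), Do = dout(2);
  const arma::uword C = X.n_cols;
  AxisMap mh = axis_map(H, Ho, nearest), mw = axis_map(W, Wo, nearest),
          md = axis_map(D, Do, nearest);
  arma::mat out(Ho * Wo * Do, C, arma::fill::zeros);
  for (arma::sword d = 0; d < Do; ++d)
    for (arma::sword w = 0; w < Wo; ++w)
      for (arma::sword h = 0; h < Ho; ++h) {
        arma::sword vo = lin3(h, w, d, Ho, Wo);
        for (int cc = 0; cc < 8; ++cc) {
          arma::sword sh = (cc & 1) ? mh.i1(h) : mh.i0(h);
          arma::sword sw = (cc & 2) ? mw.i1(w) : mw.i0(w);
          arma::sword sd = (cc & 4) ? md.i1(d) : md.i0(d);
          double wt = ((cc & 1) ? mh.w1(h) : 1 - mh.w1(h)) *
                      ((cc & 2) ? mw.w1(w) : 1 - mw.w1(w)) *
                      ((cc & 4) ? md.w1(d) : 1 - md.w1(d));
          if (wt == 0.0) continue;
          out.row(vo) += wt * X.row(lin3(sh, sw, sd, H, W));
        }
      }
  return out;
}

// Adjoint of trilinear resize (for gradients).
// [[Rcpp::export]]
arma::mat cpp_resize3_bwd(const arma::mat& G, const arma::ivec& din,
                          const arma::ivec& dout) {
  const arma::sword H = din(0), W = din(1), D = din(2);
  const arma::sword Ho = dout(0), Wo = dout(1), Do = dout(2);
  AxisMap mh = axis_map(H, Ho, false), mw = axis_map(W, Wo, false),
          md = axis_map(D, Do, false);
  arma::mat dX(H * W * D, G.n_cols, arma::fill::zeros);
  for (arma::sword d = 0; d < Do; ++d)
    for (arma::sword w = 0; w < Wo; ++w)
      for (arma::sword h = 0; h < Ho; ++h) {
        arma::sword vo = lin3(h, w, d, Ho, Wo);
        for (int cc = 0; cc < 8; ++cc) {
          arma::sword sh = (cc & 1) ? mh.i1(h) : mh.i0(h);
          arma::sword sw = (cc & 2) ? mw.i1(w) : mw.i0(w);
          arma::sword sd = (cc & 4) ? md.i1(d) : md.i0(d);
          double wt = ((cc & 1) ? mh.w1(h) : 1 - mh.w1(h)) *
                      ((cc & 2) ? mw.w1(w) : 1 - mw.w1(w)) *
                      ((cc & 4) ? md.w1(d) : 1 - md.w1(d));
          if (wt == 0.0) continue;
          dX.row(lin3(sh, sw, sd, H, W)) += wt * G.row(vo);
        }
      }
  return dX;
}

// Row gather with zero-padding: idx is 1-based, 0 selects a zero row.
// [[Rcpp::export]]
arma::mat cpp_gather_rows(const arma::mat& X, const arma::ivec& idx) {
  arma::mat out(idx.n_elem, X.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    if (idx(i) > 0) out.row(i) = X.row(idx(i) - 1);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_scatter_rows(const arma::mat& G, const arma::ivec& idx,
                           int nrow_out) {
  arma::mat dX(nrow_out, G.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    if (idx(i) > 0) dX.row(idx(i) - 1) += G.row(i);
  return dX;
}

// [[Rcpp::export]]
arma::vec cpp_gather_elems(const arma::vec& x, const arma::ivec& idx) {
  arma::vec out(idx.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    if (idx(i) > 0) out(i) = x(idx(i) - 1);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_scatter_elems(const arma::vec& g, const arma::ivec& idx,
                            int n_out) {
  arma::vec out(n_out, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    if (idx(i) > 0) out(idx(i) - 1) += g(i);
  return out;
}

// Batched masked window attention.
// Q, K, V: cubes (t, dh, nb) with nb = nW * heads, slice b -> window b/heads,
// head b%heads. B: relative-position bias, cube (t, t, heads). region:
// imat (t, nW); negative entries are padding tokens, tokens may attend only
// within equal region ids. Scores = Q K^T / sqrt(dh) + bias, masked softmax.
// Padding query rows output zeros.
// [[Rcpp::export]]
List cpp_attn_fwd(const arma::cube& Q, const arma::cube& K,
                  const arma::cube& V, const arma::cube& B,
                  const arma::imat& region, int heads) {
  const arma::uword t = Q.n_rows, dh = Q.n_cols, nb = Q.n_slices;
  const double sc = 1.0 / std::sqrt((double)dh);
  arma::cube out(t, dh, nb, arma::fill::zeros);
  arma::cube P(t, t, nb, arma::fill::zeros);
  for (arma::uword b = 0; b < nb; ++b) {
    arma::uword w = b / heads, hd = b % heads;
    arma::mat S = sc * (Q.slice(b) * K.slice(b).t()) + B.slice(hd);
    for (arma::uword i = 0; i < t; ++i) {
      int ri = region(i, w);
      if (ri < 0) continue;  // pad query row -> zeros
      double mx = -arma::datum::inf;
      for (arma::uword j = 0; j < t; ++j)
        if (region(j, w) == ri && S(i, j) > mx) mx = S(i, j);
      double Z = 0.0;
      for (arma::uword j = 0; j < t; ++j) {
        if (region(j, w) == ri) {
          double e = std::exp(S(i, j) - mx);
          P(i, j, b) = e;
          Z += e;
        }
      }
      for (arma::uword j = 0; j < t; ++j) P(i, j, b) /= Z;
    }
    out.slice(b) = P.slice(b) * V.slice(b);
  }
  return List::create(_["out"] = out, _["P"] = P);
}

// [[Rcpp::export]]
List cpp_attn_bwd(const arma::cube& Q, const arma::cube& K,
                  const arma::cube& V, const arma::cube& P,
                  const arma::cube& G, int heads) {
  const arma::uword t = Q.n_rows, dh = Q.n_cols, nb = Q.n_slices;
  const double sc = 1.0 / std::sqrt((double)dh);
  arma::cube dQ(t, dh, nb), dK(t, dh, nb), dV(t, dh, nb);
  arma::cube dB(t, t, heads, arma::fill::zeros);
  for (arma::uword b = 0; b < nb; ++b) {
    arma::uword hd = b % heads;
    dV.slice(b) = P.slice(b).t() * G.slice(b);
    arma::mat dP = G.slice(b) * V.slice(b).t();
    arma::vec rs = arma::sum(dP % P.slice(b), 1);
    arma::mat dS = P.slice(b) % dP - P.slice(b).each_col() % rs;
    dQ.slice(b) = sc * (dS * K.slice(b));
    dK.slice(b) = sc * (dS.t() * Q.slice(b));
    dB.slice(hd) += dS;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV, _["dB"] = dB);
}

// 6-connected binary erosion with zero padding outside the grid.
// [[Rcpp::export]]
arma::ivec cpp_erode6(const arma::ivec& mask, const arma::ivec& dims) {
  const arma::sword H = dims(0), W = dims(1), D = dims(2);
  arma::ivec out(mask.n_elem, arma::fill::zeros);
  for (arma::sword d = 0; d < D; ++d)
    for (arma::sword w = 0; w < W; ++w)
      for (arma::sword h = 0; h < H; ++h) {
        arma::sword v = lin3(h, w, d, H, W);
        if (!mask(v)) continue;
        bool keep =
            h > 0 && mask(lin3(h - 1, w, d, H, W)) &&
            h < H - 1 && mask(lin3(h + 1, w, d, H, W)) &&
            w > 0 && mask(lin3(h, w - 1, d, H, W)) &&
            w < W - 1 && mask(lin3(h, w + 1, d, H, W)) &&
            d > 0 && mask(lin3(h, w, d - 1, H, W)) &&
            d < D - 1 && mask(lin3(h, w, d + 1, H, W));
        out(v) = keep ? 1 : 0;
      }
  return out;
}

// Count surface voxels of A (rows of coords, 0-based) lying within Euclidean
// distance d of any surface voxel of Bc.
// [[Rcpp::export]]
int cpp_surface_within(const arma::imat& Ac, const arma::imat& Bc, double d) {
  const double d2 = d * d;
  int n = 0;
  for (arma::uword i = 0; i < Ac.n_rows; ++i) {
    bool hit = false;
    for (arma::uword j = 0; j < Bc.n_rows && !hit; ++j) {
      double dx = Ac(i, 0) - Bc(j, 0), dy = Ac(i, 1) - Bc(j, 1),
             dz = Ac(i, 2) - Bc(j, 2);
      if (dx * dx + dy * dy + dz * dz <= d2) hit = true;
    }
    if (hit) ++n;
  }
  return n;
}
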