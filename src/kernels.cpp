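#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Activations are R arrays dim (H, W, C), column-major: x[h + H*w + H*W*c].
// im2col rows are ordered kh-fastest, then kw, then channel, matching a
// weight array of dim (kh, kw, C, F) flattened column-major into a
// (kh*kw*C) x F matrix. Output column p indexes positions oh + outH*ow.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  int outH = (H + 2 * pad - kh) / stride + 1;
  int outW = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, outH * outW);
  double *po = out.begin();
  const double *px = x.begin();
  for (int ow = 0; ow < outW; ++ow) {
    for (int oh = 0; oh < outH; ++oh) {
      int p = oh + outH * ow;
      int h0 = oh * stride - pad, w0 = ow * stride - pad;
      double *col = po + (R_xlen_t)p * (kh * kw * C);
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          int wp = w0 + dw;
          const double *slab = px + (R_xlen_t)H * (wp + (R_xlen_t)W * c);
          for (int dh = 0; dh < kh; ++dh) {
            int hp = h0 + dh;
            double v = 0.0;
            if (hp >= 0 && hp < H && wp >= 0 && wp < W) v = slab[hp];
            col[dh + kh * (dw + kw * c)] = v;
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col: cols is (kh*kw*C) x (outH*outW).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  int outH = (H + 2 * pad - kh) / stride + 1;
  int outW = (W + 2 * pad - kw) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int ow = 0; ow < outW; ++ow) {
    for (int oh = 0; oh < outH; ++oh) {
      int p = oh + outH * ow;
      int h0 = oh * stride - pad, w0 = ow * stride - pad;
      const double *col = pc + (R_xlen_t)p * (kh * kw * C);
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          int wp = w0 + dw;
          if (wp < 0 || wp >= W) continue;
          double *slab = px + (R_xlen_t)H * (wp + (R_xlen_t)W * c);
          for (int dh = 0; dh < kh; ++dh) {
            int hp = h0 + dh;
            if (hp < 0 || hp >= H) continue;
            slab[hp] += col[dh + kh * (dw + kw * c)];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling with argmax bookkeeping (0-based linear indices into input).
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  int outH = (H + 2 * pad - k) / stride + 1;
  int outW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)outH * outW * C);
  IntegerVector arg((R_xlen_t)outH * outW * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < outW; ++ow) {
      for (int oh = 0; oh < outH; ++oh) {
        int h0 = oh * stride - pad, w0 = ow * stride - pad;
        double best = R_NegInf;
        int bi = -1;
        for (int dw = 0; dw < k; ++dw) {
          int wp = w0 + dw;
          if (wp < 0 || wp >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hp = h0 + dh;
            if (hp < 0 || hp >= H) continue;
            R_xlen_t idx = hp + (R_xlen_t)H * (wp + (R_xlen_t)W * c);
            if (px[idx] > best) { best = px[idx]; bi = (int)idx; }
          }
        }
        R_xlen_t o = oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * c);
        // window entirely in padding cannot occur for k > pad
        y[o] = (bi < 0) ? 0.0 : best;
        arg[o] = bi;
      }
    }
  }
  return List::create(_["values"] = y, _["argmax"] = arg,
                      _["outH"] = outH, _["outW"] = outW);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector argmax,
                                   R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    int a = argmax[i];
    if (a >= 0) dx[a] += dy[i];
  }
  return dx;
}

// Two-pass connected-component labelling with union-find; connectivity 4 or 8.
// Labels are assigned in raster (row-major over rows within columns? we use
// column-major scan but relabel at the end so final ids are by first pixel in
// row-major order, giving deterministic row-major component ordering).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // parent[0] unused
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int h = 0; h < H; ++h) {     // row-major scan
    for (int w = 0; w < W; ++w) {
      if (!mask(h, w)) continue;
      int up = (h > 0 && mask(h - 1, w)) ? lab(h - 1, w) : 0;
      int left = (w > 0 && mask(h, w - 1)) ? lab(h, w - 1) : 0;
      int ul = 0, ur = 0;
      if (connectivity == 8) {
        if (h > 0 && w > 0 && mask(h - 1, w - 1)) ul = lab(h - 1, w - 1);
        if (h > 0 && w < W - 1 && mask(h - 1, w + 1)) ur = lab(h - 1, w + 1);
      }
      int lbl = 0;
      int nb[4] = {up, left, ul, ur};
      for (int i = 0; i < 4; ++i)
        if (nb[i] > 0) lbl = (lbl == 0) ? nb[i] : std::min(lbl, nb[i]);
      if (lbl == 0) {
        lbl = next++;
        parent.push_back(lbl);
      } else {
        for (int i = 0; i < 4; ++i) if (nb[i] > 0) unite(lbl, nb[i]);
      }
      lab(h, w) = lbl;
    }
  }
  // resolve + compact labels in row-major first-appearance order
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) {
      if (!lab(h, w)) continue;
      int r = find(lab(h, w));
      if (!remap[r]) remap[r] = ++out;
      lab(h, w) = remap[r];
    }
  }
  return lab;
}

// Bilinear resize of an (H, W, C) array to (outH, outW, C); half-pixel centers.
// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(NumericVector x, int H, int W, int C,
                                  int outH, int outW) {
  NumericVector y((R_xlen_t)outH * outW * C);
  const double *px = x.begin();
  double sh = (double)H / outH, sw = (double)W / outW;
  for (int c = 0; c < C; ++c) {
    const double *slab = px + (R_xlen_t)H * W * c;
    for (int ow = 0; ow < outW; ++ow) {
      double wf = (ow + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(wf);
      double tw = wf - w0;
      int w0c = std::min(std::max(w0, 0), W - 1);
      int w1c = std::min(std::max(w0 + 1, 0), W - 1);
      for (int oh = 0; oh < outH; ++oh) {
        double hf = (oh + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(hf);
        double th = hf - h0;
        int h0c = std::min(std::max(h0, 0), H - 1);
        int h1c = std::min(std::max(h0 + 1, 0), H - 1);
        double v00 = slab[h0c + (R_xlen_t)H * w0c];
        double v10 = slab[h1c + (R_xlen_t)H * w0c];
        double v01 = slab[h0c + (R_xlen_t)H * w1c];
        double v11 = slab[h1c + (R_xlen_t)H * w1c];
        double v0 = v00 * (1 - th) + v10 * th;
        double v1 = v01 * (1 - th) + v11 * th;
        y[oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * c)] =
          v0 * (1 - tw) + v1 * tw;
      }
    }
  }
  return y;
}
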