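// Low-level numerical kernels: same-padding 2-D convolution (im2col +
// BLAS gemm) with its gradients, max pooling with argmax bookkeeping,
// nearest-neighbour upsampling, and the adaptive median filter.
// Layout convention matches R arrays: cube(H, W, C), column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for stride-1 same (zero) padding, pixel-major layout:
// output (H*W) x (k*k*C), so the hot inner loops walk contiguous
// memory in both source and destination.  Single precision: the gemm
// calls dominate training cost and sgemm doubles the throughput.
static fmat im2col_same(const fcube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  fmat col(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat& xc = x.slice(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        float* dst = col.colptr(c * k * k + kx * k + ky);
        const int i0 = std::max(0, pad - ky);
        const int i1 = std::min(H, H + pad - ky);
        const int j0 = std::max(0, pad - kx);
        const int j1 = std::min(W, W + pad - kx);
        for (int j = j0; j < j1; ++j) {
          const float* src = xc.colptr(j + kx - pad) + (i0 + ky - pad);
          std::copy(src, src + (i1 - i0), dst + j * H + i0);
        }
      }
    }
  }
  return col;
}

// scatter-add counterpart of im2col_same (pixel-major layout)
static fcube col2im_same(const fmat& colm, const int H, const int W,
                         const int C, const int k) {
  const int pad = (k - 1) / 2;
  fcube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat& xc = x.slice(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const float* src = colm.colptr(c * k * k + kx * k + ky);
        const int i0 = std::max(0, pad - ky);
        const int i1 = std::min(H, H + pad - ky);
        const int j0 = std::max(0, pad - kx);
        const int j1 = std::min(W, W + pad - kx);
        for (int j = j0; j < j1; ++j) {
          float* dst = xc.colptr(j + kx - pad) + (i0 + ky - pad);
          const float* s = src + j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube lf_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int F = w.n_cols;
  const fcube xf = conv_to<fcube>::from(x);
  const fmat wf = conv_to<fmat>::from(w);
  const frowvec bf = conv_to<frowvec>::from(b.t());
  fmat col = im2col_same(xf, k);
  fmat out = col * wf;             // (H*W) x F
  out.each_row() += bf;
  cube o(H, W, F);
  for (int f = 0; f < F; ++f) {
    o.slice(f) = conv_to<mat>::from(reshape(out.col(f), H, W));
  }
  return o;
}

// [[Rcpp::export]]
Rcpp::List lf_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dout, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int F = dout.n_slices;
  const fcube xf = conv_to<fcube>::from(x);
  const fmat wf = conv_to<fmat>::from(w);
  fmat dmat(H * W, F);             // pixel-major gradient
  for (int f = 0; f < F; ++f) {
    dmat.col(f) = conv_to<fvec>::from(vectorise(dout.slice(f)));
  }
  fmat col = im2col_same(xf, k);
  fmat dWf = col.t() * dmat;       // (k*k*C) x F
  frowvec dbf = sum(dmat, 0);
  fmat dcol = dmat * wf.t();       // (H*W) x (k*k*C)
  fcube dxf = col2im_same(dcol, H, W, C, k);
  return Rcpp::List::create(
    Rcpp::Named("dx") = conv_to<cube>::from(dxf),
    Rcpp::Named("dW") = conv_to<mat>::from(dWf),
    Rcpp::Named("db") = conv_to<vec>::from(dbf.t()));
}

// [[Rcpp::export]]
Rcpp::List lf_maxpool_fwd(const arma::cube& x, const int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / p, Wo = W / p;
  cube o(Ho, Wo, C);
  ucube idx(Ho, Wo, C);            // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < p; ++dj) {
          for (int di = 0; di < p; ++di) {
            const int ii = i * p + di, jj = j * p + dj;
            const double v = xc(ii, jj);
            if (v > best) { best = v; bi = jj * H + ii; }
          }
        }
        o(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = o, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube lf_maxpool_bwd(const arma::cube& dout, const arma::ucube& idx,
                          const int H, const int W, const int p) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dc = dx.slice(c);
    const mat& oc = dout.slice(c);
    const umat& ic = idx.slice(c);
    for (uword j = 0; j < oc.n_cols; ++j) {
      for (uword i = 0; i < oc.n_rows; ++i) {
        dc(ic(i, j)) += oc(i, j);
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube lf_upsample_fwd(const arma::cube& x, const int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube o(H * p, W * p, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        o.slice(c).submat(i * p, j * p, i * p + p - 1, j * p + p - 1)
          .fill(x(i, j, c));
      }
    }
  }
  return o;
}

// [[Rcpp::export]]
arma::cube lf_upsample_bwd(const arma::cube& dout, const int p) {
  const int H = dout.n_rows / p, W = dout.n_cols / p, C = dout.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        dx(i, j, c) = accu(
          dout.slice(c).submat(i * p, j * p, i * p + p - 1, j * p + p - 1));
      }
    }
  }
  return dx;
}

// Classical A/B-stage adaptive median filter on one channel.
// Decisions use rounded intensities; `margin` is the minimum distance
// from the window median for an extreme-valued pixel to be judged
// impulsive (0 disables both robustness guards and reproduces the
// textbook rule exactly).  With margin > 0 the deviation must also
// exceed 5x the window's median absolute deviation (a Hampel-style
// guard), so pixels of high-contrast texture are not mistaken for
// impulses while genuine salt-and-pepper outliers -- 60-250 levels from
// the local median -- are always replaced.
// [[Rcpp::export]]
arma::mat lf_adaptive_median(const arma::mat& x, const int smax,
                             const double margin) {
  const int H = x.n_rows, W = x.n_cols;
  mat xr = round(x);
  mat out = x;
  std::vector<double> buf, dev;
  buf.reserve(smax * smax);
  dev.reserve(smax * smax);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      for (int s = 3; s <= smax; s += 2) {
        const int r = s / 2;
        buf.clear();
        const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
        const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii)
            buf.push_back(xr(ii, jj));
        std::sort(buf.begin(), buf.end());
        const double zmin = buf.front(), zmax = buf.back();
        const double zmed = buf[buf.size() / 2];
        const double zxy = xr(i, j);
        double thresh = margin;
        if (margin > 0) {
          dev.clear();
          for (double v : buf) dev.push_back(std::abs(v - zmed));
          std::sort(dev.begin(), dev.end());
          thresh = std::max(margin, 5.0 * dev[dev.size() / 2]);
        }
        if (zmed > zmin && zmed < zmax) {          // stage A: median usable
          const bool interior = (zxy > zmin && zxy < zmax);
          const bool impulsive = !interior && std::abs(zxy - zmed) > thresh;
          if (impulsive) out(i, j) = zmed;
          break;                                    // stage B decided
        }
        if (s == smax) {
          // window exhausted; replace only clear impulses
          if (std::abs(zxy - zmed) > thresh) out(i, j) = zmed;
        }
      }
    }
  }
  return out;
}
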