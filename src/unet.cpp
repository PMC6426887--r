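// Minimal CPU U-Net (two classes, configurable depth/width) with hand-written
// forward and backward passes.  Feature maps are stored as (npix x channels)
// matrices in column-major pixel order (p = ix + iy*nx); 3x3 convolutions are
// computed as nine shifted GEMMs, avoiding an explicit im2col buffer.
// Zero padding ("same" convolutions), 2x2 max-pooling, 2x2 stride-2
// transposed convolutions for upsampling, skip concatenation [skip, up],
// softmax cross-entropy with optional class weights.
//
// Weight list layout (order fixed, produced by unet_init() on the R side;
// biases are (n x 1) matrices):
//   enc{l}_c1_W (9*Cin x Cout), enc{l}_c1_b, enc{l}_c2_W, enc{l}_c2_b
//     for l = 0..depth-1
//   up{l}_W (Cin x 4*Cout), up{l}_b, dec{l}_c1_W, dec{l}_c1_b,
//     dec{l}_c2_W, dec{l}_c2_b for l = depth-2..0
//   out_W (F x 2), out_b (2 x 1)

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int OFF[9][2] = {
  {-1,-1},{0,-1},{1,-1},{-1,0},{0,0},{1,0},{-1,1},{0,1},{1,1}};

// shift feature map by (dx,dy): out(p) = X(ix+dx, iy+dy), zero outside
static mat shift_map(const mat& X, int nx, int ny, int dx, int dy) {
  mat out(X.n_rows, X.n_cols, arma::fill::zeros);
  int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
  int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
  if (x0 >= x1 || y0 >= y1) return out;
  for (int iy = y0; iy < y1; ++iy) {
    int src0 = (x0 + dx) + (iy + dy) * nx;
    out.rows(x0 + iy * nx, x1 - 1 + iy * nx) =
      X.rows(src0, src0 + (x1 - x0) - 1);
  }
  return out;
}

static mat conv3_fwd(const mat& X, int nx, int ny, const mat& W, const mat& b) {
  const int cin = X.n_cols;
  mat Y(X.n_rows, W.n_cols);
  Y.each_row() = b.col(0).t();
  for (int o = 0; o < 9; ++o)
    Y += shift_map(X, nx, ny, OFF[o][0], OFF[o][1]) *
         W.rows(o * cin, (o + 1) * cin - 1);
  return Y;
}

// accumulate dW, db; return dX
static mat conv3_bwd(const mat& X, const mat& dY, int nx, int ny,
                     const mat& W, mat& dW, mat& db) {
  const int cin = X.n_cols;
  mat dX(X.n_rows, cin, arma::fill::zeros);
  db += arma::sum(dY, 0).t();
  for (int o = 0; o < 9; ++o) {
    dW.rows(o * cin, (o + 1) * cin - 1) +=
      shift_map(X, nx, ny, OFF[o][0], OFF[o][1]).t() * dY;
    dX += shift_map(dY * W.rows(o * cin, (o + 1) * cin - 1).t(),
                    nx, ny, -OFF[o][0], -OFF[o][1]);
  }
  return dX;
}

static mat maxpool_fwd(const mat& X, int nx, int ny, arma::umat& argmax) {
  const int c = X.n_cols, nx2 = nx / 2, ny2 = ny / 2;
  mat Y(nx2 * ny2, c);
  argmax.set_size(nx2 * ny2, c);
  for (int ch = 0; ch < c; ++ch)
    for (int iy = 0; iy < ny2; ++iy)
      for (int ix = 0; ix < nx2; ++ix) {
        int p00 = 2 * ix + 2 * iy * nx;
        int cand[4] = {p00, p00 + 1, p00 + nx, p00 + nx + 1};
        int best = cand[0];
        double bv = X(cand[0], ch);
        for (int j = 1; j < 4; ++j)
          if (X(cand[j], ch) > bv) { bv = X(cand[j], ch); best = cand[j]; }
        Y(ix + iy * nx2, ch) = bv;
        argmax(ix + iy * nx2, ch) = best;
      }
  return Y;
}

static mat maxpool_bwd(const mat& dY, int npix_in, const arma::umat& argmax) {
  mat dX(npix_in, dY.n_cols, arma::fill::zeros);
  for (arma::uword ch = 0; ch < dY.n_cols; ++ch)
    for (arma::uword p = 0; p < dY.n_rows; ++p)
      dX(argmax(p, ch), ch) += dY(p, ch);
  return dX;
}

// transposed conv 2x2 stride 2; W (Cin x 4*Cout), sub-position s = dx + 2*dy
static mat upconv_fwd(const mat& X, int nx, int ny, const mat& W, const mat& b) {
  const int cout = W.n_cols / 4;
  const int nx2 = 2 * nx, ny2 = 2 * ny;
  mat T = X * W;
  mat Y(nx2 * ny2, cout);
  Y.each_row() = b.col(0).t();
  for (int s = 0; s < 4; ++s) {
    int dx = s % 2, dy = s / 2;
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        Y.row((2 * ix + dx) + (2 * iy + dy) * nx2) +=
          T(ix + iy * nx, arma::span(s * cout, (s + 1) * cout - 1));
  }
  return Y;
}

static mat upconv_bwd(const mat& X, const mat& dY, int nx, int ny,
                      const mat& W, mat& dW, mat& db) {
  const int cout = W.n_cols / 4;
  const int nx2 = 2 * nx;
  db += arma::sum(dY, 0).t();
  mat dT(X.n_rows, W.n_cols, arma::fill::zeros);
  for (int s = 0; s < 4; ++s) {
    int dx = s % 2, dy = s / 2;
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        dT(ix + iy * nx, arma::span(s * cout, (s + 1) * cout - 1)) =
          dY.row((2 * ix + dx) + (2 * iy + dy) * nx2);
  }
  dW += X.t() * dT;
  return dT * W.t();
}

static mat relu(const mat& X) { return arma::clamp(X, 0.0, arma::datum::inf); }

static mat relu_grad(const mat& dY, const mat& A) {
  mat out = dY;
  out.elem(arma::find(A <= 0)).zeros();
  return out;
}

struct Cache {
  std::vector<mat> enc_in, enc_a1, enc_a2;
  std::vector<arma::umat> argmax;
  std::vector<mat> up_in, up_out, cat, dec_a1, dec_a2, skip_grad;
  mat final_in;
};

// forward through the whole network for one sample; returns logits (N x 2)
static mat unet_fwd(const mat& X0, int nx, int ny, const List& w,
                    int depth, Cache& C) {
  int wi = 0;
  std::vector<mat> skips;
  mat X = X0;
  int cx = nx, cy = ny;
  for (int l = 0; l < depth; ++l) {
    mat W1 = as<mat>(w[wi]), B1 = as<mat>(w[wi + 1]);
    mat W2 = as<mat>(w[wi + 2]), B2 = as<mat>(w[wi + 3]);
    wi += 4;
    C.enc_in.push_back(X);
    mat A1 = relu(conv3_fwd(X, cx, cy, W1, B1));
    C.enc_a1.push_back(A1);
    mat A2 = relu(conv3_fwd(A1, cx, cy, W2, B2));
    C.enc_a2.push_back(A2);
    if (l < depth - 1) {
      arma::umat am;
      mat P = maxpool_fwd(A2, cx, cy, am);
      C.argmax.push_back(am);
      skips.push_back(A2);
      X = P; cx /= 2; cy /= 2;
    } else {
      X = A2;
    }
  }
  for (int l = depth - 2; l >= 0; --l) {
    mat UW = as<mat>(w[wi]), UB = as<mat>(w[wi + 1]);
    mat W1 = as<mat>(w[wi + 2]), B1 = as<mat>(w[wi + 3]);
    mat W2 = as<mat>(w[wi + 4]), B2 = as<mat>(w[wi + 5]);
    wi += 6;
    C.up_in.push_back(X);
    mat U = upconv_fwd(X, cx, cy, UW, UB);
    cx *= 2; cy *= 2;
    C.up_out.push_back(U);
    mat Cat = arma::join_rows(skips[l], U);
    C.cat.push_back(Cat);
    mat A1 = relu(conv3_fwd(Cat, cx, cy, W1, B1));
    C.dec_a1.push_back(A1);
    mat A2 = relu(conv3_fwd(A1, cx, cy, W2, B2));
    C.dec_a2.push_back(A2);
    X = A2;
  }
  mat OW = as<mat>(w[wi]), OB = as<mat>(w[wi + 1]);
  C.final_in = X;
  mat logits = X * OW;
  logits.each_row() += OB.col(0).t();
  return logits;
}

// [[Rcpp::export]]
arma::mat cpp_unet_predict(const arma::mat& img, const List& weights,
                           int depth) {
  const int nx = img.n_rows, ny = img.n_cols;
  mat X0 = arma::reshape(img, nx * ny, 1);
  Cache C;
  mat logits = unet_fwd(X0, nx, ny, weights, depth, C);
  vec d = logits.col(1) - logits.col(0);
  vec p = 1.0 / (1.0 + arma::exp(-d));
  return arma::reshape(mat(p), nx, ny);
}

// One training batch: forward + loss + backward, gradients averaged over
// the batch.  X: nx x ny x B cube, Y: same shape, labels in {0,1}
// (1 = cell border).
// [[Rcpp::export]]
List cpp_unet_batch(const arma::cube& X, const arma::cube& Y,
                    const List& weights, int depth,
                    const arma::vec& class_weights) {
  const int nx = X.n_rows, ny = X.n_cols, B = X.n_slices;
  const int nw = weights.size();
  std::vector<mat> gW(nw);
  for (int i = 0; i < nw; ++i) {
    mat Wi = as<mat>(weights[i]);
    gW[i] = mat(Wi.n_rows, Wi.n_cols, arma::fill::zeros);
  }
  double loss = 0.0, acc = 0.0;
  const int N = nx * ny;

  for (int s = 0; s < B; ++s) {
    Cache C;
    mat X0 = arma::reshape(X.slice(s), N, 1);
    vec yv = arma::vectorise(Y.slice(s));
    mat logits = unet_fwd(X0, nx, ny, weights, depth, C);

    vec d = logits.col(1) - logits.col(0);
    vec p1 = 1.0 / (1.0 + arma::exp(-d));
    double wsum = 0.0, l = 0.0;
    long ncorrect = 0;
    mat dlog(N, 2);
    for (int p = 0; p < N; ++p) {
      int y = yv(p) > 0.5 ? 1 : 0;
      double pr1 = std::min(std::max(p1(p), 1e-12), 1.0 - 1e-12);
      double w = class_weights(y);
      wsum += w;
      l += w * (y == 1 ? -std::log(pr1) : -std::log(1.0 - pr1));
      dlog(p, 1) = w * (pr1 - y);
      dlog(p, 0) = -dlog(p, 1);
      if ((p1(p) >= 0.5 ? 1 : 0) == y) ++ncorrect;
    }
    dlog /= wsum;
    loss += l / wsum;
    acc += static_cast<double>(ncorrect) / N;

    // output layer backward
    mat OW = as<mat>(weights[nw - 2]);
    gW[nw - 2] += C.final_in.t() * dlog;
    gW[nw - 1] += arma::sum(dlog, 0).t();
    mat dX = dlog * OW.t();

    // decoder backward: finest level (l = 0, cache idx depth-2) first
    int cx = nx, cy = ny;
    C.skip_grad.resize(depth - 1);
    for (int l = 0; l <= depth - 2; ++l) {
      int idx = depth - 2 - l;           // cache index of decoder level l
      int base = 4 * depth + 6 * idx;    // weight index of up{l}_W
      mat UW = as<mat>(weights[base]);
      mat W1 = as<mat>(weights[base + 2]);
      mat W2 = as<mat>(weights[base + 4]);
      mat dA2 = relu_grad(dX, C.dec_a2[idx]);
      mat dA1 = conv3_bwd(C.dec_a1[idx], dA2, cx, cy, W2,
                          gW[base + 4], gW[base + 5]);
      dA1 = relu_grad(dA1, C.dec_a1[idx]);
      mat dCat = conv3_bwd(C.cat[idx], dA1, cx, cy, W1,
                           gW[base + 2], gW[base + 3]);
      int cskip = C.cat[idx].n_cols - C.up_out[idx].n_cols;
      C.skip_grad[l] = dCat.cols(0, cskip - 1);
      mat dU = dCat.cols(cskip, dCat.n_cols - 1);
      cx /= 2; cy /= 2;
      dX = upconv_bwd(C.up_in[idx], dU, cx, cy, UW, gW[base], gW[base + 1]);
    }

    // encoder backward, from the bottom level up
    for (int l = depth - 1; l >= 0; --l) {
      int base = 4 * l;
      mat W1 = as<mat>(weights[base]);
      mat W2 = as<mat>(weights[base + 2]);
      mat dA2;
      if (l == depth - 1) {
        dA2 = dX;
      } else {
        dA2 = maxpool_bwd(dX, C.enc_a2[l].n_rows, C.argmax[l]) +
              C.skip_grad[l];
      }
      dA2 = relu_grad(dA2, C.enc_a2[l]);
      mat dA1 = conv3_bwd(C.enc_a1[l], dA2, cx, cy, W2,
                          gW[base + 2], gW[base + 3]);
      dA1 = relu_grad(dA1, C.enc_a1[l]);
      dX = conv3_bwd(C.enc_in[l], dA1, cx, cy, W1, gW[base], gW[base + 1]);
      cx *= 2; cy *= 2;
    }
  }

  List grads(nw);
  for (int i = 0; i < nw; ++i) grads[i] = gW[i] / B;
  grads.attr("names") = weights.attr("names");
  return List::create(Named("loss") = loss / B,
                      Named("accuracy") = acc / B,
                      Named("grads") = grads);
}
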