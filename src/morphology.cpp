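// Flat grayscale morphology, geodesic reconstruction, regional maxima,
// connected-component labelling and marker-constrained watershed flooding.
//
// Images are arma::mat with element (ix, iy); boundary convention for
// erosion/dilation is "ignore outside" (the min/max runs over the part of
// the structuring element that falls inside the frame), which is the
// convention the brute-force definitional tests assert.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline bool inside(int ix, int iy, int nx, int ny) {
  return ix >= 0 && iy >= 0 && ix < nx && iy < ny;
}

// se: k x 2 integer matrix of (dx, dy) offsets
// [[Rcpp::export]]
arma::mat cpp_erode(const arma::mat& x, const arma::imat& se) {
  const int nx = x.n_rows, ny = x.n_cols, k = se.n_rows;
  arma::mat out(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double m = arma::datum::inf;
      for (int j = 0; j < k; ++j) {
        int qx = ix + se(j, 0), qy = iy + se(j, 1);
        if (inside(qx, qy, nx, ny)) {
          double v = x(qx, qy);
          if (v < m) m = v;
        }
      }
      out(ix, iy) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_dilate(const arma::mat& x, const arma::imat& se) {
  const int nx = x.n_rows, ny = x.n_cols, k = se.n_rows;
  arma::mat out(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double m = -arma::datum::inf;
      for (int j = 0; j < k; ++j) {
        int qx = ix + se(j, 0), qy = iy + se(j, 1);
        if (inside(qx, qy, nx, ny)) {
          double v = x(qx, qy);
          if (v > m) m = v;
        }
      }
      out(ix, iy) = m;
    }
  }
  return out;
}

static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX4[4] = {0, -1, 1, 0};
static const int DY4[4] = {-1, 0, 0, 1};

// Grayscale reconstruction by dilation of `marker` under `mask`
// (8-connected), by alternating raster/anti-raster sweeps to convergence.
// [[Rcpp::export]]
arma::mat cpp_reconstruct(const arma::mat& marker, const arma::mat& mask) {
  const int nx = marker.n_rows, ny = marker.n_cols;
  arma::mat f = arma::min(marker, mask);
  bool changed = true;
  // forward scan neighbours: already-visited in column-major order
  const int fdx[4] = {-1, -1, -1, 0}, fdy[4] = {-1, 0, 1, -1};
  const int bdx[4] = {1, 1, 1, 0},    bdy[4] = {-1, 0, 1, 1};
  while (changed) {
    changed = false;
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        double m = f(ix, iy);
        for (int j = 0; j < 4; ++j) {
          int qx = ix + fdx[j], qy = iy + fdy[j];
          if (inside(qx, qy, nx, ny) && f(qx, qy) > m) m = f(qx, qy);
        }
        m = std::min(m, mask(ix, iy));
        if (m > f(ix, iy)) { f(ix, iy) = m; changed = true; }
      }
    }
    for (int iy = ny - 1; iy >= 0; --iy) {
      for (int ix = nx - 1; ix >= 0; --ix) {
        double m = f(ix, iy);
        for (int j = 0; j < 4; ++j) {
          int qx = ix + bdx[j], qy = iy + bdy[j];
          if (inside(qx, qy, nx, ny) && f(qx, qy) > m) m = f(qx, qy);
        }
        m = std::min(m, mask(ix, iy));
        if (m > f(ix, iy)) { f(ix, iy) = m; changed = true; }
      }
    }
  }
  return f;
}

// Label connected components of non-zero pixels; conn = 4 or 8.
// Labels assigned in column-major order of first encounter.
// [[Rcpp::export]]
arma::imat cpp_label(const arma::imat& mask, int conn) {
  const int nx = mask.n_rows, ny = mask.n_cols;
  const int* dx = (conn == 8) ? DX8 : DX4;
  const int* dy = (conn == 8) ? DY8 : DY4;
  const int nn = (conn == 8) ? 8 : 4;
  arma::imat lab(nx, ny, arma::fill::zeros);
  int next = 0;
  std::vector<int> stack;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      if (mask(ix, iy) == 0 || lab(ix, iy) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(ix + iy * nx);
      lab(ix, iy) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int px = p % nx, py = p / nx;
        for (int j = 0; j < nn; ++j) {
          int qx = px + dx[j], qy = py + dy[j];
          if (inside(qx, qy, nx, ny) && mask(qx, qy) != 0 && lab(qx, qy) == 0) {
            lab(qx, qy) = next;
            stack.push_back(qx + qy * nx);
          }
        }
      }
    }
  }
  return lab;
}

// a plateau spanning the whole frame is background, not a marker
static bool whole_frame_plateau(size_t plateau_size, int nx, int ny) {
  return plateau_size == static_cast<size_t>(nx) * static_cast<size_t>(ny);
}

// Regional maxima: connected plateaus (conn-connectivity among equal-valued
// pixels) strictly greater than every pixel adjacent to the plateau.
// Returns plateau labels (> 0) on maxima, 0 elsewhere.  A constant image has
// none (its single plateau has no outside neighbour to dominate, but is
// rejected explicitly to avoid a degenerate whole-frame marker).
// [[Rcpp::export]]
arma::imat cpp_regional_maxima(const arma::mat& x, int conn) {
  const int nx = x.n_rows, ny = x.n_cols;
  const int* dx = (conn == 8) ? DX8 : DX4;
  const int* dy = (conn == 8) ? DY8 : DY4;
  const int nn = (conn == 8) ? 8 : 4;
  arma::imat lab(nx, ny, arma::fill::zeros);
  arma::imat seen(nx, ny, arma::fill::zeros);
  int next = 0;
  std::vector<int> stack, plateau;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      if (seen(ix, iy)) continue;
      double v = x(ix, iy);
      bool is_max = true;
      stack.clear(); plateau.clear();
      stack.push_back(ix + iy * nx);
      seen(ix, iy) = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int px = p % nx, py = p / nx;
        for (int j = 0; j < nn; ++j) {
          int qx = px + dx[j], qy = py + dy[j];
          if (!inside(qx, qy, nx, ny)) continue;
          double w = x(qx, qy);
          if (w > v) { is_max = false; }
          else if (w == v && !seen(qx, qy)) {
            seen(qx, qy) = 1;
            stack.push_back(qx + qy * nx);
          }
        }
      }
      if (whole_frame_plateau(plateau.size(), nx, ny)) is_max = false;
      if (is_max) {
        ++next;
        for (size_t j = 0; j < plateau.size(); ++j)
          lab(plateau[j] % nx, plateau[j] / nx) = next;
      }
    }
  }
  return lab;
}

// Meyer's marker-constrained flooding.  relief: heights to flood; markers:
// integer labels > 0 at marker pixels.  4-connected basin growth; pixels
// where distinct basins meet stay 0 (watershed line).  Priority: lower
// relief first, FIFO among equal heights (deterministic).
// [[Rcpp::export]]
arma::imat cpp_watershed(const arma::mat& relief, const arma::imat& markers) {
  const int nx = relief.n_rows, ny = relief.n_cols;
  arma::imat lab(nx, ny, arma::fill::zeros);
  arma::imat state(nx, ny, arma::fill::zeros); // 0 free, 1 queued, 2 done
  typedef std::pair<double, long long> PK; // (height, push order)
  typedef std::pair<PK, int> QE;           // key, pixel index
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  long long counter = 0;

  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix)
      if (markers(ix, iy) > 0) { lab(ix, iy) = markers(ix, iy); state(ix, iy) = 2; }

  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      if (state(ix, iy) != 2) continue;
      for (int j = 0; j < 4; ++j) {
        int qx = ix + DX4[j], qy = iy + DY4[j];
        if (inside(qx, qy, nx, ny) && state(qx, qy) == 0) {
          state(qx, qy) = 1;
          q.push(QE(PK(relief(qx, qy), counter++), qx + qy * nx));
        }
      }
    }

  while (!q.empty()) {
    int p = q.top().second; q.pop();
    int px = p % nx, py = p / nx;
    if (state(px, py) == 2) continue;
    int found = 0; bool conflict = false;
    for (int j = 0; j < 4; ++j) {
      int qx = px + DX4[j], qy = py + DY4[j];
      if (!inside(qx, qy, nx, ny)) continue;
      int l = lab(qx, qy);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    state(px, py) = 2;
    if (conflict || found == 0) {
      lab(px, py) = 0; // watershed line (found==0 cannot happen in practice)
      continue;
    }
    lab(px, py) = found;
    for (int j = 0; j < 4; ++j) {
      int qx = px + DX4[j], qy = py + DY4[j];
      if (inside(qx, qy, nx, ny) && state(qx, qy) == 0) {
        state(qx, qy) = 1;
        q.push(QE(PK(relief(qx, qy), counter++), qx + qy * nx));
      }
    }
  }
  return lab;
}

// Assign watershed-line (0) pixels to an adjacent basin: repeated sweeps
// taking the smallest positive 4-neighbour label (deterministic tie-break).
// [[Rcpp::export]]
arma::imat cpp_fill_lines(const arma::imat& labels) {
  const int nx = labels.n_rows, ny = labels.n_cols;
  arma::imat lab = labels;
  bool changed = true;
  while (changed) {
    changed = false;
    arma::imat src = lab;
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        if (src(ix, iy) != 0) continue;
        int best = 0;
        for (int j = 0; j < 4; ++j) {
          int qx = ix + DX4[j], qy = iy + DY4[j];
          if (!inside(qx, qy, nx, ny)) continue;
          int l = src(qx, qy);
          if (l > 0 && (best == 0 || l < best)) best = l;
        }
        if (best > 0) { lab(ix, iy) = best; changed = true; }
      }
  }
  return lab;
}
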