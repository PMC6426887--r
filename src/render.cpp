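// Per-pixel nearest / second-nearest cell centre, used to rasterize
// Voronoi mosaics in the synthetic-data generator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// cx, cy: centre coordinates (0-based pixel units).  Returns a list with
// d1, d2 (distances to nearest / second nearest centre) and lab (1-based
// index of the nearest centre), each an nx x ny matrix.
// [[Rcpp::export]]
Rcpp::List cpp_nearest_two(int nx, int ny,
                           const arma::vec& cx, const arma::vec& cy) {
  const int k = cx.n_elem;
  arma::mat d1(nx, ny), d2(nx, ny);
  arma::imat lab(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double b1 = arma::datum::inf, b2 = arma::datum::inf;
      int bi = 0;
      for (int j = 0; j < k; ++j) {
        double dx = ix - cx(j), dy = iy - cy(j);
        double d = dx * dx + dy * dy;
        if (d < b1) { b2 = b1; b1 = d; bi = j + 1; }
        else if (d < b2) { b2 = d; }
      }
      d1(ix, iy) = std::sqrt(b1);
      d2(ix, iy) = std::sqrt(b2);
      lab(ix, iy) = bi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("d1") = d1,
                            Rcpp::Named("d2") = d2,
                            Rcpp::Named("lab") = lab);
}
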