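sq_grid <- function(k, s, origin) {
  g <- expand.grid(x = origin + (0:(k - 1)) * s, y = origin + (0:(k - 1)) * s)
  centroid_set(g)
}

test_that("square-grid Voronoi areas are exact and border cells excluded", {
  cs <- sq_grid(5, 20, 60)   # 5x5 grid well inside a 260x260 frame
  va <- voronoi_areas(cs, c(260, 260))
  expect_equal(sum(!va$is_border), 9)  # interior 3x3
  expect_true(all(abs(va$area[!va$is_border] - 400) < 1e-9))

  est <- estimate_density(cs, c(260, 260), scale_calibration(1))
  expect_true(est$gradable)
  expect_equal(est$cells_per_mm2, 1e6 / 400, tolerance = 1e-12)
  expect_equal(est$n_interior, 9)
  expect_equal(est$n_excluded_border, 16)
})

hex_grid <- function(nr, nc, s, origin) {
  rows <- lapply(0:(nr - 1), function(r) {
    data.frame(x = origin + (0:(nc - 1)) * s + (r %% 2) * s / 2,
               y = origin + r * s * sqrt(3) / 2)
  })
  centroid_set(do.call(rbind, rows))
}

test_that("hexagonal-grid interior areas match the closed form", {
  s <- 21.5
  cs <- hex_grid(11, 11, s, 80)
  va <- voronoi_areas(cs, c(500, 500))
  # the closed form holds for cells with a complete hexagonal neighbourhood;
  # lattice-edge cells (even when frame-bounded) legitimately bulge
  d <- as.matrix(dist(cs$points))
  full_ring <- rowSums(d > 0 & d < 1.01 * s) == 6
  interior <- va$area[!va$is_border & full_ring]
  expect_gt(length(interior), 20)
  expect_lt(max(abs(interior - (sqrt(3) / 2) * s^2)) / ((sqrt(3)/2) * s^2),
            1e-6)
})

test_that("degenerate centroid sets admit no density estimate", {
  # fewer than 4 points
  va3 <- voronoi_areas(centroid_set(data.frame(x = c(1, 5, 9),
                                               y = c(1, 5, 2))), c(20, 20))
  expect_true(all(va3$is_border))
  # collinear points
  vac <- voronoi_areas(centroid_set(data.frame(x = 1:6, y = 2 * (1:6))),
                       c(30, 30))
  expect_true(all(vac$is_border))
  # all centroids on the frame edge
  vae <- voronoi_areas(centroid_set(data.frame(x = c(0, 10, 19, 10),
                                               y = c(10, 0, 10, 19))),
                       c(20, 20))
  expect_true(all(vae$is_border))
  # empty set -> ungradable
  est <- estimate_density(centroid_set(), c(20, 20), scale_calibration(1))
  expect_false(est$gradable)
  expect_true(is.na(est$cells_per_mm2))
})

test_that("density scales dimensionally and is rigid-motion invariant", {
  set.seed(51)
  # frame much larger than the point cloud so no bounded cell can touch it
  base <- data.frame(x = runif(80, 610, 790), y = runif(80, 610, 790))
  est1 <- estimate_density(centroid_set(base), c(1500, 1500),
                           scale_calibration(1))
  k <- 1.7
  estk <- estimate_density(centroid_set(base * k), c(2550, 2550),
                           scale_calibration(1))
  expect_equal(estk$median_area_px2, k^2 * est1$median_area_px2,
               tolerance = 1e-9)
  expect_equal(estk$cells_per_mm2, est1$cells_per_mm2 / k^2,
               tolerance = 1e-9)

  # translation within the large frame
  estt <- estimate_density(centroid_set(base - 300), c(1500, 1500),
                           scale_calibration(1))
  expect_equal(estt$cells_per_mm2, est1$cells_per_mm2, tolerance = 1e-9)

  # 90-degree rotation: (x, y) -> (y, 1499 - x) maps the frame onto itself
  rot <- data.frame(x = base$y, y = 1499 - base$x)
  estr <- estimate_density(centroid_set(rot), c(1500, 1500),
                           scale_calibration(1))
  expect_equal(estr$cells_per_mm2, est1$cells_per_mm2, tolerance = 1e-9)

  # scale calibration enters quadratically
  est2 <- estimate_density(centroid_set(base), c(1500, 1500),
                           scale_calibration(2))
  expect_equal(est2$cells_per_mm2, est1$cells_per_mm2 / 4, tolerance = 1e-12)
})

test_that("the median-based estimate resists a few large-area outliers", {
  s <- 20
  cs <- hex_grid(12, 12, s, 60)
  full <- estimate_density(cs, c(500, 500), scale_calibration(1))
  # deleting ~8% of interior cells inflates their neighbours' areas
  # (a strictly worse perturbation than scaling 8% of areas by 10x)
  set.seed(52)
  keep <- cs$points[-sample(which(!voronoi_areas(cs, c(500, 500))$is_border),
                            10), ]
  thinned <- estimate_density(centroid_set(keep), c(500, 500),
                              scale_calibration(1))
  expect_lt(abs(thinned$cells_per_mm2 - full$cells_per_mm2) /
              full$cells_per_mm2, 0.15)
})

test_that("jittered hexagonal samples reproduce the target density", {
  for (dens in c(1200, 2500)) {
    spec <- mosaic_spec(width = 300, height = 300, target_density = dens,
                        jitter = 0.2, seed = 13)
    pts <- sample_cell_centers(spec)
    inside <- pts[pts$x >= 0 & pts$x <= 299 & pts$y >= 0 & pts$y <= 299, ]
    est <- estimate_density(centroid_set(inside), c(300, 300),
                            scale_calibration(1))
    expect_lt(abs(est$cells_per_mm2 - dens) / dens, 0.05)
  }
})
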