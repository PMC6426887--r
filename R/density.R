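#' Scale calibration
#'
#' Physical pixel pitch of the microscope print.  There is no universal
#' value: it must be supplied by the user (the synthetic generator and the
#' test-suite fixtures use 1 micron/pixel so ground-truth densities are
#' self-consistent).
#'
#' @param microns_per_pixel microns per pixel, > 0.
#' @return An object of class `scale_calibration`.
#' @export
scale_calibration <- function(microns_per_pixel) {
  stopifnot(is.numeric(microns_per_pixel), microns_per_pixel > 0)
  structure(list(microns_per_pixel = microns_per_pixel),
            class = "scale_calibration")
}

# Sutherland-Hodgman clip of a convex polygon by half-plane a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  s <- a * poly[, 1] + b * poly[, 2] - c
  inside <- s <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Voronoi cell areas of a centroid set
#'
#' Computes the planar Voronoi tessellation of the centroids clipped to the
#' image frame (the rectangle from `(0, 0)` to `(width - 1, height - 1)`)
#' and returns each cell's area in square pixels.  A centroid is flagged
#' `is_border` when its Voronoi cell is unbounded or touches the frame: in
#' either case the area is an artifact of the frame and must not enter the
#' density estimate.  Cells are built by intersecting perpendicular-
#' bisector half-planes, with a distance cutoff so only near neighbours are
#' visited.
#'
#' Degenerate inputs (fewer than 4 points, or all points collinear) admit
#' no bounded cell; every centroid is then flagged border and no areas are
#' reported.
#'
#' @param centroids a [centroid_set()].
#' @param frame image frame as `c(width, height)` in pixels.
#' @return A data frame with one row per centroid: `x`, `y`, `area`
#'   (square pixels, `NA` for border cells) and `is_border`.
#' @export
voronoi_areas <- function(centroids, frame) {
  pts <- centroids$points
  n <- nrow(pts)
  w <- frame[1]; h <- frame[2]
  degenerate <- function() {
    data.frame(x = pts$x, y = pts$y, area = rep(NA_real_, n),
               is_border = rep(TRUE, n))
  }
  if (n < 4) return(degenerate())
  cx <- pts$x - mean(pts$x); cy <- pts$y - mean(pts$y)
  if (min(svd(cbind(cx, cy))$d) < 1e-9) return(degenerate())
  rect <- matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1),
                 ncol = 2, byrow = TRUE)
  area <- numeric(n); border <- logical(n)
  P <- as.matrix(pts[, c("x", "y")])
  for (i in seq_len(n)) {
    poly <- rect
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      # bisector of i and j can no longer cut the cell once the neighbour
      # is more than twice as far as the farthest remaining vertex
      if (nrow(poly) == 0) break
      maxv2 <- max((poly[, 1] - P[i, 1])^2 + (poly[, 2] - P[i, 2])^2)
      if (d2[j] > 4 * maxv2) break
      mx <- (P[i, 1] + P[j, 1]) / 2
      my <- (P[i, 2] + P[j, 2]) / 2
      a <- P[j, 1] - P[i, 1]; b <- P[j, 2] - P[i, 2]
      poly <- clip_halfplane(poly, a, b, a * mx + b * my)
    }
    if (nrow(poly) < 3) {
      border[i] <- TRUE
      area[i] <- NA_real_
      next
    }
    eps <- 1e-7
    on_frame <- any(poly[, 1] < eps | poly[, 1] > w - 1 - eps |
                    poly[, 2] < eps | poly[, 2] > h - 1 - eps)
    border[i] <- on_frame
    area[i] <- if (on_frame) NA_real_ else polygon_area(poly)
  }
  data.frame(x = pts$x, y = pts$y, area = area, is_border = border)
}

#' Estimate endothelial cell density from centroids
#'
#' The cell density in cells/mm^2 is the inverse of the median interior
#' Voronoi cell area: border centroids (cells clipped by the frame) are
#' excluded, the median pixel area of the remaining cells is converted to
#' mm^2 via the scale calibration, and inverted.  The median of an even
#' count is the mean of the two central values.  With no interior cell the
#' estimate is ungradable.
#'
#' @param centroids a [centroid_set()].
#' @param frame image frame as `c(width, height)` in pixels.
#' @param scale a [scale_calibration()].
#' @return An object of class `density_estimate`: `cells_per_mm2`,
#'   `median_area_px2`, `n_interior`, `n_excluded_border`, `gradable`.
#' @export
estimate_density <- function(centroids, frame, scale) {
  va <- voronoi_areas(centroids, frame)
  interior <- va$area[!va$is_border]
  n_int <- length(interior)
  if (n_int == 0) {
    est <- list(cells_per_mm2 = NA_real_, median_area_px2 = NA_real_,
                n_interior = 0L, n_excluded_border = sum(va$is_border),
                gradable = FALSE)
  } else {
    med <- median(interior)
    umpp <- scale$microns_per_pixel
    est <- list(cells_per_mm2 = 1e6 / (med * umpp^2),
                median_area_px2 = med, n_interior = n_int,
                n_excluded_border = sum(va$is_border), gradable = TRUE)
  }
  structure(est, class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  if (x$gradable)
    cat(sprintf(
      "<density_estimate: %.0f cells/mm^2 (median area %.1f px^2, %d interior, %d border excluded)>\n",
      x$cells_per_mm2, x$median_area_px2, x$n_interior, x$n_excluded_border))
  else
    cat("<density_estimate: ungradable (no interior cells)>\n")
  invisible(x)
}
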