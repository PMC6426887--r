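#' Synthetic endothelial mosaic specification
#'
#' Describes one synthetic specular-microscopy-like image: a jittered
#' hexagonal cell mosaic rendered as bright polygonal interiors separated
#' by dark Voronoi borders, with per-cell brightness variation, additive
#' Gaussian noise, a linear illumination gradient, optional guttae (dark
#' discs occluding local borders) and an optional contiguous blurred-out
#' region in which no cells are visible (emulating overexposure / edema;
#' `blur_region_fraction = 1` yields a fully ungradable image).  Rendered
#' intensities are quantized to 256 levels, as an 8-bit capture would be.
#'
#' @param width,height frame size in pixels.
#' @param target_density nominal cell density, cells/mm^2.
#' @param microns_per_pixel scale calibration of the synthetic image.
#' @param jitter centre displacement as a fraction of the lattice spacing,
#'   in \[0, 0.5); models pleomorphism.
#' @param border_width rendered border line width, pixels.
#' @param border_darkness intensity drop of border pixels below their cell
#'   interior.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param illumination_gradient total intensity span of the linear
#'   illumination gradient across the frame.
#' @param n_guttae number of guttae discs.
#' @param guttae_radius_range disc radius range, pixels.
#' @param blur_region_fraction fraction of the frame rendered unreadable.
#' @param blur_region_side which edge the unreadable band grows from
#'   (`"bottom"`, `"top"`, `"left"`, `"right"`).
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return An object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(width = 260L, height = 476L, target_density = 2500,
                        microns_per_pixel = 1, jitter = 0.15,
                        border_width = 2, border_darkness = 0.45,
                        noise_sigma = 0.04, illumination_gradient = 0.15,
                        n_guttae = 0L, guttae_radius_range = c(8, 16),
                        blur_region_fraction = 0,
                        blur_region_side = "bottom", seed = 1L) {
  stopifnot(width >= 1, height >= 1, target_density > 0,
            microns_per_pixel > 0, jitter >= 0, jitter < 0.5,
            border_width >= 0, border_darkness > 0, noise_sigma >= 0,
            illumination_gradient >= 0, n_guttae >= 0,
            blur_region_fraction >= 0, blur_region_fraction <= 1,
            blur_region_side %in% c("bottom", "top", "left", "right"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 target_density = target_density,
                 microns_per_pixel = microns_per_pixel, jitter = jitter,
                 border_width = border_width,
                 border_darkness = border_darkness,
                 noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 n_guttae = as.integer(n_guttae),
                 guttae_radius_range = guttae_radius_range,
                 blur_region_fraction = blur_region_fraction,
                 blur_region_side = blur_region_side,
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

#' Lattice spacing for a target density
#'
#' Inverts the hexagonal Voronoi area formula: a hexagonal lattice of
#' spacing `s` has cell area `(sqrt(3)/2) * s^2`, so
#' `s = sqrt(2e6 / (sqrt(3) * density)) / microns_per_pixel` pixels.
#'
#' @param target_density cells/mm^2.
#' @param microns_per_pixel scale calibration.
#' @return Spacing in pixels.
#' @export
hex_spacing <- function(target_density, microns_per_pixel = 1) {
  sqrt(2e6 / (sqrt(3) * target_density)) / microns_per_pixel
}

#' Sample cell centres for a mosaic
#'
#' Jittered hexagonal lattice whose spacing matches the spec's target
#' density; the lattice extends two spacings beyond the frame so boundary
#' cells are shaped like interior ones.  Deterministic given the spec seed.
#'
#' @param spec a [mosaic_spec()].
#' @return Data frame of centre coordinates `x`, `y` (0-based pixels).
#' @export
sample_cell_centers <- function(spec) {
  s <- hex_spacing(spec$target_density, spec$microns_per_pixel)
  if (s < 3) stop(sprintf("density %.0f gives spacing %.2f px (< 3 px)",
                          spec$target_density, s))
  ry <- s * sqrt(3) / 2
  margin <- 2 * s
  ys <- seq(-margin, spec$height - 1 + margin, by = ry)
  pts <- local_seed(spec$seed, {
    rows <- lapply(seq_along(ys), function(r) {
      off <- if (r %% 2 == 0) s / 2 else 0
      xs <- seq(-margin + off, spec$width - 1 + margin, by = s)
      cbind(xs, rep(ys[r], length(xs)))
    })
    p <- do.call(rbind, rows)
    jit <- spec$jitter * s
    if (jit > 0) {
      p[, 1] <- p[, 1] + runif(nrow(p), -jit, jit)
      p[, 2] <- p[, 2] + runif(nrow(p), -jit, jit)
    }
    p
  })
  data.frame(x = pts[, 1], y = pts[, 2])
}

unreadable_band <- function(spec) {
  w <- spec$width; h <- spec$height
  f <- spec$blur_region_fraction
  m <- matrix(FALSE, w, h)
  if (f <= 0) return(m)
  xm <- row(m) - 1; ym <- col(m) - 1
  switch(spec$blur_region_side,
         bottom = m[ym >= (1 - f) * h - 0.5] <- TRUE,
         top    = m[ym <= f * h - 0.5] <- TRUE,
         left   = m[xm <= f * w - 0.5] <- TRUE,
         right  = m[xm >= (1 - f) * w - 0.5] <- TRUE)
  m
}

#' Render a synthetic specular-microscopy image
#'
#' Rasterizes the Voronoi mosaic of the given centres and applies the
#' degradations described by the spec.  The returned sample carries exact
#' ground truth: the centroids of visible cells, the border raster in
#' readable areas, the readable-region mask, and the ground-truth density
#' (computed from the interior Voronoi areas of the visible centroids, so
#' truth and estimate share one geometric definition).
#'
#' @param points centre data frame from [sample_cell_centers()].
#' @param spec a [mosaic_spec()].
#' @return An object of class `synthetic_sample` with fields `image`,
#'   `truth_centroids`, `truth_borders`, `truth_density`, `readable_mask`
#'   and `spec`.
#' @export
render_mosaic <- function(points, spec) {
  w <- spec$width; h <- spec$height
  s <- hex_spacing(spec$target_density, spec$microns_per_pixel)
  nt <- cpp_nearest_two(w, h, points$x, points$y)
  border <- (nt$d2 - nt$d1) <= spec$border_width

  rng <- local_seed(spec$seed + 1L, {
    list(cell_b = pmin(pmax(0.78 + rnorm(nrow(points), 0, 0.06),
                            0.62), 0.94),
         gut_x = runif(spec$n_guttae, 0, w - 1),
         gut_y = runif(spec$n_guttae, 0, h - 1),
         gut_r = runif(spec$n_guttae, spec$guttae_radius_range[1],
                       spec$guttae_radius_range[2]),
         noise = matrix(rnorm(w * h, 0, spec$noise_sigma), w, h))
  })

  img <- matrix(rng$cell_b[nt$lab], w, h)
  img[border] <- img[border] - spec$border_darkness

  unreadable <- unreadable_band(spec)
  if (any(unreadable)) img[unreadable] <- 0.68

  gut_mask <- matrix(FALSE, w, h)
  if (spec$n_guttae > 0) {
    xm <- row(img) - 1; ym <- col(img) - 1
    for (g in seq_len(spec$n_guttae)) {
      d2 <- (xm - rng$gut_x[g])^2 + (ym - rng$gut_y[g])^2
      inside <- d2 <= rng$gut_r[g]^2
      img[inside] <- 0.12
      gut_mask <- gut_mask | inside
    }
  }

  if (spec$illumination_gradient > 0) {
    xm <- row(img) - 1
    img <- img + spec$illumination_gradient * (xm / max(w - 1, 1) - 0.5)
  }
  img <- img + rng$noise
  img <- pmin(pmax(img, 0.02), 1)
  img <- round(img * 255) / 255

  readable <- !(unreadable | gut_mask)

  inside_frame <- points$x >= 0 & points$x <= w - 1 &
                  points$y >= 0 & points$y <= h - 1
  px <- pmin(pmax(round(points$x), 0), w - 1) + 1L
  py <- pmin(pmax(round(points$y), 0), h - 1) + 1L
  vis <- inside_frame & readable[cbind(px, py)]
  if (any(!readable)) {
    # require a clear margin so partially obscured cells are not dotted
    Dr <- EBImage::imageData(EBImage::distmap(EBImage::Image(readable * 1)))
    vis <- vis & Dr[cbind(px, py)] > 0.35 * s
  }
  truth <- centroid_set(points[vis, c("x", "y")],
                        image_id = sprintf("synth_seed%d", spec$seed))

  est <- estimate_density(truth, c(w, h),
                          scale_calibration(spec$microns_per_pixel))
  structure(list(
    image = gray_image(img, id = truth$image_id),
    truth_centroids = truth,
    truth_borders = border_label_map((border & readable) * 1L,
                                     image_id = truth$image_id),
    truth_density = est$cells_per_mm2,
    readable_mask = readable * 1L,
    spec = spec), class = "synthetic_sample")
}

#' Generate a synthetic sample in one call
#'
#' @param spec a [mosaic_spec()].
#' @return A `synthetic_sample`, see [render_mosaic()].
#' @export
synthetic_sample <- function(spec = mosaic_spec()) {
  render_mosaic(sample_cell_centers(spec), spec)
}

#' Generate a synthetic image corpus on disk
#'
#' Writes `n` synthetic samples in the package's corpus layout:
#' `images/*.png`, per-image centroid CSVs under `centroids/`, border
#' label maps under `borders/`, a `manifest.csv`
#' (`image_id,split,ungradable,guttae,annotation_path`) and a
#' `truth.csv` sidecar with generator ground truth (target and realized
#' density, centroid count, blur fraction).  A fixed fraction of samples
#' (rounded to the nearest count) is rendered fully ungradable
#' (`blur_region_fraction = 1`, empty annotation); a further fraction gets
#' a partial unreadable band; some samples receive guttae.  Densities are
#' drawn uniformly across `density_range`.  Byte-identical outputs for the
#' same seed.
#'
#' @param n number of images.
#' @param out_dir output directory (created).
#' @param density_range range of target densities, cells/mm^2.
#' @param ungradable_fraction fraction of fully ungradable samples.
#' @param partial_blur_fraction fraction of the gradable samples receiving
#'   a partial unreadable band.
#' @param partial_blur_size band size as fraction of the frame.
#' @param guttae_fraction fraction of gradable samples with guttae.
#' @param width,height frame size in pixels.
#' @param microns_per_pixel scale calibration.
#' @param jitter lattice jitter fraction.
#' @param seed integer master seed (per-sample seeds are derived from it).
#' @return A list with `manifest` (a [corpus_manifest()]), `truth` (the
#'   sidecar data frame) and `dir`.
#' @export
generate_corpus <- function(n, out_dir, density_range = c(500, 3000),
                            ungradable_fraction = 0.1,
                            partial_blur_fraction = 0.2,
                            partial_blur_size = 0.3,
                            guttae_fraction = 0.3,
                            width = 260L, height = 476L,
                            microns_per_pixel = 1, jitter = 0.15,
                            seed = 1L) {
  stopifnot(n >= 1)
  for (d in c("images", "centroids", "borders"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  n_ungr <- round(ungradable_fraction * n)
  draw <- local_seed(seed, {
    list(dens = runif(n, density_range[1], density_range[2]),
         seeds = sample.int(2^30, n),
         ungr = sample.int(n, n_ungr),
         u = runif(n), v = runif(n), ng = sample(0:3, n, replace = TRUE))
  })
  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("synth_%03d", i)
    ungr <- i %in% draw$ungr
    blur <- if (ungr) 1 else if (draw$u[i] < partial_blur_fraction)
      partial_blur_size else 0
    guttae <- !ungr && draw$v[i] < guttae_fraction && draw$ng[i] > 0
    spec <- mosaic_spec(width = width, height = height,
                        target_density = draw$dens[i],
                        microns_per_pixel = microns_per_pixel,
                        jitter = jitter,
                        n_guttae = if (guttae) draw$ng[i] else 0L,
                        blur_region_fraction = blur,
                        seed = draw$seeds[i])
    smp <- synthetic_sample(spec)
    smp$image$id <- id
    smp$truth_centroids$image_id <- id
    ann <- file.path("centroids", paste0(id, ".csv"))
    write_image(smp$image, file.path(out_dir, "images", paste0(id, ".png")))
    write_centroids(smp$truth_centroids, file.path(out_dir, ann))
    write_image(gray_image(smp$truth_borders$mask + 0),
                file.path(out_dir, "borders", paste0(id, ".png")))
    rows[[i]] <- data.frame(image_id = id, split = "validation",
                            ungradable = ungr || n_centroids(smp$truth_centroids) == 0,
                            guttae = guttae, annotation_path = ann,
                            stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(image_id = id,
                                  target_density = draw$dens[i],
                                  truth_density = smp$truth_density,
                                  n_truth = n_centroids(smp$truth_centroids),
                                  blur_fraction = blur,
                                  stringsAsFactors = FALSE)
  }
  manifest <- corpus_manifest(do.call(rbind, rows))
  truth <- do.call(rbind, truth_rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  list(manifest = manifest, truth = truth, dir = out_dir)
}
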