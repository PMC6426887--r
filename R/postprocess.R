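#' Post-processing parameters
#'
#' @param prob_threshold probability above which a pixel is classified as
#'   cell border.
#' @param min_object_px connected border objects smaller than this pixel
#'   count are removed as noise / ambiguous-border areas.
#' @param min_peak_separation optional minimum distance (pixels) between
#'   extracted centroids; centroids closer than this to a stronger one are
#'   suppressed.  `0` disables the suppression.
#' @return An object of class `postprocess_params`.
#' @export
postprocess_params <- function(prob_threshold = 0.60, min_object_px = 1000L,
                               min_peak_separation = 0) {
  stopifnot(prob_threshold > 0, prob_threshold < 1, min_object_px >= 1,
            min_peak_separation >= 0)
  structure(list(prob_threshold = prob_threshold,
                 min_object_px = as.integer(min_object_px),
                 min_peak_separation = min_peak_separation),
            class = "postprocess_params")
}

#' Threshold a probability map
#'
#' Pixels with border probability greater than or equal to
#' `prob_threshold` become border-class pixels.  Raising the threshold
#' never adds foreground.
#'
#' @param pm a [probability_map()].
#' @param params a [postprocess_params()].
#' @return A [border_label_map()].
#' @export
binarize <- function(pm, params = postprocess_params()) {
  border_label_map((pm$probs >= params$prob_threshold) * 1L,
                   image_id = pm$image_id)
}

#' Remove small border objects
#'
#' Deletes 8-connected foreground components with strictly fewer than
#' `min_object_px` pixels; larger components are untouched.  The operation
#' is idempotent.
#'
#' @param mask a [border_label_map()].
#' @param params a [postprocess_params()].
#' @return The cleaned [border_label_map()].
#' @export
remove_small_objects <- function(mask, params = postprocess_params()) {
  lab <- label_components(mask$mask, conn = 8L)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_object_px)
  cleaned <- matrix((lab %in% keep) * 1L, nrow(mask$mask), ncol(mask$mask))
  border_label_map(cleaned, image_id = mask$image_id)
}

#' Segmentation result
#'
#' @param centroids extracted [centroid_set()].
#' @param border_mask cleaned [border_label_map()].
#' @param cell_regions integer raster labelling detected cell regions
#'   (0 = unassigned).
#' @param gradable logical; an output with zero extracted centroids is
#'   ungradable.
#' @return An object of class `segmentation_result`.
#' @export
segmentation_result <- function(centroids, border_mask, cell_regions,
                                gradable = n_centroids(centroids) > 0) {
  stopifnot(gradable == (n_centroids(centroids) > 0))
  structure(list(centroids = centroids, border_mask = border_mask,
                 cell_regions = cell_regions, gradable = gradable),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result '%s': %d centroids, %s>\n",
              x$centroids$image_id, n_centroids(x$centroids),
              if (x$gradable) "gradable" else "ungradable"))
  invisible(x)
}

# per-region centroid at the distance-map maximum: the plateau of maximal
# value containing the smallest (y, x) pixel wins; its centre of mass is
# reported, snapped to the nearest plateau pixel if the rounded centre
# falls off the plateau.  Returns a data.frame (x, y, peak) 0-based.
region_peak_centroids <- function(D, regions) {
  ids <- sort(unique(regions[regions > 0L]))
  if (length(ids) == 0)
    return(data.frame(x = numeric(), y = numeric(), peak = numeric()))
  nx <- nrow(D)
  res <- lapply(ids, function(id) {
    p <- which(regions == id)
    d <- D[p]
    dmax <- max(d)
    top <- p[d == dmax]
    # column-major linear order sorts by (y, x) here (columns are y), so
    # the first element of `top` is the smallest-(y, x) maximal pixel
    tm <- matrix(0L, nx, ncol(D))
    tm[top] <- 1L
    plat <- label_components(tm, conn = 8L)
    sel <- plat[top[1L]]
    pp <- which(plat == sel)
    cx <- (pp - 1L) %% nx
    cy <- (pp - 1L) %/% nx
    gx <- mean(cx); gy <- mean(cy)
    ip <- round(gx) + round(gy) * nx + 1L
    if (!(ip %in% pp)) {
      j <- which.min((cx - gx)^2 + (cy - gy)^2)
      gx <- cx[j]; gy <- cy[j]
    }
    c(gx, gy, dmax)
  })
  res <- do.call(rbind, res)
  data.frame(x = res[, 1], y = res[, 2], peak = res[, 3])
}

# Euclidean distance of every non-border pixel to the nearest retained
# border pixel (border pixels themselves are 0).
border_distance_map <- function(mask, pad_frame = FALSE) {
  fg <- 1 - mask
  if (pad_frame) {
    nx <- nrow(fg); ny <- ncol(fg)
    padded <- matrix(0, nx + 2L, ny + 2L)
    padded[2:(nx + 1L), 2:(ny + 1L)] <- fg
    D <- EBImage::imageData(EBImage::distmap(EBImage::Image(padded)))
    D <- D[2:(nx + 1L), 2:(ny + 1L)]
  } else {
    D <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg)))
  }
  D[!is.finite(D)] <- sqrt(nrow(fg)^2 + ncol(fg)^2)
  D
}

#' Extract cell centroids from a cleaned border mask
#'
#' Computes the Euclidean distance map of the non-border class (distance to
#' the nearest retained border pixel), labels candidate cell regions as the
#' 4-connected components of the border-mask complement, discards regions
#' that touch the image frame or whose boundary is not at least half
#' covered by retained border pixels (these are the open surround left
#' after poor-quality areas were removed), and places one centroid per
#' surviving region at the maximum of the distance map.  An output with no
#' centroids is flagged ungradable.
#'
#' @param mask the cleaned [border_label_map()].
#' @param params a [postprocess_params()].
#' @return A [segmentation_result()].
#' @export
extract_centroids <- function(mask, params = postprocess_params()) {
  m <- mask$mask
  nx <- nrow(m); ny <- ncol(m)
  empty <- function() {
    segmentation_result(centroid_set(image_id = mask$image_id), mask,
                        matrix(0L, nx, ny))
  }
  if (all(m == 0L) || all(m == 1L)) return(empty())
  regions <- label_components(1L - m, conn = 4L)

  # frame-touching regions
  frame_ids <- unique(c(regions[1, ], regions[nx, ], regions[, 1],
                        regions[, ny]))
  frame_ids <- frame_ids[frame_ids > 0L]

  # boundary pixels: region pixels with a 4-neighbour outside the region
  pad <- function(mm, dx, dy) {
    out <- matrix(-1L, nx, ny)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    ok_x <- xs >= 1L & xs <= nx; ok_y <- ys >= 1L & ys <= ny
    out[ok_x, ok_y] <- mm[xs[ok_x], ys[ok_y]]
    out
  }
  differs <- (pad(regions, 1L, 0L) != regions) |
             (pad(regions, -1L, 0L) != regions) |
             (pad(regions, 0L, 1L) != regions) |
             (pad(regions, 0L, -1L) != regions)
  is_boundary <- regions > 0L & differs
  near_border <- gray_dilate(m + 0,
                             cbind(rep(-1:1, 3), rep(-1:1, each = 3))) > 0
  bnd_ids <- regions[is_boundary]
  covered <- near_border[is_boundary]
  n_bnd <- tapply(rep(1L, length(bnd_ids)), bnd_ids, sum)
  n_cov <- tapply(covered * 1L, bnd_ids, sum)
  frac <- rep(0, max(regions))
  frac[as.integer(names(n_bnd))] <- as.numeric(n_cov) / as.numeric(n_bnd)
  keep <- setdiff(which(frac >= 0.5), frame_ids)
  if (length(keep) == 0) return(empty())

  kept <- matrix(0L, nx, ny)
  sel <- regions %in% keep
  kept[sel] <- match(regions[sel], keep)

  D <- border_distance_map(m)
  pts <- region_peak_centroids(D, kept)
  if (nrow(pts) > 0 && params$min_peak_separation > 0) {
    ord <- order(-pts$peak, pts$y, pts$x)
    taken <- rep(TRUE, nrow(pts))
    for (i in seq_along(ord)) {
      if (!taken[ord[i]]) next
      for (j in if (i < length(ord)) (i + 1):length(ord) else integer()) {
        d <- sqrt((pts$x[ord[i]] - pts$x[ord[j]])^2 +
                  (pts$y[ord[i]] - pts$y[ord[j]])^2)
        if (d < params$min_peak_separation) taken[ord[j]] <- FALSE
      }
    }
    pts <- pts[taken, , drop = FALSE]
  }
  segmentation_result(centroid_set(pts[, c("x", "y")],
                                   image_id = mask$image_id),
                      mask, kept)
}

#' Full post-processing of a probability map
#'
#' Threshold, small-object removal and centroid extraction in one call.
#'
#' @param pm a [probability_map()].
#' @param params a [postprocess_params()].
#' @return A [segmentation_result()].
#' @export
postprocess_probability_map <- function(pm, params = postprocess_params()) {
  extract_centroids(remove_small_objects(binarize(pm, params), params),
                    params)
}
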