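#' Parameters of the classical watershed baseline
#'
#' Vincent-style marker-driven watershed segmentation: noise is removed
#' with an alternating sequential filter (disc openings and closings of
#' increasing radius), cell peaks are isolated with the h-dome transform,
#' the regional maxima of the dome image become markers, and the inverted
#' filtered image is flooded from those markers.
#'
#' @param asf_max_radius largest disc radius of the alternating sequential
#'   filter.
#' @param hdome_h dome height on \[0, 1\] intensities.
#' @param min_marker_px regional-maxima plateaus smaller than this pixel
#'   count are discarded as noise markers.
#' @return An object of class `vincent_params`.
#' @export
vincent_params <- function(asf_max_radius = 1L, hdome_h = 0.02,
                           min_marker_px = 3L) {
  stopifnot(asf_max_radius >= 1, hdome_h > 0, hdome_h < 1, min_marker_px >= 1)
  structure(list(asf_max_radius = as.integer(asf_max_radius),
                 hdome_h = hdome_h,
                 min_marker_px = as.integer(min_marker_px)),
            class = "vincent_params")
}

#' Alternating sequential filter
#'
#' Applies `open_r` then `close_r` with disc structuring elements for
#' r = 1, ..., `asf_max_radius`, in increasing order.
#'
#' @param img a [gray_image()].
#' @param params a [vincent_params()].
#' @return The filtered [gray_image()].
#' @export
asf_filter <- function(img, params = vincent_params()) {
  px <- as_pixel_matrix(img)
  for (r in seq_len(params$asf_max_radius)) {
    se <- disc_se(r)
    px <- gray_close(gray_open(px, se), se)
  }
  gray_image(pmin(pmax(px, 0), 1), id = img_id(img))
}

#' h-dome transform
#'
#' `hdome(f) = f - Rec_f(f - h)`, where `Rec` is grayscale reconstruction
#' by dilation.  Isolated peaks of height H produce domes of height
#' `min(H, h)`; the output is pointwise in \[0, h\].
#'
#' @inheritParams asf_filter
#' @return A [gray_image()]-shaped matrix of dome heights.
#' @export
hdome <- function(img, params = vincent_params()) {
  px <- as_pixel_matrix(img)
  px - cpp_reconstruct(px - params$hdome_h, px)
}

#' Extract watershed markers via the h-dome decomposition
#'
#' The h-dome transform splits the filtered image into its reconstruction
#' `Rec_f(f - h)` plus the dome residue.  Markers are the regional-maxima
#' plateaus of the reconstruction (8-connected): sub-peaks separated by
#' dips shallower than `h` merge into a single marker, which is what makes
#' `h` the significance scale of the marker extraction.  Plateaus smaller
#' than `min_marker_px` are discarded; every surviving plateau becomes one
#' labeled marker component, summarized by its centre of mass.
#'
#' @param img the ASF-filtered [gray_image()].
#' @param params a [vincent_params()].
#' @return A list with `markers` (integer raster, one positive label per
#'   marker) and `centroids` (a [centroid_set()] of marker centres).
#' @export
vincent_markers <- function(img, params = vincent_params()) {
  px <- as_pixel_matrix(img)
  # the h-dome's complement under f: peaks separated by dips shallower
  # than h merge into one plateau of the reconstruction, so each cell
  # contributes one marker instead of one per sub-peak
  hmax <- cpp_reconstruct(px - params$hdome_h, px)
  rm_lab <- cpp_regional_maxima(hmax, 8L)
  ids <- sort(unique(rm_lab[rm_lab > 0L]))
  if (length(ids)) {
    sizes <- tabulate(rm_lab[rm_lab > 0L])
    keep <- which(sizes >= params$min_marker_px)
    sel <- rm_lab %in% keep
    out <- matrix(0L, nrow(rm_lab), ncol(rm_lab))
    out[sel] <- match(rm_lab[sel], keep)
    rm_lab <- out
    ids <- seq_len(length(keep))
  }
  nx <- nrow(rm_lab)
  pts <- if (length(ids)) {
    p <- which(rm_lab > 0L)
    cx <- (p - 1L) %% nx
    cy <- (p - 1L) %/% nx
    data.frame(x = as.numeric(tapply(cx, rm_lab[p], mean)),
               y = as.numeric(tapply(cy, rm_lab[p], mean)))
  } else data.frame(x = numeric(), y = numeric())
  list(markers = rm_lab, centroids = centroid_set(pts, image_id = img_id(img)))
}

#' Classical watershed segmentation of a specular image
#'
#' Runs the full baseline: ASF filtering, h-dome marker extraction, and
#' marker-constrained watershed of the inverted filtered image.  Every
#' marker produces one region; each region's centroid is placed at the
#' maximum of its distance map (distance to the nearest watershed line or
#' to the frame), the same convention as the U-Net post-processing.  With
#' no markers the result is ungradable.
#'
#' Unlike the U-Net pipeline this method has no mechanism to reject
#' poor-quality areas, so it reports (spurious) cells there as well.
#'
#' @param img a [gray_image()] (raw or ASF-filtered input is accepted; the
#'   filter is applied internally).
#' @param params a [vincent_params()].
#' @return A [segmentation_result()]; `cell_regions` partitions the full
#'   frame (watershed-line pixels are merged into adjacent basins with a
#'   deterministic smallest-label tie-break).
#' @export
vincent_segment <- function(img, params = vincent_params()) {
  f <- asf_filter(img, params)
  mk <- vincent_markers(f, params)
  nx <- nrow(f$pixels); ny <- ncol(f$pixels)
  if (max(mk$markers) == 0L) {
    return(segmentation_result(centroid_set(image_id = img_id(img)),
                               border_label_map(matrix(0L, nx, ny),
                                                image_id = img_id(img)),
                               matrix(0L, nx, ny)))
  }
  labels0 <- cpp_watershed(1 - f$pixels, mk$markers)
  lines <- (labels0 == 0L) * 1L
  regions <- cpp_fill_lines(labels0)
  D <- border_distance_map(lines, pad_frame = TRUE)
  pts <- region_peak_centroids(D, regions)
  segmentation_result(centroid_set(pts[, c("x", "y")],
                                   image_id = img_id(img)),
                      border_label_map(lines, image_id = img_id(img)),
                      regions)
}
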