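#' Disc structuring element
#'
#' Offsets `(dx, dy)` with `dx^2 + dy^2 <= r^2`, the flat disc used by the
#' top-hat and the alternating sequential filter.
#'
#' @param r disc radius in pixels; radius 0 gives the single-pixel element.
#' @return Integer matrix of offsets, one `(dx, dy)` row per element pixel.
#' @export
disc_se <- function(r) {
  r <- as.integer(r)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

se_matrix <- function(se) {
  se <- as.matrix(se)
  storage.mode(se) <- "integer"
  se
}

#' Flat grayscale erosion / dilation / opening / closing
#'
#' Erosion takes the minimum (dilation the maximum) of the image over the
#' structuring-element offsets that fall inside the frame; opening is
#' erosion followed by dilation, closing the reverse.  These primitives
#' back the top-hat and the alternating sequential filter of the classical
#' watershed baseline.
#'
#' @param px numeric matrix (or [gray_image()]).
#' @param se structuring element as an offset matrix, see [disc_se()].
#' @return A numeric matrix of the same dimensions.
#' @export
gray_erode <- function(px, se) {
  cpp_erode(as_pixel_matrix(px), se_matrix(se))
}

#' @rdname gray_erode
#' @export
gray_dilate <- function(px, se) {
  cpp_dilate(as_pixel_matrix(px), se_matrix(se))
}

#' @rdname gray_erode
#' @export
gray_open <- function(px, se) {
  se <- se_matrix(se)
  cpp_dilate(cpp_erode(as_pixel_matrix(px), se), -se)
}

#' @rdname gray_erode
#' @export
gray_close <- function(px, se) {
  se <- se_matrix(se)
  cpp_erode(cpp_dilate(as_pixel_matrix(px), se), -se)
}

#' Grayscale reconstruction by dilation
#'
#' Iteratively dilates `marker` (8-connected) while keeping it below
#' `mask`, until stability.  Used by the h-dome transform.
#'
#' @param marker,mask numeric matrices with `marker <= mask` pointwise
#'   (the marker is clipped to the mask internally).
#' @return The reconstructed matrix.
#' @export
gray_reconstruct <- function(marker, mask) {
  cpp_reconstruct(as_pixel_matrix(marker), as_pixel_matrix(mask))
}

#' Regional maxima
#'
#' Labels connected plateaus that are strictly greater than every adjacent
#' pixel.  A plateau spanning the entire frame (a constant image) yields no
#' maxima, preventing a degenerate whole-image marker.
#'
#' @param px numeric matrix (or [gray_image()]).
#' @param conn plateau connectivity, 4 or 8.
#' @return Integer matrix: positive plateau labels on maxima, 0 elsewhere.
#' @export
regional_maxima <- function(px, conn = 8L) {
  stopifnot(conn %in% c(4L, 8L))
  cpp_regional_maxima(as_pixel_matrix(px), as.integer(conn))
}

#' Connected-component labelling
#'
#' @param mask logical or 0/1 matrix.
#' @param conn connectivity, 4 or 8.
#' @return Integer label matrix (0 = background), labels in column-major
#'   order of first encounter.
#' @export
label_components <- function(mask, conn = 8L) {
  stopifnot(conn %in% c(4L, 8L))
  m <- mask * 1L
  storage.mode(m) <- "integer"
  cpp_label(m, as.integer(conn))
}

#' Marker-constrained watershed
#'
#' Meyer's flooding of the relief from the given markers: basins grow
#' 4-connectedly in order of increasing relief height (FIFO among equal
#' heights, so the result is deterministic), and pixels where distinct
#' basins meet become watershed-line pixels.
#'
#' @param relief numeric matrix of heights to flood.
#' @param markers integer matrix; positive values label marker pixels,
#'   0 elsewhere.  Marker pixels keep their label.
#' @return Integer matrix of basin labels with 0 on watershed lines.
#' @export
marker_watershed <- function(relief, markers) {
  relief <- as_pixel_matrix(relief)
  storage.mode(markers) <- "integer"
  stopifnot(identical(dim(relief), dim(markers)))
  cpp_watershed(relief, markers)
}
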