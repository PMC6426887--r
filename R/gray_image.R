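#' Grayscale image container
#'
#' A `gray_image` wraps a numeric pixel matrix with intensities in \[0, 1\].
#' The matrix uses the same orientation as `EBImage`: element
#' `pixels[x + 1, y + 1]` is the pixel at 0-based column `x` (from the left)
#' and row `y` (from the top), so `nrow(pixels)` is the image width and
#' `ncol(pixels)` the height.  Centroid coordinates used throughout the
#' package are 0-based `(x, y)` in this convention and may be sub-pixel.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param id opaque image identifier.
#' @return An object of class `gray_image` with fields `pixels` and `id`.
#' @export
gray_image <- function(pixels, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  structure(list(pixels = pixels, id = as.character(id)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s' %dx%d px, range [%.3f, %.3f]>\n",
              x$id, image_width(x), image_height(x),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Image dimensions
#'
#' @param img a `gray_image`.
#' @return Width (or height) in pixels.
#' @export
image_width <- function(img) nrow(img$pixels)

#' @rdname image_width
#' @export
image_height <- function(img) ncol(img$pixels)

as_pixel_matrix <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a gray_image or a numeric matrix")
}

#' Read a grayscale image from disk
#'
#' Reads an 8- or 16-bit PNG or TIFF image and linearly rescales intensities
#' to \[0, 1\].  Color inputs are converted to grayscale by Rec. 601
#' luminance (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path path to a PNG or TIFF file.
#' @param id image identifier; defaults to the file name without extension.
#' @return A [gray_image()].
#' @export
read_image <- function(path, id = NULL) {
  if (!file.exists(path))
    stop(sprintf("image file does not exist: '%s'", path))
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop(sprintf("cannot read image '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    px <- if (nch >= 3L)
      0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
    else px[, , 1L]
  }
  px <- pmin(pmax(px, 0), 1)
  if (is.null(id))
    id <- sub("\\.[^.]+$", "", basename(path))
  gray_image(matrix(px, nrow = dim(px)[1L]), id = id)
}

#' Write a grayscale image to disk
#'
#' Writes an 8-bit PNG or TIFF depending on the file extension.
#'
#' @param img a [gray_image()].
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixel_matrix(img)
  ext <- tolower(sub(".*\\.", "", path))
  type <- switch(ext, png = "png", tif = , tiff = "tiff",
                 stop(sprintf("unsupported image extension '.%s'", ext)))
  EBImage::writeImage(EBImage::Image(px), path, type = type,
                      bits.per.sample = 8L)
  invisible(path)
}
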