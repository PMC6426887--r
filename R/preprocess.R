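#' Preprocessing parameters
#'
#' The fixed preprocessing chain applied before both training-label
#' synthesis and inference is Gaussian blur, then grayscale white top-hat,
#' then histogram equalization.
#'
#' The blur is parameterized by `blur_sigma` (standard deviation, pixels);
#' the kernel half-width is `max(blur_radius, ceiling(3 * blur_sigma))`, so
#' sigma governs the effective support and `blur_radius` is advisory.  The
#' top-hat uses a disc structuring element whose radius must exceed the
#' typical cell radius so that the operation flattens illumination
#' gradients at scales above the cell mosaic rather than erasing cells.
#'
#' @param blur_radius advisory blur kernel radius in pixels.
#' @param blur_sigma Gaussian standard deviation in pixels.
#' @param tophat_radius disc radius (pixels) of the top-hat structuring
#'   element; about one typical cell diameter.
#' @param equalize_bins number of histogram bins for equalization.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(blur_radius = 1, blur_sigma = 2,
                              tophat_radius = 15, equalize_bins = 256) {
  stopifnot(blur_radius >= 0, blur_sigma > 0, tophat_radius >= 0,
            equalize_bins >= 2)
  structure(list(blur_radius = blur_radius, blur_sigma = blur_sigma,
                 tophat_radius = tophat_radius,
                 equalize_bins = as.integer(equalize_bins)),
            class = "preprocess_params")
}

# symmetric (half-sample mirror) padding indices for length n, pad h
sym_pad_index <- function(n, h) {
  if (h == 0) return(seq_len(n))
  left <- pmin(pmax(h:1, 1L), n)
  right <- pmin(pmax(n:(n - h + 1L), 1L), n)
  c(left, seq_len(n), right)
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with a normalized kernel and symmetric
#' (mirror) boundary padding, which preserves the image mean exactly for
#' the symmetric kernel.
#'
#' @param img a [gray_image()].
#' @param params a [preprocess_params()].
#' @return A blurred [gray_image()] of identical dimensions.
#' @export
gaussian_blur <- function(img, params = preprocess_params()) {
  px <- as_pixel_matrix(img)
  h <- max(params$blur_radius, ceiling(3 * params$blur_sigma))
  k <- exp(-((-h:h)^2) / (2 * params$blur_sigma^2))
  k <- k / sum(k)
  out <- convolve_sep(px, k)
  gray_image(pmin(pmax(out, 0), 1), id = img_id(img))
}

img_id <- function(img) if (inherits(img, "gray_image")) img$id else "image"

# separable 1-D convolution along both axes with symmetric padding
convolve_sep <- function(px, k) {
  h <- (length(k) - 1L) %/% 2L
  nx <- nrow(px); ny <- ncol(px)
  p1 <- px[sym_pad_index(nx, h), , drop = FALSE]
  out <- matrix(0, nx, ny)
  for (j in seq_along(k))
    out <- out + k[j] * p1[(j - 1L) + seq_len(nx), , drop = FALSE]
  p2 <- out[, sym_pad_index(ny, h), drop = FALSE]
  out <- matrix(0, nx, ny)
  for (j in seq_along(k))
    out <- out + k[j] * p2[, (j - 1L) + seq_len(ny), drop = FALSE]
  out
}

#' Grayscale white top-hat
#'
#' Subtracts the morphological opening (disc structuring element of radius
#' `tophat_radius`) from the image, removing background structure larger
#' than the disc; the output is non-negative and pointwise no larger than
#' the input.
#'
#' @inheritParams gaussian_blur
#' @return A [gray_image()] of identical dimensions.
#' @export
top_hat <- function(img, params = preprocess_params()) {
  px <- as_pixel_matrix(img)
  opened <- gray_open(px, disc_se(params$tophat_radius))
  gray_image(pmin(pmax(px - opened, 0), 1), id = img_id(img))
}

#' Histogram equalization
#'
#' Maps each intensity to its empirical CDF value computed on
#' `equalize_bins` bins over \[0, 1\].  The mapping is monotone, so the rank
#' order of distinct intensities is preserved; a constant image is returned
#' unchanged.
#'
#' @inheritParams gaussian_blur
#' @return A [gray_image()] with an approximately uniform intensity
#'   histogram.
#' @export
equalize_hist <- function(img, params = preprocess_params()) {
  px <- as_pixel_matrix(img)
  if (diff(range(px)) == 0)
    return(gray_image(px, id = img_id(img)))
  nb <- params$equalize_bins
  bin <- pmin(floor(px * nb) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  cdf <- cumsum(counts) / length(px)
  out <- matrix(cdf[bin], nrow(px), ncol(px))
  gray_image(out, id = img_id(img))
}

#' Full preprocessing chain
#'
#' Gaussian blur, white top-hat, histogram equalization, in that order.
#' Every stage preserves the image dimensions and maps \[0, 1\] into
#' \[0, 1\].
#'
#' @inheritParams gaussian_blur
#' @return The preprocessed [gray_image()].
#' @export
preprocess <- function(img, params = preprocess_params()) {
  equalize_hist(top_hat(gaussian_blur(img, params), params), params)
}
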