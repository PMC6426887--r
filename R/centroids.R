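#' Centroid set
#'
#' Stores the per-image list of cell-center coordinates, either from expert
#' dotting or from automated extraction.  Coordinates are 0-based `(x, y)`
#' pixel positions (x = column from the left, y = row from the top) and may
#' be sub-pixel.
#'
#' @param points data frame (or matrix) with numeric columns `x` and `y`.
#' @param image_id identifier of the image the points belong to.
#' @return An object of class `centroid_set` with fields `image_id` and
#'   `points`.
#' @export
centroid_set <- function(points = data.frame(x = numeric(), y = numeric()),
                         image_id = "image") {
  points <- as.data.frame(points)
  if (nrow(points) > 0) {
    if (!all(c("x", "y") %in% names(points)))
      stop("centroid table must have columns `x` and `y`")
    points <- data.frame(x = as.numeric(points$x), y = as.numeric(points$y))
    if (anyNA(points$x) || anyNA(points$y))
      stop("centroid coordinates must be numeric and non-missing")
    if (anyDuplicated(points))
      stop("duplicate centroid rows: ",
           paste(which(duplicated(points)), collapse = ", "))
  } else {
    points <- data.frame(x = numeric(), y = numeric())
  }
  structure(list(image_id = as.character(image_id), points = points),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set '%s': %d points>\n", x$image_id, n_centroids(x)))
  invisible(x)
}

#' Number of centroids in a set
#' @param cs a [centroid_set()].
#' @export
n_centroids <- function(cs) nrow(cs$points)

#' Read expert centroid annotations
#'
#' Reads a centroid CSV (columns `image_id,x,y`, one row per dotted cell)
#' and validates every point against the image bounds.  An empty table is a
#' valid annotation for an ungradable image.
#'
#' @param path path to the centroid CSV.
#' @param image the [gray_image()] the annotations belong to, used for
#'   bounds validation.
#' @return A [centroid_set()].
#' @export
read_centroids <- function(path, image) {
  if (!file.exists(path))
    stop(sprintf("centroid file does not exist: '%s'", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    return(centroid_set(image_id = image$id))
  if (!all(c("x", "y") %in% names(tab)))
    stop(sprintf("'%s' must have columns x and y", path))
  w <- image_width(image); h <- image_height(image)
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y) |
                 tab$x < 0 | tab$x > w - 1 | tab$y < 0 | tab$y > h - 1)
  if (length(bad))
    stop(sprintf("centroids out of image bounds (%dx%d) in '%s', rows: %s",
                 w, h, path, paste(bad, collapse = ", ")))
  dup <- which(duplicated(tab[, c("x", "y")]))
  if (length(dup))
    stop(sprintf("duplicate centroid rows in '%s': %s",
                 path, paste(dup, collapse = ", ")))
  centroid_set(tab[, c("x", "y")], image_id = image$id)
}

#' Write a centroid set as CSV
#'
#' @param cs a [centroid_set()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(cs, path) {
  df <- data.frame(image_id = rep(cs$image_id, n_centroids(cs)),
                   x = cs$points$x, y = cs$points$y)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
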