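#' Binary border label map
#'
#' @param mask 0/1 matrix, 1 = cell-border class, same dimensions as the
#'   source image.
#' @param image_id identifier of the source image.
#' @return An object of class `border_label_map` with fields `mask` and
#'   `image_id`.
#' @export
border_label_map <- function(mask, image_id = "image") {
  mask <- mask * 1L
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("label map must be binary")
  structure(list(mask = mask, image_id = as.character(image_id)),
            class = "border_label_map")
}

#' Synthesize a dense border label map from centroid dots
#'
#' Converts sparse expert dots into a two-class training label map by
#' marker-constrained watershed: the preprocessed intensity raster is
#' inverted (bright cell interiors become basins, dark borders become
#' ridges), one marker is imposed per dot, and the watershed lines between
#' basins become the cell-border class.  The line is one pixel wide and the
#' flooding is deterministic, so the same inputs always give the same map.
#'
#' With fewer than two dots there is no interior watershed line; an
#' all-zero label map is returned with a warning.  Dots that round to the
#' same pixel are collapsed to one marker (with a warning).
#'
#' The raw watershed line is one pixel wide.  A one-pixel target is hard
#' for a probability-map segmenter to hit confidently (its localization
#' uncertainty smears the probability mass below practical thresholds), so
#' by default the line is dilated to a band of `2 * line_halfwidth + 1`
#' pixels for training; `line_halfwidth = 0` keeps the raw line.
#'
#' @param img the preprocessed [gray_image()].
#' @param dots a [centroid_set()] of expert dots.
#' @param line_halfwidth dilation radius of the border class, pixels.
#' @return A [border_label_map()]; the attribute `n_basins` records the
#'   number of watershed basins (equal to the number of distinct markers).
#' @export
centroids_to_labelmap <- function(img, dots, line_halfwidth = 1L) {
  px <- as_pixel_matrix(img)
  nx <- nrow(px); ny <- ncol(px)
  pts <- dots$points
  mx <- pmin(pmax(round(pts$x), 0), nx - 1) + 1L
  my <- pmin(pmax(round(pts$y), 0), ny - 1) + 1L
  pix <- cbind(mx, my)
  dup <- duplicated(pix)
  if (any(dup)) {
    warning(sprintf("%d dots rounded onto occupied pixels were collapsed",
                    sum(dup)))
    pix <- pix[!dup, , drop = FALSE]
  }
  if (nrow(pix) < 2) {
    warning("fewer than 2 centroids: returning an empty label map")
    out <- border_label_map(matrix(0L, nx, ny), image_id = img_id(img))
    attr(out, "n_basins") <- nrow(pix)
    return(out)
  }
  markers <- matrix(0L, nx, ny)
  markers[pix] <- seq_len(nrow(pix))
  labels <- cpp_watershed(1 - px, markers)
  line <- (labels == 0L) * 1L
  if (line_halfwidth > 0)
    line <- (gray_dilate(line + 0, disc_se(line_halfwidth)) > 0) * 1L
  out <- border_label_map(line, image_id = img_id(img))
  attr(out, "n_basins") <- length(unique(labels[labels > 0L]))
  out
}

#' Tile an image / label pair into training patches
#'
#' Cuts non-overlapping `size x size` tiles on a grid anchored at the
#' top-left corner; partial tiles at the right and bottom edges are
#' discarded.  Image and label are tiled identically.
#'
#' @param img a [gray_image()].
#' @param label the matching [border_label_map()] (same dimensions).
#' @param size tile side length in pixels.
#' @return A `patch_set`: a list of patches, each with fields `image`,
#'   `label` (both `size x size` matrices), `source_id`, `tile_origin`
#'   (0-based `(x, y)` of the tile's top-left corner) and `mirror`
#'   (`"none"` here).
#' @export
tile_patches <- function(img, label, size = 78L) {
  px <- as_pixel_matrix(img)
  lm <- label$mask
  if (!identical(dim(px), dim(lm)))
    stop("image and label map dimensions differ")
  size <- as.integer(size)
  ntx <- nrow(px) %/% size
  nty <- ncol(px) %/% size
  patches <- vector("list", ntx * nty)
  k <- 0L
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      xs <- (tx - 1L) * size + seq_len(size)
      ys <- (ty - 1L) * size + seq_len(size)
      k <- k + 1L
      patches[[k]] <- list(image = px[xs, ys, drop = FALSE],
                           label = lm[xs, ys, drop = FALSE],
                           source_id = img_id(img),
                           tile_origin = c((tx - 1L) * size, (ty - 1L) * size),
                           mirror = "none")
    }
  }
  structure(patches, class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  sz <- if (length(x)) paste0(nrow(x[[1]]$image), "x", ncol(x[[1]]$image))
        else "empty"
  cat(sprintf("<patch_set: %d patches (%s)>\n", length(x), sz))
  invisible(x)
}

mirror_patch <- function(m, mirror) {
  switch(mirror,
         none = m,
         horizontal = m[rev(seq_len(nrow(m))), , drop = FALSE],
         vertical = m[, rev(seq_len(ncol(m))), drop = FALSE],
         both = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         stop("unknown mirror tag"))
}

#' Four-way mirror augmentation
#'
#' Replicates every patch by mirroring horizontally, vertically, and at
#' both axes; labels are mirrored identically.  The output always has four
#' times as many patches as the input.
#'
#' @param patches a `patch_set` from [tile_patches()].
#' @return The augmented `patch_set`.
#' @export
augment_mirror <- function(patches) {
  out <- vector("list", 4L * length(patches))
  tags <- c("none", "horizontal", "vertical", "both")
  k <- 0L
  for (p in patches) {
    for (tag in tags) {
      k <- k + 1L
      q <- p
      q$image <- mirror_patch(p$image, tag)
      q$label <- mirror_patch(p$label, tag)
      q$mirror <- tag
      out[[k]] <- q
    }
  }
  structure(out, class = "patch_set")
}

#' Serialize a patch set to disk
#'
#' Writes paired `images/` and `labels/` PNG directories plus an index CSV
#' (`patch,source_id,tile_x,tile_y,mirror`).
#'
#' @param patches a `patch_set`.
#' @param dir output directory (created if missing).
#' @return The index data frame, invisibly.
#' @export
write_patches <- function(patches, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(patch = character(), source_id = character(),
                    tile_x = integer(), tile_y = integer(),
                    mirror = character(), stringsAsFactors = FALSE)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    name <- sprintf("patch_%05d.png", i)
    write_image(gray_image(p$image), file.path(dir, "images", name))
    write_image(gray_image(p$label + 0), file.path(dir, "labels", name))
    idx[i, ] <- list(name, p$source_id, p$tile_origin[1], p$tile_origin[2],
                     p$mirror)
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE, quote = FALSE)
  invisible(idx)
}
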