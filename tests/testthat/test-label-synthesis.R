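test_that("watershed of a flat relief reproduces the nearest-marker split", {
  # two markers at the same height: the separating line is equidistant
  px <- matrix(0.5, 41, 21)
  dots <- centroid_set(data.frame(x = c(10, 30), y = c(10, 10)))
  lm <- centroids_to_labelmap(gray_image(px), dots, line_halfwidth = 0)
  expect_equal(attr(lm, "n_basins"), 2)
  line_x <- which(rowSums(lm$mask) > 0) - 1
  expect_true(all(line_x == 20))           # vertical midline
  expect_equal(sum(lm$mask), 21)           # one pixel wide
})

test_that("fewer than two dots yields an all-zero label map with a warning", {
  px <- matrix(0.5, 20, 20)
  one <- centroid_set(data.frame(x = 10, y = 10))
  expect_warning(lm <- centroids_to_labelmap(gray_image(px), one),
                 "fewer than 2")
  expect_true(all(lm$mask == 0))
})

test_that("basin count equals marker count on random synthetic marker sets", {
  set.seed(21)
  for (n in c(2, 5, 23, 80, 200)) {
    px <- matrix(runif(60 * 60), 60, 60)
    # markers at least 2 px apart so a 1-px line fits between basins
    cells <- expand.grid(x = seq(0, 59, by = 2), y = seq(0, 59, by = 2))
    pts <- cells[sample(nrow(cells), n), ]
    lm <- centroids_to_labelmap(gray_image(px), centroid_set(pts),
                                line_halfwidth = 0)
    expect_equal(attr(lm, "n_basins"), n)
    # complement components reproduce the basins
    comp <- label_components(1L - lm$mask, conn = 4L)
    expect_equal(max(comp), n)
  }
})

test_that("label-map borders track the true mosaic borders", {
  smp <- quick_mosaic(width = 160, height = 160, target_density = 2500,
                      noise_sigma = 0.02, seed = 8)
  pre <- preprocess(smp$image)
  lm <- centroids_to_labelmap(pre, smp$truth_centroids,
                              line_halfwidth = 0)
  D <- matrix(EBImage::imageData(
    EBImage::distmap(EBImage::Image(1 - smp$truth_borders$mask))), 160, 160)
  frac_close <- mean(D[lm$mask == 1] <= 2)
  expect_gte(frac_close, 0.9)
})

test_that("tiling discards partial tiles and partitions the covered region", {
  img <- gray_image(matrix(runif(78 * 78), 78, 78))
  lbl <- border_label_map(matrix(0L, 78, 78))
  expect_length(tile_patches(img, lbl), 1)

  img77 <- gray_image(matrix(runif(77 * 78), 77, 78))
  lbl77 <- border_label_map(matrix(0L, 77, 78))
  expect_length(tile_patches(img77, lbl77), 0)

  img_full <- gray_image(matrix(runif(260 * 476), 260, 476), id = "full")
  lbl_full <- border_label_map(matrix(0L, 260, 476))
  tiles <- tile_patches(img_full, lbl_full)
  expect_length(tiles, 18)  # floor(260/78) * floor(476/78) = 3 * 6

  # partition: every covered pixel appears exactly once
  seen <- matrix(0L, 260, 476)
  for (p in tiles) {
    xs <- p$tile_origin[1] + seq_len(78)
    ys <- p$tile_origin[2] + seq_len(78)
    seen[xs, ys] <- seen[xs, ys] + 1L
    expect_equal(p$image, img_full$pixels[xs, ys])
  }
  expect_true(all(seen %in% c(0L, 1L)))
  expect_equal(sum(seen), 18 * 78 * 78)
})

test_that("mirror augmentation emits 4 tagged variants per patch", {
  img <- gray_image(matrix(runif(78 * 156), 78, 156), id = "m")
  lbl <- border_label_map(matrix(rbinom(78 * 156, 1, 0.1), 78, 156))
  tiles <- tile_patches(img, lbl)
  aug <- augment_mirror(tiles)
  expect_length(aug, 4 * length(tiles))
  expect_equal(vapply(aug[1:4], function(p) p$mirror, character(1)),
               c("none", "horizontal", "vertical", "both"))

  # mirroring twice is the identity
  h1 <- aug[[2]]$image
  expect_equal(h1[rev(seq_len(nrow(h1))), ], aug[[1]]$image)
  b <- aug[[4]]$image
  expect_equal(b[rev(seq_len(nrow(b))), rev(seq_len(ncol(b)))],
               aug[[1]]$image)

  # a fully symmetric patch yields 4 pixel-identical variants
  sym <- matrix(0, 78, 78); sym[39:40, 39:40] <- 1
  symp <- structure(list(list(image = sym, label = sym * 1L,
                              source_id = "s", tile_origin = c(0, 0),
                              mirror = "none")), class = "patch_set")
  aug2 <- augment_mirror(symp)
  expect_true(all(vapply(aug2, function(p) identical(p$image, sym),
                         logical(1))))
  expect_equal(length(unique(vapply(aug2, function(p) p$mirror,
                                    character(1)))), 4)
})
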