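test_that("parameter count matches the layer-by-layer tally", {
  # depth 3, 26 root features, summed by hand over the architecture
  expected <- (9 * 1 * 26 + 26) + (9 * 26 * 26 + 26) +          # enc0
    (9 * 26 * 52 + 52) + (9 * 52 * 52 + 52) +                   # enc1
    (9 * 52 * 104 + 104) + (9 * 104 * 104 + 104) +              # bottom
    (104 * 4 * 52 + 52) +                                       # up1
    (9 * 104 * 52 + 52) + (9 * 52 * 52 + 52) +                  # dec1
    (52 * 4 * 26 + 26) +                                        # up0
    (9 * 52 * 26 + 26) + (9 * 26 * 26 + 26) +                   # dec0
    (26 * 2 + 2)                                                # 1x1 out
  expect_equal(unet_n_params(unet_config()), expected)
  expect_equal(expected, 307790)
})

test_that("initialization is deterministic in the seed", {
  m1 <- unet_build(unet_config(root_features = 4, seed = 11))
  m2 <- unet_build(unet_config(root_features = 4, seed = 11))
  expect_identical(m1$weights, m2$weights)
  m3 <- unet_build(unet_config(root_features = 4, seed = 12))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("prediction is a deterministic probability raster of input size", {
  model <- unet_build(unet_config(depth = 2, root_features = 4, seed = 2))
  img <- gray_image(matrix(runif(26 * 18), 26, 18))
  p1 <- unet_predict(model, img)
  expect_equal(dim(p1$probs), c(26, 18))
  expect_true(all(p1$probs > 0 & p1$probs < 1))
  expect_identical(p1$probs, unet_predict(model, img)$probs)

  # odd sizes are padded and cropped back
  odd <- gray_image(matrix(runif(13 * 11), 13, 11))
  expect_equal(dim(unet_predict(model, odd)$probs), c(13, 11))
})

test_that("a horizontally symmetric network is mirror-equivariant", {
  cfg <- unet_config(depth = 2, root_features = 4, seed = 3)
  model <- unet_build(cfg)
  # symmetrize 3x3 kernels under dx -> -dx; offsets are laid out in rows
  # of Cin grouped by o = (dy+1)*3 + (dx+1)
  sym3 <- function(W, cin) {
    for (dy in -1:1) for (dx in -1:1) {
      o1 <- (dy + 1) * 3 + (dx + 1); o2 <- (dy + 1) * 3 + (-dx + 1)
      r1 <- o1 * cin + seq_len(cin); r2 <- o2 * cin + seq_len(cin)
      avg <- (W[r1, , drop = FALSE] + W[r2, , drop = FALSE]) / 2
      W[r1, ] <- avg; W[r2, ] <- avg
    }
    W
  }
  for (nm in names(model$weights)) {
    if (grepl("^(enc|dec)[0-9]+_c[12]_W$", nm)) {
      cin <- nrow(model$weights[[nm]]) / 9
      model$weights[[nm]] <- sym3(model$weights[[nm]], cin)
    }
    if (grepl("^up[0-9]+_W$", nm)) {
      W <- model$weights[[nm]]
      cout <- ncol(W) / 4
      for (s in c(0, 2)) {   # swap dx=0 / dx=1 within each dy
        c1 <- s * cout + seq_len(cout); c2 <- (s + 1) * cout + seq_len(cout)
        avg <- (W[, c1, drop = FALSE] + W[, c2, drop = FALSE]) / 2
        W[, c1] <- avg; W[, c2] <- avg
      }
      model$weights[[nm]] <- W
    }
  }
  img <- matrix(runif(16 * 16), 16, 16)
  p <- unet_predict(model, gray_image(img))$probs
  pm <- unet_predict(model, gray_image(img[16:1, ]))$probs
  expect_equal(pm, p[16:1, ], tolerance = 1e-10)
})

toy_patches <- function(n = 4, size = 16, seed = 5) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    lbl <- matrix(0L, size, size)
    lbl[, seq(3, size, by = 6)] <- 1L     # stripes as "borders"
    img <- 0.8 - 0.6 * lbl + matrix(rnorm(size^2, 0, 0.05), size, size)
    list(image = pmin(pmax(img, 0), 1), label = lbl, source_id = "toy",
         tile_origin = c(0, 0), mirror = "none")
  })
  structure(out, class = "patch_set")
}

test_that("training overfits a tiny patch set and keeps its books", {
  patches <- toy_patches()
  cfg <- unet_config(depth = 2, root_features = 6, epochs = 5,
                     iterations_per_epoch = 30, batch_size = 4,
                     learning_rate = 2e-3, seed = 8)
  model <- unet_train(unet_build(cfg), patches)
  expect_equal(nrow(model$history), 5)
  expect_lt(model$history$loss[5], 0.10 * model$history$loss[1])

  # thresholded reconstruction of a training patch
  pm <- unet_predict(model, gray_image(patches[[1]]$image))
  hard <- (pm$probs >= 0.5) * 1L
  expect_lt(mean(abs(hard - patches[[1]]$label)), 0.05)

  expect_error(unet_train(model, structure(list(), class = "patch_set")),
               "empty")
})

test_that("all-background labels drive border probability to zero", {
  patches <- toy_patches()
  for (i in seq_along(patches)) patches[[i]]$label[] <- 0L
  cfg <- unet_config(depth = 2, root_features = 4, epochs = 2,
                     iterations_per_epoch = 25, batch_size = 4,
                     learning_rate = 2e-3, seed = 9)
  model <- unet_train(unet_build(cfg), patches)
  pm <- unet_predict(model, gray_image(patches[[1]]$image))
  expect_lt(max(pm$probs), 0.1)
})

test_that("checkpoints round-trip through disk", {
  model <- unet_build(unet_config(depth = 2, root_features = 4, seed = 1))
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$weights, model$weights)
  img <- gray_image(matrix(runif(16 * 16), 16, 16))
  expect_identical(unet_predict(back, img)$probs,
                   unet_predict(model, img)$probs)
})
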