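#' U-Net configuration
#'
#' A small two-class U-Net: `depth` resolution levels (so `depth - 1`
#' 2x2 max-poolings), `root_features` channels at the top level doubling
#' with every level, 3x3 "same" convolutions, one grayscale input channel
#' and two output classes (cell border vs. no cell border).  Training runs
#' `epochs` epochs of `iterations_per_epoch` optimizer steps over randomly
#' drawn patch batches.
#'
#' @param depth number of resolution levels.
#' @param root_features channel width at the top level.
#' @param iterations_per_epoch optimizer steps per epoch.
#' @param epochs number of epochs.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size patches per optimizer step.
#' @param class_weights length-2 weights for the (background, border)
#'   classes in the cross-entropy loss; `c(1, 1)` is the unweighted loss.
#' @param seed integer seed for parameter initialization and batch order.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 3L, root_features = 26L,
                        iterations_per_epoch = 200L, epochs = 150L,
                        optimizer = "adam", learning_rate = 1e-3,
                        batch_size = 16L, class_weights = c(1, 1),
                        seed = 1L) {
  stopifnot(depth >= 1, root_features >= 1, iterations_per_epoch >= 1,
            epochs >= 1, learning_rate > 0, batch_size >= 1,
            length(class_weights) == 2, all(class_weights > 0))
  if (!identical(tolower(optimizer), "adam"))
    stop("only the 'adam' optimizer is implemented")
  structure(list(depth = as.integer(depth),
                 root_features = as.integer(root_features),
                 n_classes = 2L,
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 epochs = as.integer(epochs), optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 class_weights = as.numeric(class_weights),
                 seed = as.integer(seed)),
            class = "unet_config")
}

# canonical weight shapes for the architecture; biases are (n x 1) matrices
unet_shapes <- function(config) {
  d <- config$depth; f <- config$root_features
  shapes <- list()
  for (l in 0:(d - 1)) {
    cin <- if (l == 0) 1L else f * 2L^(l - 1L)
    cout <- f * 2L^l
    shapes[[sprintf("enc%d_c1_W", l)]] <- c(9L * cin, cout)
    shapes[[sprintf("enc%d_c1_b", l)]] <- c(cout, 1L)
    shapes[[sprintf("enc%d_c2_W", l)]] <- c(9L * cout, cout)
    shapes[[sprintf("enc%d_c2_b", l)]] <- c(cout, 1L)
  }
  if (d >= 2) {
    for (l in (d - 2):0) {
      cin <- f * 2L^(l + 1L)
      cout <- f * 2L^l
      shapes[[sprintf("up%d_W", l)]] <- c(cin, 4L * cout)
      shapes[[sprintf("up%d_b", l)]] <- c(cout, 1L)
      shapes[[sprintf("dec%d_c1_W", l)]] <- c(9L * 2L * cout, cout)
      shapes[[sprintf("dec%d_c1_b", l)]] <- c(cout, 1L)
      shapes[[sprintf("dec%d_c2_W", l)]] <- c(9L * cout, cout)
      shapes[[sprintf("dec%d_c2_b", l)]] <- c(cout, 1L)
    }
  }
  shapes[["out_W"]] <- c(f, 2L)
  shapes[["out_b"]] <- c(2L, 1L)
  shapes
}

#' Build an untrained U-Net
#'
#' He-initializes all convolution weights (standard deviation
#' `sqrt(2 / fan_in)`) and zeroes the biases.  Initialization is
#' deterministic given `config$seed`.
#'
#' @param config a [unet_config()].
#' @return An object of class `unet_model` with fields `weights`, `config`
#'   and `trained`.
#' @export
unet_build <- function(config = unet_config()) {
  shapes <- unet_shapes(config)
  weights <- local_seed(config$seed, {
    lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (grepl("_b$", nm)) return(matrix(0, sh[1], sh[2]))
      fan_in <- if (grepl("^up", nm)) sh[1] else sh[1]
      matrix(rnorm(prod(sh), sd = sqrt(2 / fan_in)), sh[1], sh[2])
    })
  })
  names(weights) <- names(shapes)
  structure(list(weights = weights, config = config, trained = FALSE,
                 history = NULL),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model` or [unet_config()].
#' @export
unet_n_params <- function(model) {
  config <- if (inherits(model, "unet_config")) model else model$config
  sum(vapply(unet_shapes(config), prod, numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model: depth %d, root %d, %s parameters, %s>\n",
              x$config$depth, x$config$root_features,
              format(unet_n_params(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# mirror-pad a matrix so both dimensions are multiples of 2^(depth-1)
pad_for_depth <- function(px, depth) {
  mult <- 2L^(depth - 1L)
  nx <- nrow(px); ny <- ncol(px)
  tx <- ceiling(nx / mult) * mult
  ty <- ceiling(ny / mult) * mult
  if (tx > 2 * nx || ty > 2 * ny)
    stop(sprintf("image (%dx%d) too small for depth %d", nx, ny, depth))
  ix <- c(seq_len(nx), rev(seq_len(nx)))[seq_len(tx)]
  iy <- c(seq_len(ny), rev(seq_len(ny)))[seq_len(ty)]
  px[ix, iy, drop = FALSE]
}

patchset_arrays <- function(patches, depth) {
  imgs <- lapply(patches, function(p) pad_for_depth(p$image, depth))
  labs <- lapply(patches, function(p) pad_for_depth(p$label + 0, depth))
  nx <- nrow(imgs[[1]]); ny <- ncol(imgs[[1]])
  if (!all(vapply(imgs, function(m) nrow(m) == nx && ncol(m) == ny,
                  logical(1))))
    stop("all patches must share dimensions")
  list(x = array(unlist(imgs), c(nx, ny, length(imgs))),
       y = array(unlist(labs), c(nx, ny, length(labs))))
}

#' Train the U-Net on a patch set
#'
#' Minimizes the (optionally class-weighted) pixel-wise two-class
#' cross-entropy with Adam over randomly drawn batches.  The patch order is
#' seeded, so training is deterministic given the configuration.  Patches
#' are mirror-padded to the next multiple of `2^(depth - 1)` so the pooling
#' ladder always divides evenly.
#'
#' @param model an untrained (or previously trained) `unet_model`.
#' @param patches a `patch_set` with paired labels, see [tile_patches()].
#' @param config training configuration; defaults to the model's own.
#' @return The trained `unet_model`; `$history` holds a data frame with one
#'   row per epoch (`epoch`, `loss`, `pixel_accuracy`).
#' @export
unet_train <- function(model, patches, config = model$config) {
  if (length(patches) == 0) stop("cannot train on an empty patch set")
  arr <- patchset_arrays(patches, config$depth)
  n <- dim(arr$x)[3]
  w <- model$weights
  m <- lapply(w, function(x) x * 0)
  v <- lapply(w, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  lr <- config$learning_rate
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     pixel_accuracy = numeric())
  local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0; ep_acc <- 0
      for (it in seq_len(config$iterations_per_epoch)) {
        idx <- sample.int(n, min(config$batch_size, n))
        res <- cpp_unet_batch(arr$x[, , idx, drop = FALSE],
                              arr$y[, , idx, drop = FALSE],
                              w, config$depth, config$class_weights)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at epoch %d, iteration %d", ep, it))
        t <- t + 1L
        for (j in seq_along(w)) {
          g <- res$grads[[j]]
          m[[j]] <- b1 * m[[j]] + (1 - b1) * g
          v[[j]] <- b2 * v[[j]] + (1 - b2) * g^2
          mhat <- m[[j]] / (1 - b1^t)
          vhat <- v[[j]] / (1 - b2^t)
          w[[j]] <- w[[j]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + res$loss
        ep_acc <- ep_acc + res$accuracy
      }
      hist[ep, ] <- list(ep, ep_loss / config$iterations_per_epoch,
                         ep_acc / config$iterations_per_epoch)
    }
  })
  model$weights <- w
  model$config <- config
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Per-pixel border probability map
#'
#' @param probs numeric matrix of border-class probabilities in \[0, 1\],
#'   same orientation as [gray_image()].
#' @param image_id source image identifier.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(probs, image_id = "image") {
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("probabilities must be finite and in [0, 1]")
  structure(list(probs = probs, image_id = as.character(image_id)),
            class = "probability_map")
}

#' Predict the border-probability map for an image
#'
#' Runs the trained network on a whole preprocessed image.  The input is
#' mirror-padded to the next multiple of `2^(depth - 1)` and the output
#' cropped back, so the map has exactly the input raster size.  Prediction
#' is deterministic.
#'
#' @param model a trained `unet_model`.
#' @param img the preprocessed [gray_image()].
#' @return A [probability_map()].
#' @export
unet_predict <- function(model, img) {
  px <- as_pixel_matrix(img)
  padded <- pad_for_depth(px, model$config$depth)
  p <- cpp_unet_predict(padded, model$weights, model$config$depth)
  probability_map(p[seq_len(nrow(px)), seq_len(ncol(px)), drop = FALSE],
                  image_id = img_id(img))
}

#' Save / load a model checkpoint
#'
#' @param model a `unet_model`.
#' @param path checkpoint file path (a single RDS archive).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop("not a unet_model checkpoint")
  model
}
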