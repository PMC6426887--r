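#' Default pipeline configuration
#'
#' A single nested list configures every stage; [read_pipeline_config()]
#' merges a YAML file over these defaults and rejects unknown keys.  The
#' global `seed` derives per-stage seeds by fixed offsets, so full runs are
#' reproducible from one value.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preprocess = list(blur_radius = 1, blur_sigma = 2, tophat_radius = 15,
                      equalize_bins = 256),
    unet = list(depth = 3, root_features = 26, iterations_per_epoch = 200,
                epochs = 150, optimizer = "adam", learning_rate = 1e-3,
                batch_size = 16, class_weights = c(1, 1), patch_size = 78),
    postprocess = list(prob_threshold = 0.60, min_object_px = 1000,
                       min_peak_separation = 0),
    vincent = list(asf_max_radius = 1, hdome_h = 0.02, min_marker_px = 3),
    density = list(microns_per_pixel = 1),
    synth = list(width = 260, height = 476, density_range = c(500, 3000),
                 ungradable_fraction = 0.1, partial_blur_fraction = 0.2,
                 partial_blur_size = 0.3, guttae_fraction = 0.3,
                 jitter = 0.15)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a section", full))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with any subset of the sections of
#'   [default_config()]; unknown keys are rejected.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

config_objects <- function(config) {
  u <- config$unet
  list(
    preprocess = do.call(preprocess_params, config$preprocess),
    unet = unet_config(depth = u$depth, root_features = u$root_features,
                       iterations_per_epoch = u$iterations_per_epoch,
                       epochs = u$epochs, optimizer = u$optimizer,
                       learning_rate = u$learning_rate,
                       batch_size = u$batch_size,
                       class_weights = unlist(u$class_weights),
                       seed = config$seed + 100L),
    postprocess = do.call(postprocess_params, config$postprocess),
    vincent = do.call(vincent_params, config$vincent),
    scale = scale_calibration(config$density$microns_per_pixel)
  )
}

write_run_manifest <- function(out_dir, config, stage) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         package_version = as.character(utils::packageVersion("cecseg")),
         config = config),
    file.path(out_dir, paste0(stage, "_run.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Train the U-Net from a corpus manifest
#'
#' End-to-end training: reads every gradable training image and its
#' centroid annotations, preprocesses, synthesizes border label maps by
#' marker-constrained watershed, tiles into `patch_size` patches with
#' four-way mirror augmentation, and trains the network.  Writes the model
#' checkpoint, the per-epoch loss CSV, the patch index CSV and a run
#' manifest into `out_dir`.
#'
#' @param config pipeline configuration, see [default_config()].
#' @param manifest a [corpus_manifest()] with at least one gradable
#'   training record.
#' @param corpus_dir directory the manifest's paths are relative to;
#'   images are looked up as `images/<image_id>.png`.
#' @param out_dir output directory.
#' @return The trained `unet_model`, invisibly.
#' @export
run_train <- function(config, manifest, corpus_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)
  train <- manifest[manifest$split == "train" & !manifest$ungradable, ]
  if (nrow(train) == 0) stop("no gradable training images in the manifest")
  all_patches <- list()
  index <- list()
  for (i in seq_len(nrow(train))) {
    id <- train$image_id[i]
    img <- read_image(file.path(corpus_dir, "images", paste0(id, ".png")),
                      id = id)
    dots <- read_centroids(file.path(corpus_dir, train$annotation_path[i]),
                           img)
    pre <- preprocess(img, obj$preprocess)
    lm <- centroids_to_labelmap(pre, dots)
    patches <- augment_mirror(tile_patches(pre, lm,
                                           size = config$unet$patch_size))
    all_patches <- c(all_patches, patches)
    index[[i]] <- data.frame(
      source_id = id,
      tile_x = vapply(patches, function(p) p$tile_origin[1], numeric(1)),
      tile_y = vapply(patches, function(p) p$tile_origin[2], numeric(1)),
      mirror = vapply(patches, function(p) p$mirror, character(1)))
  }
  class(all_patches) <- "patch_set"
  write.csv(do.call(rbind, index), file.path(out_dir, "patch_index.csv"),
            row.names = FALSE, quote = FALSE)
  model <- unet_build(obj$unet)
  model <- unet_train(model, all_patches)
  write.csv(model$history, file.path(out_dir, "training_curve.csv"),
            row.names = FALSE, quote = FALSE)
  save_model(model, file.path(out_dir, "model.rds"))
  write_run_manifest(out_dir, config, "train")
  invisible(model)
}

density_row <- function(id, est) {
  data.frame(image_id = id,
             cells_per_mm2 = est$cells_per_mm2,
             median_area_px2 = est$median_area_px2,
             n_interior = est$n_interior,
             n_excluded_border = est$n_excluded_border,
             gradable = est$gradable, stringsAsFactors = FALSE)
}

segment_batch <- function(config, image_paths, out_dir, segment_one, stage) {
  dir.create(file.path(out_dir, "centroids"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (path in image_paths) {
    id <- sub("\\.[^.]+$", "", basename(path))
    rows[[id]] <- tryCatch({
      img <- read_image(path, id = id)
      seg <- segment_one(img)
      write_centroids(seg$centroids,
                      file.path(out_dir, "centroids", paste0(id, ".csv")))
      frame <- c(image_width(img), image_height(img))
      est <- estimate_density(seg$centroids, frame,
                              scale_calibration(config$density$microns_per_pixel))
      density_row(id, est)
    }, error = function(e) {
      message(sprintf("[%s] %s failed: %s", id, stage, conditionMessage(e)))
      data.frame(image_id = id, cells_per_mm2 = NA_real_,
                 median_area_px2 = NA_real_, n_interior = NA_integer_,
                 n_excluded_border = NA_integer_, gradable = NA,
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file.path(out_dir, "density.csv"), row.names = FALSE,
            quote = FALSE)
  write_run_manifest(out_dir, config, stage)
  out
}

#' Segment a batch of images with the trained U-Net
#'
#' Per image: preprocessing, border-probability prediction,
#' post-processing and density estimation.  Ungradable images produce a
#' `gradable = FALSE` row (and an empty centroid CSV); a failure on one
#' image is reported and the batch continues.
#'
#' @param config pipeline configuration.
#' @param model trained `unet_model`.
#' @param image_paths character vector of image files.
#' @param out_dir output directory (`centroids/*.csv`, `density.csv`).
#' @return The density data frame, one row per image.
#' @export
run_segment <- function(config, model, image_paths, out_dir) {
  obj <- config_objects(config)
  segment_batch(config, image_paths, out_dir, function(img) {
    pre <- preprocess(img, obj$preprocess)
    postprocess_probability_map(unet_predict(model, pre), obj$postprocess)
  }, "segment")
}

#' Segment a batch of images with the classical watershed baseline
#'
#' @inheritParams run_segment
#' @return The density data frame, one row per image.
#' @export
run_vincent <- function(config, image_paths, out_dir) {
  obj <- config_objects(config)
  segment_batch(config, image_paths, out_dir, function(img) {
    vincent_segment(img, obj$vincent)
  }, "vincent")
}
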