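#' Corpus manifest
#'
#' A manifest assigns every image of a corpus to a train/validation split
#' and carries the ungradable and guttae flags plus the path of the centroid
#' annotation file.  Ungradable images are, by definition, images without
#' any dotted cells; their annotation tables are empty and they are never
#' used for training.
#'
#' @param records data frame with columns `image_id`, `split`
#'   (`"train"`/`"validation"`), `ungradable`, `guttae` (logical), and
#'   `annotation_path`.
#' @return An object of classes `corpus_manifest` and `data.frame`.
#' @export
corpus_manifest <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("image_id", "split", "ungradable", "guttae", "annotation_path")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  records <- records[, need]
  if (anyDuplicated(records$image_id))
    stop("manifest image_ids must be unique")
  if (!all(records$split %in% c("train", "validation")))
    stop("split must be 'train' or 'validation'")
  records$ungradable <- as.logical(records$ungradable)
  records$guttae <- as.logical(records$guttae)
  if (any(records$ungradable & records$split == "train"))
    stop("ungradable images cannot be in the training split")
  class(records) <- c("corpus_manifest", "data.frame")
  records
}

#' Read / write a corpus manifest CSV
#'
#' @param path path of the manifest CSV
#'   (`image_id,split,ungradable,guttae,annotation_path`).
#' @return [corpus_manifest()] for `read_manifest`; `path` invisibly for
#'   `write_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest does not exist: '%s'", path))
  corpus_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest a [corpus_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Randomly assign training images in a manifest
#'
#' Draws `n_train` images at random from the gradable records and marks them
#' `train`; every other record (including all ungradable images) becomes
#' `validation`.  The draw is deterministic given `seed`.
#'
#' @param manifest a [corpus_manifest()].
#' @param n_train number of training images to select.
#' @param seed integer seed for the random draw.
#' @return The manifest with an updated `split` column.
#' @export
split_manifest <- function(manifest, n_train, seed = 1L) {
  gradable <- which(!manifest$ungradable)
  if (n_train > length(gradable))
    stop(sprintf("n_train (%d) exceeds the %d gradable records",
                 n_train, length(gradable)))
  manifest$split <- "validation"
  if (n_train > 0) {
    chosen <- local_seed(seed, sample(gradable, n_train))
    manifest$split[chosen] <- "train"
  }
  corpus_manifest(manifest)
}
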