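#' Match predicted against ground-truth centroids
#'
#' A predicted centroid counts as a correct detection when it can be
#' paired, one-to-one, with a ground-truth dot no farther than
#' `tolerance_px` away.  The pairing is a maximum-cardinality bipartite
#' matching over all pairs within tolerance, so one prediction can never
#' "detect" several cells and the matched count is the best achievable.
#'
#' Recall is `n_matched / n_truth` (undefined, `NA`, when the image has no
#' ground-truth dots, i.e. an expert-ungradable image); precision is
#' `n_matched / n_pred` (`NA` when nothing was predicted).
#'
#' @param pred predicted [centroid_set()].
#' @param truth ground-truth [centroid_set()] (expert dots).
#' @param tolerance_px matching radius in pixels.
#' @return A `match_report`: `image_id`, `n_truth`, `n_pred`, `n_matched`,
#'   `recall`, `precision`, `tolerance_px`.
#' @export
match_centroids <- function(pred, truth, tolerance_px = 8) {
  np <- n_centroids(pred); nt <- n_centroids(truth)
  n_matched <- 0L
  if (np > 0 && nt > 0) {
    dx <- outer(truth$points$x, pred$points$x, "-")
    dy <- outer(truth$points$y, pred$points$y, "-")
    ok <- sqrt(dx^2 + dy^2) <= tolerance_px
    ij <- which(ok, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      edges <- as.vector(t(cbind(ij[, 1], nt + ij[, 2])))
      g <- igraph::make_bipartite_graph(c(rep(TRUE, nt), rep(FALSE, np)),
                                        edges, directed = FALSE)
      n_matched <- igraph::max_bipartite_match(g)$matching_size
    }
  }
  structure(list(image_id = truth$image_id, n_truth = nt, n_pred = np,
                 n_matched = as.integer(n_matched),
                 recall = if (nt > 0) n_matched / nt else NA_real_,
                 precision = if (np > 0) n_matched / np else NA_real_,
                 tolerance_px = tolerance_px),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report '%s': %d/%d truth matched (recall %s), %d predicted (precision %s), tol %g px>\n",
    x$image_id, x$n_matched, x$n_truth, format(x$recall, digits = 3),
    x$n_pred, format(x$precision, digits = 3), x$tolerance_px))
  invisible(x)
}

#' Recall and precision from a match report
#'
#' Recall is the number of correctly identified cells divided by the number
#' of cells in the manual annotation; precision divides by the total number
#' of cells identified by the segmentation method.  Division-by-zero cases
#' are reported as `NA` (not applicable).
#'
#' @param report a `match_report` from [match_centroids()].
#' @return Named numeric vector `c(recall = , precision = )`.
#' @export
compute_recall_precision <- function(report) {
  c(recall = report$recall, precision = report$precision)
}

#' Density agreement between manual and automated estimates
#'
#' Pearson R-squared plus the fraction of images whose automated density
#' falls within +/-250 and +/-500 cells/mm^2 of the manual estimate.
#' Images ungradable on both sides must be excluded upstream.
#'
#' @param manual,automated paired density vectors (cells/mm^2).
#' @param corridors corridor half-widths, cells/mm^2.
#' @return An `agreement_report`: `n_images`, `r_squared`,
#'   `pct_within_250`, `pct_within_500` (percent scale).
#' @export
density_agreement <- function(manual, automated,
                              corridors = c(250, 500)) {
  stopifnot(length(manual) == length(automated))
  ok <- is.finite(manual) & is.finite(automated)
  manual <- manual[ok]; automated <- automated[ok]
  n <- length(manual)
  r2 <- if (n >= 2 && stats::sd(manual) > 0 && stats::sd(automated) > 0)
    cor(manual, automated)^2 else NA_real_
  pct <- vapply(corridors, function(cw)
    100 * mean(abs(manual - automated) <= cw), numeric(1))
  structure(list(n_images = n, r_squared = r2,
                 pct_within_250 = pct[1], pct_within_500 = pct[2]),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report: n %d, R^2 %s, %.0f%% within 250, %.0f%% within 500 cells/mm^2>\n",
    x$n_images, format(x$r_squared, digits = 3), x$pct_within_250,
    x$pct_within_500))
  invisible(x)
}

#' Ungradable-detection cross-tabulation
#'
#' 2x2 contingency table of the expert's ungradable flag against the
#' automatic one (an image is automatically ungradable when the pipeline
#' extracted no centroids).
#'
#' @param expert_ungradable,auto_ungradable logical vectors, one entry per
#'   image.
#' @return A 2x2 `table` (rows: expert, columns: automatic).
#' @export
ungradable_crosstab <- function(expert_ungradable, auto_ungradable) {
  stopifnot(length(expert_ungradable) == length(auto_ungradable))
  table(expert = factor(expert_ungradable, levels = c(FALSE, TRUE)),
        auto = factor(auto_ungradable, levels = c(FALSE, TRUE)))
}

#' Evaluate a batch of segmentations against ground truth
#'
#' Convenience wrapper producing per-image match reports and the corpus
#' summary (unweighted means over images where the metric is defined).
#'
#' @param preds list of predicted [centroid_set()]s.
#' @param truths list of matching ground-truth [centroid_set()]s.
#' @param tolerance_px matching radius in pixels.
#' @return A list with `per_image` (data frame) and `mean_recall`,
#'   `mean_precision`.
#' @export
evaluate_centroids <- function(preds, truths, tolerance_px = 8) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    r <- match_centroids(preds[[i]], truths[[i]], tolerance_px)
    data.frame(image_id = r$image_id, n_truth = r$n_truth,
               n_pred = r$n_pred, n_matched = r$n_matched,
               recall = r$recall, precision = r$precision)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image,
       mean_recall = mean(per_image$recall, na.rm = TRUE),
       mean_precision = mean(per_image$precision, na.rm = TRUE))
}
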