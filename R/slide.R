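#' Slide-level class confidences from patch probabilities
#'
#' Patch probability rows are summed channel-wise: the slide confidence for
#' class `y` is the column sum over the slide's patches. For normalized patch
#' rows the confidences conserve mass: they sum to the number of patches.
#'
#' @param patch_probs matrix of per-patch class probabilities (rows normalized).
#' @return a `slide_confidence`: list with `p_hat` (named per-class sums) and
#'   `n_patches`.
#' @export
slide_confidence <- function(patch_probs) {
  if (is.null(dim(patch_probs))) patch_probs <- matrix(patch_probs, nrow = 1)
  assert_that(nrow(patch_probs) >= 1, "empty patch probability matrix")
  p <- colSums(patch_probs)
  structure(list(p_hat = p, n_patches = nrow(patch_probs)),
            class = "slide_confidence")
}

#' Likelihood-ratio slide decision
#'
#' Declares a slide positive iff `p_hat_1 / p_hat_0 >= eta`. With `p_hat_0 = 0`
#' and positive `p_hat_1` the ratio is infinite, so the slide is positive for
#' any finite threshold; both confidences zero is guarded as an error.
#'
#' @param conf a `slide_confidence` (binary: classes 0 and 1 in order).
#' @param eta nonnegative decision threshold.
#' @return a `slide_decision`: list with `y_hat` in `{0, 1}` and `eta`.
#' @export
slide_lr_decision <- function(conf, eta) {
  assert_that(inherits(conf, "slide_confidence"), "not a slide_confidence")
  assert_that(is.numeric(eta) && eta >= 0, "eta must be >= 0")
  p0 <- conf$p_hat[[1]]; p1 <- conf$p_hat[[2]]
  assert_that(p0 > 0 || p1 > 0, "both class confidences are zero")
  y <- if (p0 == 0) 1L else as.integer(p1 / p0 >= eta)
  structure(list(y_hat = y, eta = eta), class = "slide_decision")
}

#' Thresholdless slide score
#'
#' `p_hat_1 / (p_hat_0 + p_hat_1)`: a strictly increasing transform of the
#' likelihood ratio, so ranking slides by this score induces exactly the ROC
#' curve swept out by the ratio threshold.
#'
#' @param conf a `slide_confidence`.
#' @return a real in `[0, 1]`.
#' @export
slide_score <- function(conf) {
  assert_that(inherits(conf, "slide_confidence"), "not a slide_confidence")
  p0 <- conf$p_hat[[1]]; p1 <- conf$p_hat[[2]]
  assert_that(p0 > 0 || p1 > 0, "both class confidences are zero")
  p1 / (p0 + p1)
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) form: the probability that a random positive
#' outranks a random negative, ties credited 0.5.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
compute_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC undefined: both classes must be present",
          class = "undefined_metric")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score every slide in a manifest with a detection model
#'
#' Runs the patch model over each slide's patches, sums patch probabilities
#' into slide confidences and returns the slide prediction table.
#'
#' @param model a binary `trained_patch_model` (detection task).
#' @param dataset a `multicohort_dataset`.
#' @param manifest manifest rows naming the slides to score.
#' @return a tibble: `slide_id`, `cohort`, `label`, `p_hat_0`, `p_hat_1`,
#'   `score`.
#' @export
score_slides <- function(model, dataset, manifest) {
  ids <- unique(manifest$slide_id)
  pt <- filter(dataset$patches, slide_id %in% ids)
  P <- predict_patch(model, dataset$pixels[, pt$row, drop = FALSE])
  agg <- rowsum(P, pt$slide_id)
  n_per <- rowsum(rep(1, nrow(P)), pt$slide_id)[, 1]
  meta <- distinct(filter(dataset$slides, slide_id %in% ids),
                   slide_id, cohort, label)
  meta <- meta[match(rownames(agg), meta$slide_id), ]
  tibble(slide_id = rownames(agg), cohort = meta$cohort, label = meta$label,
         p_hat_0 = agg[, 1], p_hat_1 = agg[, 2],
         score = agg[, 2] / (agg[, 1] + agg[, 2]),
         n_patches = as.integer(n_per))
}

#' Detection AUROC of a model on one cohort's slides
#'
#' @inheritParams score_slides
#' @return the slide-level AUROC.
#' @export
detection_auroc <- function(model, dataset, manifest) {
  sc <- score_slides(model, dataset, manifest)
  compute_auroc(sc$score, sc$label)
}
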