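#' Augmentation configuration
#'
#' The training-time photometric and geometric jitter: 90-degree rotations and
#' horizontal flips (exact, no interpolation), then brightness, saturation,
#' hue and contrast jitter in that order, with the result clipped to
#' `[0, 1]`. Defaults follow the standard histopathology augmentation recipe:
#' brightness delta 64/255, saturation 0.25, hue 0.04, contrast 0.75.
#'
#' @param rotations candidate rotations in degrees (multiples of 90).
#' @param horizontal_flip allow horizontal flips.
#' @param max_brightness_delta additive luminance jitter bound.
#' @param max_saturation_delta additive saturation jitter bound (HSV space).
#' @param max_hue_delta additive hue jitter bound (fraction of the hue circle).
#' @param max_contrast_delta multiplicative contrast jitter bound about the
#'   per-patch mean; the factor is drawn from `[1 - d, 1 + d]`.
#' @return a classed list.
#' @export
augmentation_config <- function(rotations = c(0, 90, 180, 270),
                                horizontal_flip = TRUE,
                                max_brightness_delta = 64 / 255,
                                max_saturation_delta = 0.25,
                                max_hue_delta = 0.04,
                                max_contrast_delta = 0.75) {
  assert_that(all(rotations %% 90 == 0), "rotations must be multiples of 90")
  assert_that(max_brightness_delta >= 0 && max_saturation_delta >= 0 &&
                max_hue_delta >= 0 && max_contrast_delta >= 0,
              "jitter bounds must be nonnegative")
  structure(as.list(environment()), class = "augmentation_config")
}

# column permutation realizing (rotation k*90 ccw, optional horizontal flip)
# of one column-major size x size channel
.perm_cache <- new.env(parent = emptyenv())
rotflip_perm <- function(size, k, flip) {
  key <- sprintf("%d_%d_%d", size, k %% 4, flip)
  got <- .perm_cache[[key]]
  if (!is.null(got)) return(got)
  M <- matrix(seq_len(size * size), size, size)
  for (r in seq_len(k %% 4)) M <- t(M)[size:1, , drop = FALSE]
  if (flip) M <- M[, size:1, drop = FALSE]
  p <- as.vector(M)
  .perm_cache[[key]] <- p
  p
}

# vectorized augmentation of a batch: X holds one flat patch per column
# (3*size^2 rows); draws one transform per patch unless explicit values are
# supplied
augment_batch <- function(X, cfg, size,
                          rotation = NULL, flip = NULL,
                          d_bright = NULL, d_sat = NULL, d_hue = NULL,
                          f_contrast = NULL) {
  n <- ncol(X)
  npx <- size * size
  rotation <- rotation %||% sample(cfg$rotations, n, replace = TRUE)
  flip <- flip %||%
    (if (cfg$horizontal_flip) runif(n) < 0.5 else rep(FALSE, n))
  d_bright <- d_bright %||%
    runif(n, -cfg$max_brightness_delta, cfg$max_brightness_delta)
  d_sat <- d_sat %||%
    runif(n, -cfg$max_saturation_delta, cfg$max_saturation_delta)
  d_hue <- d_hue %||% runif(n, -cfg$max_hue_delta, cfg$max_hue_delta)
  f_contrast <- f_contrast %||%
    runif(n, 1 - cfg$max_contrast_delta, 1 + cfg$max_contrast_delta)
  rotation <- rep_len(rotation, n); flip <- rep_len(flip, n)
  d_bright <- rep_len(d_bright, n); d_sat <- rep_len(d_sat, n)
  d_hue <- rep_len(d_hue, n); f_contrast <- rep_len(f_contrast, n)
  # one compiled pass: geometric permutation (exact), then brightness ->
  # saturation -> hue -> contrast with identity steps skipped, clipped
  combos <- combo_table(size)
  combo <- match(paste((rotation / 90) %% 4, as.integer(flip)),
                 combos$keys)
  augment_cols_cpp(X, npx, combo, combos$perm,
                   d_bright, d_sat, d_hue, f_contrast)
}

.combo_cache <- new.env(parent = emptyenv())
combo_table <- function(size) {
  key <- as.character(size)
  got <- .combo_cache[[key]]
  if (!is.null(got)) return(got)
  grid <- expand.grid(k = 0:3, f = 0:1)
  perm <- vapply(seq_len(nrow(grid)),
                 function(i) rotflip_perm(size, grid$k[i], grid$f[i] == 1),
                 integer(size * size))
  out <- list(keys = paste(grid$k, grid$f), perm = perm)
  .combo_cache[[key]] <- out
  out
}

#' Augment a single patch
#'
#' Applies one draw of the training augmentation (or an explicitly requested
#' transform) to one patch. Geometric transforms are exact index permutations;
#' photometric jitter is brightness, saturation, hue, then contrast, clipped
#' to `[0, 1]`.
#'
#' @param pixels a flat patch vector or `size x size x 3` array in `[0, 1]`.
#' @param cfg an [augmentation_config()].
#' @param rotation,flip optional explicit rotation (degrees) and flip flag.
#' @param d_bright,d_sat,d_hue,f_contrast optional explicit jitter values
#'   (deltas for brightness/saturation/hue, multiplicative factor for
#'   contrast); sampled from `cfg` when `NULL`.
#' @param seed optional seed for the sampled transform.
#' @return a patch of the same shape as the input, values in `[0, 1]`.
#' @export
augment_patch <- function(pixels, cfg = augmentation_config(),
                          rotation = NULL, flip = NULL,
                          d_bright = NULL, d_sat = NULL, d_hue = NULL,
                          f_contrast = NULL, seed = NULL) {
  was_array <- !is.null(dim(pixels)) && length(dim(pixels)) == 3
  flat <- if (was_array) flatten_patch(pixels) else as.numeric(pixels)
  size <- as.integer(sqrt(length(flat) / 3))
  assert_that(all(flat >= 0 & flat <= 1), "pixels must lie in [0, 1]")
  if (!is.null(seed)) withr::local_seed(substream_seed(seed, "augment"))
  out <- augment_batch(matrix(flat, ncol = 1), cfg, size,
                       rotation = rotation, flip = flip, d_bright = d_bright,
                       d_sat = d_sat, d_hue = d_hue, f_contrast = f_contrast)
  if (was_array) patch_array(out[, 1], size) else out[, 1]
}
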