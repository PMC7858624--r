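# Deterministic image summaries fed to the patch classifier: per-channel
# colour statistics, luminance gradient energies (spatial-frequency band),
# coarse block contrast (blob structure) and luminance shape moments.

#' Summary features of a batch of patches
#'
#' @param pixels numeric matrix, one flat patch per column (`3 * size^2`
#'   rows: channel blocks R, G, B, each column-major), or a single flat
#'   patch vector.
#' @param size patch side length.
#' @return a numeric matrix, one row per patch, 11 columns.
#' @export
patch_features <- function(pixels,
                           size = as.integer(sqrt(nrow(pixels) / 3))) {
  if (is.null(dim(pixels))) {
    pixels <- matrix(pixels, ncol = 1)
    size <- as.integer(sqrt(nrow(pixels) / 3))
  }
  assert_that(nrow(pixels) == 3 * size * size, "pixel length mismatch")
  out <- patch_stats_cols_cpp(pixels, as.integer(size))
  colnames(out) <- c("mean_r", "mean_g", "mean_b", "sd_r", "sd_g", "sd_b",
                     "grad_h", "grad_v", "block_sd", "skew_l", "kurt_l")
  out
}
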