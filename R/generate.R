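#' Generation configuration for synthetic multi-cohort datasets
#'
#' Defaults are the study conditions of the desk-scale corpus: 40 positive and
#' 40 negative slides per cohort (comfortably above the 36 + 36 minimum the
#' sub-dataset resampling demands), 16 patches per slide, 32 x 32 RGB patches,
#' and tumor fraction 0.7 on positive slides so patch labels inherited from
#' the slide are genuinely noisy.
#'
#' @param n_pos,n_neg positive / negative slides per cohort.
#' @param patches_per_slide patches cropped per slide.
#' @param patch_size side length of the square patch in pixels.
#' @param tumor_fraction fraction of patches on a positive slide whose latent
#'   state is cancer; the count is `round(tumor_fraction * patches_per_slide)`.
#' @param sigma_walk Brownian step scale for parameter diffusion on the tree.
#' @param cancer_effect magnitude of the texture shift on cancer patches.
#' @param shared_cancer_weight convex weight of the shared cancer direction.
#' @param direction_groups,direction_jitter cancer-direction layout passed to
#'   [derive_cohort_params()]: `NULL` diffuses private directions along the
#'   tree; an integer plants one near-orthogonal direction per tree group.
#' @param slide_jitter standard deviation of the per-slide offset added to
#'   the cohort's theta (inter-patient heterogeneity); keeps slide-level
#'   rankings from saturating and makes cross-cohort transfer grade with
#'   parameter distance.
#' @param noise_amp amplitude of the smoothed texture noise field.
#' @param pixel_noise amplitude of iid per-pixel, per-channel noise.
#' @param paired_patient_frac fraction of patients owning two slides (one
#'   positive, one negative); 0 gives one patient per slide.
#' @return a classed list of generation settings.
#' @export
generation_config <- function(n_pos = 40, n_neg = 40, patches_per_slide = 16,
                              patch_size = 32, tumor_fraction = 0.7,
                              sigma_walk = 1, cancer_effect = 1,
                              shared_cancer_weight = 0.25,
                              direction_groups = NULL,
                              direction_jitter = 0.15,
                              slide_jitter = 0.2,
                              noise_amp = 0.25, pixel_noise = 0.08,
                              paired_patient_frac = 0) {
  assert_that(tumor_fraction >= 0 && tumor_fraction <= 1,
              "tumor_fraction must lie in [0, 1]")
  assert_that(patches_per_slide >= 1, "patches_per_slide must be >= 1")
  structure(as.list(environment()), class = "generation_config")
}

# theta -> interpretable texture parameters, kept in safe ranges
theta_to_texture <- function(theta) {
  list(
    mu = 0.25 + 0.5 * stats::plogis(theta[1:3]),   # per-channel colour means
    bandwidth = 0.5 + 2.5 * stats::plogis(theta[4]), # noise field smoothing sd (px)
    blob_rate = 5 * stats::plogis(theta[5]),       # expected blobs per patch
    blob_contrast = 0.5 * tanh(theta[6])           # signed luminance bump
  )
}

# cached 1-D Gaussian smoothing operators, keyed by (size, bandwidth)
.smooth_cache <- new.env(parent = emptyenv())
smoothing_matrix <- function(size, bw) {
  key <- sprintf("%d_%.3f", size, bw)
  got <- .smooth_cache[[key]]
  if (!is.null(got)) return(got)
  idx <- seq_len(size)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * bw^2))
  K <- K / rowSums(K)
  .smooth_cache[[key]] <- K
  K
}

# one patch as a flat vector c(R, G, B), each channel a column-major size^2 block
synth_patch_pixels <- function(tex, size, noise_amp, pixel_noise) {
  K <- smoothing_matrix(size, tex$bandwidth)
  field <- K %*% matrix(rnorm(size * size), size, size) %*% t(K)
  fs <- sd(field)
  if (fs > 0) field <- field / fs
  n_blobs <- rpois(1, tex$blob_rate)
  blob <- matrix(0, size, size)
  if (n_blobs > 0) {
    r_min <- size / 16
    r_max <- max(size / 6, r_min + 1e-6)
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 1, size); cy <- runif(1, 1, size)
      r <- runif(1, r_min, r_max)
      ix <- seq_len(size)
      blob <- blob + tex$blob_contrast *
        (outer((ix - cy)^2, (ix - cx)^2, "+") <= r^2)
    }
  }
  px <- vapply(1:3, function(ch) {
    clip01(tex$mu[ch] + noise_amp * field + blob +
             pixel_noise * matrix(rnorm(size * size), size, size))
  }, matrix(0, size, size))
  as.vector(px)
}

#' Generate one synthetic slide
#'
#' A slide is a bag of patches sharing a slide-level label. On a positive
#' slide exactly `round(tumor_fraction * patches_per_slide)` patches have
#' latent state `"cancer"` (their texture is shifted by
#' `cancer_effect * cancer_direction` in theta space); every patch's
#' `assigned_label` nonetheless equals the slide label, mirroring noisy
#' slide-inherited supervision. Negative slides are all-normal.
#'
#' @param params one row of [derive_cohort_params()] (a list with `theta`,
#'   `cancer_direction`, `cancer_effect`) or the tibble row itself.
#' @param label slide label, 0 (negative) or 1 (positive).
#' @param patches_per_slide number of patches.
#' @param tumor_fraction fraction of cancer-state patches if `label == 1`;
#'   forced to 0 for negative slides.
#' @param config a [generation_config()] supplying texture noise settings.
#' @param seed integer seed.
#' @return a list with `patches` (tibble: `patch_index`, `assigned_label`,
#'   `latent_state`) and `pixels` (matrix, one flat patch per column, values
#'   in `[0, 1]`).
#' @export
generate_slide <- function(params, label, patches_per_slide = 16,
                           tumor_fraction = 0.7,
                           config = generation_config(), seed = 1L) {
  assert_that(label %in% c(0, 1), "label must be 0 or 1")
  assert_that(patches_per_slide >= 1, "patches_per_slide must be >= 1")
  assert_that(tumor_fraction >= 0 && tumor_fraction <= 1,
              "tumor_fraction must lie in [0, 1]")
  if (is.data.frame(params)) params <- as.list(params[1, ])
  theta <- params$theta[[1]] %||% params$theta
  cdir <- params$cancer_direction[[1]] %||% params$cancer_direction
  ceff <- params$cancer_effect
  if (label == 0) tumor_fraction <- 0
  n_cancer <- round(tumor_fraction * patches_per_slide)
  withr::local_seed(substream_seed(seed, "slide"))
  latent <- rep("normal", patches_per_slide)
  if (n_cancer > 0) latent[sample.int(patches_per_slide, n_cancer)] <- "cancer"
  # per-slide (patient) heterogeneity: every slide sits at its own offset
  # from the cohort centre, shared by all its patches
  sj <- config$slide_jitter %||% 0
  theta_slide <- theta + sj * rnorm(length(theta))
  tex_normal <- theta_to_texture(theta_slide)
  tex_cancer <- theta_to_texture(theta_slide + ceff * cdir)
  size <- config$patch_size
  pix <- matrix(0, 3 * size * size, patches_per_slide)
  for (p in seq_len(patches_per_slide)) {
    tex <- if (latent[p] == "cancer") tex_cancer else tex_normal
    pix[, p] <- synth_patch_pixels(tex, size, config$noise_amp, config$pixel_noise)
  }
  list(
    patches = tibble(patch_index = seq_len(patches_per_slide),
                     assigned_label = as.integer(label),
                     latent_state = latent),
    pixels = pix
  )
}

#' Generate a multi-cohort dataset with a planted similarity hierarchy
#'
#' Produces the full desk-scale corpus: for every cohort of the planted tree,
#' `n_pos` positive and `n_neg` negative slides of `patches_per_slide` patches
#' each, textures diffused along the tree so cohort similarity follows the
#' planted truth. Deterministic given `(hierarchy, config, seed)`.
#'
#' @param hierarchy a `planted_hierarchy`.
#' @param config a [generation_config()].
#' @param seed integer master seed.
#' @return a `multicohort_dataset`: list with `slides` (tibble: `slide_id`,
#'   `patient_id`, `cohort`, `label`, `tumor_fraction`, `n_patches`),
#'   `patches` (tibble: `slide_id`, `cohort`, `patch_index`, `assigned_label`,
#'   `latent_state`, `row`: the patch's column in the pixel matrix),
#'   `pixels` (numeric matrix, one flat patch per column), `params`,
#'   `hierarchy`, `config`, `seed`, and a content `digest`.
#' @export
generate_dataset <- function(hierarchy, config = generation_config(), seed = 1L) {
  assert_that(inherits(hierarchy, "planted_hierarchy"), "not a planted_hierarchy")
  assert_that(config$n_pos >= 1 && config$n_neg >= 1,
              "need at least one slide per class")
  params <- derive_cohort_params(
    hierarchy, sigma_walk = config$sigma_walk,
    cancer_effect = config$cancer_effect,
    shared_cancer_weight = config$shared_cancer_weight, seed = seed,
    direction_groups = config$direction_groups,
    direction_jitter = config$direction_jitter %||% 0.15)
  ppsl <- config$patches_per_slide
  sl_id <- character(0); sl_pt <- character(0); sl_co <- character(0)
  sl_lab <- integer(0); sl_tf <- numeric(0)
  p_slide <- list(); p_lab <- list(); p_lat <- list()
  pixel_blocks <- list()
  for (ci in seq_len(hierarchy$n_cohorts)) {
    cohort <- params$cohort[ci]
    prow <- params[ci, ]
    n_paired <- round(config$paired_patient_frac * min(config$n_pos, config$n_neg))
    for (cls in c(1L, 0L)) {
      n_slides <- if (cls == 1L) config$n_pos else config$n_neg
      for (k in seq_len(n_slides)) {
        slide_id <- sprintf("%s_%s%03d", cohort, if (cls == 1L) "P" else "N", k)
        patient_id <- if (k <= n_paired) sprintf("pt_%s_pair%03d", cohort, k)
                      else sprintf("pt_%s_%s%03d", cohort, if (cls == 1L) "P" else "N", k)
        sl <- generate_slide(
          prow, label = cls, patches_per_slide = ppsl,
          tumor_fraction = config$tumor_fraction, config = config,
          seed = substream_seed(seed, "dataset", cohort, cls, k))
        sl_id <- c(sl_id, slide_id); sl_pt <- c(sl_pt, patient_id)
        sl_co <- c(sl_co, cohort); sl_lab <- c(sl_lab, cls)
        sl_tf <- c(sl_tf, if (cls == 1L) config$tumor_fraction else 0)
        p_slide[[length(p_slide) + 1L]] <- slide_id
        p_lab[[length(p_lab) + 1L]] <- sl$patches$assigned_label
        p_lat[[length(p_lat) + 1L]] <- sl$patches$latent_state
        pixel_blocks[[length(pixel_blocks) + 1L]] <- sl$pixels
      }
    }
  }
  pixels <- do.call(cbind, pixel_blocks)
  n_slides_total <- length(sl_id)
  ds <- structure(list(
    slides = tibble(slide_id = sl_id, patient_id = sl_pt, cohort = sl_co,
                    label = sl_lab, tumor_fraction = sl_tf,
                    n_patches = ppsl),
    patches = tibble(
      slide_id = rep(sl_id, each = ppsl),
      cohort = rep(sl_co, each = ppsl),
      patch_index = rep(seq_len(ppsl), times = n_slides_total),
      assigned_label = unlist(p_lab),
      latent_state = unlist(p_lat),
      row = seq_len(ncol(pixels))),
    pixels = pixels,
    params = params, hierarchy = hierarchy, config = config, seed = seed
  ), class = "multicohort_dataset")
  # strided pixel signature keeps the digest cheap on large corpora while
  # still changing whenever any generation input changes
  pixel_sig <- round(pixels[seq(1, length(pixels), by = 101L)], 12)
  ds$digest <- dataset_digest(list(ds$slides, ds$patches, dim(pixels),
                                   sum(pixels), pixel_sig))
  ds
}

#' @export
print.multicohort_dataset <- function(x, ...) {
  cat("Synthetic multi-cohort dataset:", x$hierarchy$n_cohorts, "cohorts,",
      nrow(x$slides), "slides,", nrow(x$patches), "patches of",
      x$config$patch_size, "x", x$config$patch_size, "px\n")
  cat("  digest:", x$digest, "\n")
  invisible(x)
}

#' Reshape a flat patch vector to an H x W x 3 array (and back)
#'
#' @param pixels numeric vector of length `3 * size^2` (channel blocks R, G,
#'   B, each column-major), or an array for [flatten_patch()].
#' @param size patch side length.
#' @return an `size x size x 3` array with values in `[0, 1]`.
#' @export
patch_array <- function(pixels, size = as.integer(sqrt(length(pixels) / 3))) {
  assert_that(length(pixels) == 3 * size * size, "pixel length mismatch")
  array(pixels, dim = c(size, size, 3))
}

#' @rdname patch_array
#' @param arr an `size x size x 3` array.
#' @export
flatten_patch <- function(arr) as.vector(arr)

#' Write the slide manifest of a dataset as CSV
#'
#' @param dataset a `multicohort_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  write.csv(dataset$slides, path, row.names = FALSE)
  invisible(path)
}
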