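#' Diffuse cohort texture parameters along the planted tree
#'
#' Each cohort gets a parameter vector `theta` describing its texture
#' (per-channel colour means, spatial-frequency band, blob density, blob
#' contrast) plus a unit `cancer_direction` along which the texture shifts on
#' latent cancer patches. `theta` evolves by Brownian motion along the planted
#' tree, so the expected squared distance between two cohorts' parameters is
#' proportional to their cophenetic (tree path) distance: cohorts that merge
#' low look alike. The cancer direction is a convex mix of one shared global
#' direction and a cohort-private direction; the private components are
#' themselves diffused along the tree, so both a cohort's baseline texture
#' and the way cancer perturbs it resemble its neighbours' — detection
#' models transfer best to nearby cohorts.
#'
#' @param hierarchy a `planted_hierarchy`.
#' @param sigma_walk positive Brownian step scale per unit tree height.
#' @param cancer_effect nonnegative magnitude of the cancer shift in theta
#'   space.
#' @param shared_cancer_weight in `[0, 1]`; 1 makes all cohorts share one
#'   cancer direction, 0 makes each direction private.
#' @param seed integer seed.
#' @param direction_groups `NULL` (default) diffuses the private components
#'   along the tree by Brownian motion; an integer `S0` instead assigns each
#'   of the `S0` tree groups one direction of a random orthonormal frame
#'   (jittered per cohort), guaranteeing distinct cancer morphology across
#'   groups.
#' @param direction_jitter per-cohort jitter scale in the orthogonal layout.
#' @return a tibble with one row per cohort: `cohort`, list-columns `theta`
#'   and `cancer_direction`, and `cancer_effect`.
#' @export
derive_cohort_params <- function(hierarchy, sigma_walk = 1, cancer_effect = 1,
                                 shared_cancer_weight = 0.25, seed = 1L,
                                 direction_groups = NULL,
                                 direction_jitter = 0.15) {
  assert_that(inherits(hierarchy, "planted_hierarchy"), "not a planted_hierarchy")
  assert_that(sigma_walk > 0, "sigma_walk must be > 0")
  assert_that(cancer_effect >= 0, "cancer_effect must be >= 0")
  assert_that(shared_cancer_weight >= 0 && shared_cancer_weight <= 1,
              "shared_cancer_weight must lie in [0, 1]")
  d <- 6L  # r, g, b mean; frequency band; blob density; blob contrast
  tr <- ape::as.phylo(hierarchy$hc)
  withr::local_seed(substream_seed(seed, "cohort-params"))
  theta <- phytools::fastBM(tr, sig2 = sigma_walk^2, nsim = d)
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1)
  theta <- theta[hierarchy$hc$labels, , drop = FALSE]
  shared <- rnorm(d)
  shared <- shared / sqrt(sum(shared^2))
  if (is.null(direction_groups)) {
    # private components diffuse along the tree like theta, so the cancer
    # shift also resembles the neighbours' on average
    priv_bm <- phytools::fastBM(tr, sig2 = 1, nsim = d)
    if (is.null(dim(priv_bm))) priv_bm <- matrix(priv_bm, ncol = 1)
    priv <- priv_bm[hierarchy$hc$labels, , drop = FALSE]
  } else {
    # orthogonal planting: every group at the requested tree level gets one
    # direction of a random orthonormal frame, jittered per cohort, so
    # cancer morphology is *guaranteed* distinct across groups (Brownian
    # directions in few dimensions can align by chance)
    assert_that(direction_groups >= 1 && direction_groups <= d,
                "direction_groups must lie in 1..6 (the parameter dimension)")
    g <- partition_at(hierarchy, direction_groups)
    frame <- qr.Q(qr(matrix(rnorm(d * d), d)))[, seq_len(direction_groups),
                                               drop = FALSE]
    priv <- t(vapply(seq_len(hierarchy$n_cohorts), function(i) {
      frame[, g[[hierarchy$hc$labels[i]]]] + direction_jitter * rnorm(d)
    }, numeric(d)))
  }
  dirs <- lapply(seq_len(hierarchy$n_cohorts), function(i) {
    p <- priv[i, ]
    p <- p / sqrt(sum(p^2))
    v <- shared_cancer_weight * shared + (1 - shared_cancer_weight) * p
    v / sqrt(sum(v^2))
  })
  tibble(
    cohort = hierarchy$hc$labels,
    theta = lapply(seq_len(hierarchy$n_cohorts), function(i) theta[i, ]),
    cancer_direction = dirs,
    cancer_effect = cancer_effect
  )
}
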