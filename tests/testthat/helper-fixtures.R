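# Shared fixtures. Small datasets for unit tests; the full study fixture
# (6 cohorts in three well-separated planted pairs, generator defaults, five
# sub-datasets) is computed once per seed and cached across test files.

tiny_generation <- function(patches_per_slide = 4, patch_size = 8,
                            n_pos = 10, n_neg = 10, ...) {
  generation_config(n_pos = n_pos, n_neg = n_neg,
                    patches_per_slide = patches_per_slide,
                    patch_size = patch_size, ...)
}

tiny_dataset <- function(n_cohorts = 4, seed = 7, ...) {
  layout <- if (n_cohorts %% 2 == 0) planted_pairs_layout(n_cohorts)
            else "balanced"
  h <- generate_planted_hierarchy(n_cohorts, layout, seed = seed)
  generate_dataset(h, tiny_generation(...), seed = seed)
}

tiny_subdatasets <- function(dataset, n_subdatasets = 2, n_train = 4,
                             n_heldout = 4, seed = 11) {
  sample_subdatasets(dataset, n_subdatasets = n_subdatasets,
                     n_train_pos = n_train, n_train_neg = n_train,
                     n_heldout_pos = n_heldout, n_heldout_neg = n_heldout,
                     seed = seed)
}

# --- study fixture -----------------------------------------------------------

study_layout <- function() planted_pairs_layout(6, pair_height = 0.01,
                                                step = 2)

study_generation <- function() generation_config()

.fixture_cache <- new.env(parent = emptyenv())

# full pipeline products for one seed; `keep_models` retains the dataset and
# fit cache (needed for the super-cohort sweep) - only requested for one seed
# to bound memory
study_fixture <- function(seed, keep_models = FALSE) {
  key <- sprintf("fix_%d_%d", seed, keep_models)
  got <- .fixture_cache[[key]]
  if (!is.null(got)) return(got)
  h <- generate_planted_hierarchy(6, study_layout(), seed = seed)
  ds <- generate_dataset(h, study_generation(), seed = seed)
  subs <- sample_subdatasets(ds, seed = seed + 1)
  cfg <- training_config(seed = seed)
  cache <- new.env(parent = emptyenv())
  singles <- train_single_models(ds, subs, cfg, cache = cache)
  mats <- list(detection_C = cross_cohort_detection_matrix(singles, ds, subs))
  for (cond in c("negative", "positive", "general")) {
    disc <- train_cohort_discriminators(ds, subs, cond, cfg)
    mats[[paste0("disc_", cond)]] <- discrimination_confidence_matrix(
      disc, ds, subs, cond, patches_per_slide = 16, seed = seed)
  }
  dendros <- lapply(mats, build_dendrogram)
  truth <- partition_at(h, 3)
  aris <- vapply(dendros, function(d) {
    part <- cut_to_supercohorts(d, 3)
    pairs_ari(part, truth)
  }, numeric(1))
  out <- list(hierarchy = h, matrices = mats, dendrograms = dendros,
              truth = truth, aris = aris, seed = seed,
              singles_epochs = vapply(singles$fit,
                                      function(f) f$record$epochs_trained,
                                      numeric(1)))
  if (keep_models) {
    out$dataset <- ds; out$subs <- subs; out$cfg <- cfg
    out$cache <- cache; out$singles <- singles
  }
  .fixture_cache[[key]] <- out
  out
}

pairs_ari <- function(partition, truth) {
  g <- partition$group[match(names(truth), partition$cohort)]
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(g, truth)
  } else {
    ari_from_tables(g, truth)
  }
}

# contingency-table ARI, used when mclust is unavailable
ari_from_tables <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  row_c <- sum_comb(rowSums(tab)); col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  maxi <- (row_c + col_c) / 2
  (idx - expected) / (maxi - expected)
}

# brute-force Ward agglomeration oracle: recompute the merge cost of every
# cluster pair from scratch at each step (cost = increase in within-cluster
# sum of squares; reported height matches hclust's ward.D2 scale)
ward_oracle <- function(V) {
  pts <- t(V)  # one row per cohort column vector
  clusters <- lapply(seq_len(nrow(pts)), function(i) i)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ca <- colMeans(pts[clusters[[a]], , drop = FALSE])
        cb <- colMeans(pts[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]]); nb <- length(clusters[[b]])
        cost <- na * nb / (na + nb) * sum((ca - cb)^2)
        if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(a, b) }
      }
    }
    heights <- c(heights, sqrt(2 * best_cost))
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# canonical form of a partition for label-free comparison
canonical_partition <- function(groups) {
  unname(sort(vapply(split(seq_along(groups), groups),
                     function(ix) paste(sort(ix), collapse = ","),
                     character(1))))
}
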