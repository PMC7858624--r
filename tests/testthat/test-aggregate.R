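fake_eval <- function(kind, S, mean_auroc, hw = 0.01, epochs = 10 * S) {
  structure(list(per_cohort = tibble::tibble(cohort = "x", mean_auroc = mean_auroc),
                 per_sub = NULL, mean_auroc = mean_auroc, ci_halfwidth = hw,
                 per_group_epochs = NULL, total_epochs = epochs,
                 S = S, kind = kind), class = "partition_evaluation")
}

test_that("Ward trees match a from-scratch agglomeration oracle", {
  withr::with_seed(100, {
    for (i in 1:20) {
      n <- sample(3:8, 1)
      V <- matrix(runif(n * n), n, dimnames = list(paste0("c", 1:n),
                                                   paste0("c", 1:n)))
      m <- similarity_matrix(V, "detection_C", paste0("c", 1:n))
      d <- build_dendrogram(m)
      oracle <- ward_oracle(unclass(m))
      expect_equal(sort(d$hc$height), sort(oracle$heights), tolerance = 1e-8)
      for (k in seq_len(n)) {
        part <- cut_to_supercohorts(d, k)
        expect_equal(length(unique(part$group)), k)
      }
      # the first merge is the oracle's first merge
      first <- sort(abs(d$hc$merge[1, ]))
      expect_equal(first, oracle$merges[[1]])
    }
  })
})

test_that("identical columns merge first at height zero", {
  V <- matrix(c(0.9, 0.1, 0.2,
                0.9, 0.1, 0.2,
                0.1, 0.8, 0.7), 3,
              dimnames = list(NULL, NULL))
  m <- similarity_matrix(V / rowSums(V), "disc_general", c("a", "b", "c"))
  # columns 1 and 2 of the row-normalized matrix are identical by construction
  d <- build_dendrogram(m)
  expect_equal(d$hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(d$hc$merge[1, ]), c(1, 2))
})

test_that("a planted two-pair matrix clusters into its pairs", {
  V <- rbind(c(0.45, 0.45, 0.05, 0.05),
             c(0.44, 0.46, 0.05, 0.05),
             c(0.06, 0.04, 0.44, 0.46),
             c(0.05, 0.05, 0.45, 0.45))
  m <- similarity_matrix(V, "disc_general", paste0("c", 1:4))
  d <- build_dendrogram(m)
  part <- cut_to_supercohorts(d, 2)
  expect_identical(canonical_partition(part$group), c("1,2", "3,4"))
  # brute-force check over all pairings: the first two oracle merges agree
  oracle <- ward_oracle(unclass(m))
  expect_identical(oracle$merges[[1]],
                   sort(abs(d$hc$merge[1, ])))
})

test_that("dendrogram cuts cover the boundary cases and reject bad S", {
  h <- generate_planted_hierarchy(5, "random", seed = 2)
  p1 <- cut_to_supercohorts(h, 1)
  expect_equal(length(unique(p1$group)), 1)
  p5 <- cut_to_supercohorts(h, 5)
  expect_equal(length(unique(p5$group)), 5)
  expect_error(cut_to_supercohorts(h, 0), class = "invalid_argument")
  expect_error(cut_to_supercohorts(h, 6), class = "invalid_argument")
  expect_error(build_dendrogram(matrix(c(1, NA, 1, 1), 2)),
               class = "invalid_argument")
})

test_that("the confidence halfwidth matches the closed t form", {
  expect_equal(mean_ci(c(0.5, 0.5, 0.5))$halfwidth, 0)
  ci <- mean_ci(c(0, 1))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$halfwidth, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(ci$halfwidth, 6.3531, tolerance = 1e-4)
  # halfwidth shrinks with n at fixed sd
  hw <- vapply(c(4, 8, 16), function(n) {
    x <- rep(c(0, 1), n / 2)
    mean_ci(x)$halfwidth
  }, numeric(1))
  expect_true(all(diff(hw) < 0))
  expect_error(mean_ci(0.5), class = "invalid_argument")
})

test_that("the CI gate qualifies and selects as specified", {
  ref <- fake_eval("single", 6, 0.96, hw = 0.02, epochs = 60)
  evals <- list(fake_eval("detection_C", 2, 0.95, epochs = 25),
                fake_eval("detection_C", 3, 0.93, epochs = 30),
                fake_eval("disc_negative", 2, 0.95, epochs = 18),
                fake_eval("single", 6, 0.96, epochs = 60))
  sel <- select_partitions(evals, ref)
  expect_false(sel$empty)
  expect_setequal(sel$qualifying$kind[sel$qualifying$S == 2],
                  c("detection_C", "disc_negative"))
  expect_false(any(sel$qualifying$mean_auroc < 0.94))
  # S = N always qualifies (mean >= mean - halfwidth)
  expect_true("single" %in% sel$qualifying$kind)
  expect_equal(sel$min_time_choice$kind, "disc_negative")
  expect_equal(sel$min_time_choice$total_epochs, 18)
  expect_equal(sel$best_performance_choice$mean_auroc, 0.96)
  # tie on AUROC: smaller S, then kind order
  evals2 <- list(fake_eval("b_kind", 3, 0.95, epochs = 30),
                 fake_eval("a_kind", 3, 0.95, epochs = 30))
  sel2 <- select_partitions(evals2, fake_eval("single", 4, 0.95, 0.01, 40))
  expect_equal(sel2$min_time_choice$kind, "a_kind")
  # an unreachable reference empties the qualifying set
  sel3 <- select_partitions(evals, fake_eval("single", 6, 1.99, 1e-6, 60))
  expect_true(sel3$empty)
  expect_null(sel3$min_time_choice)
})

test_that("partition evaluation sums group epochs into training time", {
  ds <- tiny_dataset(n_cohorts = 2, seed = 95)
  subs <- tiny_subdatasets(ds, n_subdatasets = 2, seed = 8)
  cfg <- training_config(seed = 5, max_epochs = 2)
  part <- cut_to_supercohorts(ds$hierarchy, 2)
  models <- train_supercohort_models(part, ds, subs, cfg)
  ev <- evaluate_partition(models, part, ds, subs)
  by_hand <- tapply(vapply(models$fit, function(f) f$record$epochs_trained,
                           numeric(1)), models$group, mean)
  expect_equal(ev$total_epochs, sum(by_hand))
  expect_equal(ev$S, 2)
  expect_true(all(ev$per_cohort$mean_auroc >= 0 &
                    ev$per_cohort$mean_auroc <= 1))
  expect_equal(nrow(ev$per_sub), 2 * 2)
  # all-identical per-cohort AUROCs give a zero halfwidth
  ev0 <- ev
  ci <- mean_ci(rep(0.9, 4))
  expect_equal(ci$halfwidth, 0)
})

test_that("singleton groups reproduce the direct training path bit for bit", {
  ds <- tiny_dataset(n_cohorts = 2, seed = 96)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 8)
  cfg <- training_config(seed = 13, max_epochs = 3)
  # engine path
  fit_engine <- train_group_detection_model(ds, subs, "C02", 1, cfg)
  # independent assembly: same derived seed, manually filtered streams
  man <- dplyr::filter(tibble::as_tibble(subs), sub_index == 1,
                       cohort == "C02")
  cfg2 <- cfg
  cfg2$seed <- supercohort:::substream_seed(cfg$seed, "detection", "C02", 1)
  fit_direct <- train_patch_model(
    assign_patch_labels(ds, dplyr::filter(man, role == "train"), "detection"),
    assign_patch_labels(ds, dplyr::filter(man, role == "val"), "detection"),
    cfg2)
  expect_identical(fit_engine$model$params, fit_direct$model$params)
  expect_identical(fit_engine$record$trace, fit_direct$record$trace)
})
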