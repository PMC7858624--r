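# Well-separated two-cohort dataset: distant cohorts, clean positive patches
separable_dataset <- function(seed = 77) {
  layout <- list(merge = matrix(c(-1L, -2L), 1), height = 4)
  h <- generate_planted_hierarchy(2, layout, seed = seed)
  generate_dataset(
    h, tiny_generation(n_pos = 12, n_neg = 12, patches_per_slide = 6,
                       tumor_fraction = 1, cancer_effect = 2),
    seed = seed)
}

test_that("patch labels come from slide metadata, never the latent state", {
  ds <- tiny_dataset(n_cohorts = 2, seed = 13)
  man <- ds$slides
  st <- assign_patch_labels(ds, man, "detection")
  # positive slides with tumor_fraction < 1 still label all patches positive
  pos_rows <- ds$patches$assigned_label == 1
  expect_true(any(ds$patches$latent_state[pos_rows] == "normal"))
  expect_equal(sort(unique(st$labels)), c(1L, 2L))
  expect_equal(st$labels, ds$patches$assigned_label[
    match(st$rows, ds$patches$row)] + 1L)

  disc <- assign_patch_labels(ds, man, "discrimination")
  expect_equal(disc$class_levels, c("C01", "C02"))
  # negative-condition stream holds no patches from positive slides
  subs <- tiny_subdatasets(ds, seed = 2)
  neg_man <- build_discrimination_splits(subs, "negative")
  neg_st <- assign_patch_labels(ds, neg_man, "discrimination")
  src_labels <- ds$patches$assigned_label[match(neg_st$rows, ds$patches$row)]
  expect_true(all(src_labels == 0L))
})

test_that("the stopping rule replays exactly on crafted traces", {
  # no improvement after epoch 1: stops at 1 + patience
  r <- epochs_from_trace(rep(0.5, 20), patience = 5)
  expect_equal(r$epochs_trained, 6)
  expect_false(r$truncated)
  # monotone improvement: runs to the end, truncated
  r2 <- epochs_from_trace(seq(0.1, 0.9, length.out = 10), patience = 5)
  expect_equal(r2$epochs_trained, 10)
  expect_true(r2$truncated)
  # tolerance turns sub-threshold gains into non-improvements
  r3 <- epochs_from_trace(c(0.5, 0.5005, 0.501, 0.5015, 0.502, 0.5025),
                          patience = 3, tol = 0.01)
  expect_equal(r3$epochs_trained, 4)
})

test_that("training separates a clean two-cohort fixture", {
  ds <- separable_dataset()
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 3)
  man <- split_subdatasets(subs)[[1]]
  cfg <- training_config(seed = 5, max_epochs = 15)
  tr <- assign_patch_labels(ds, man[man$role == "train", ], "discrimination")
  va <- assign_patch_labels(ds, man[man$role == "val", ], "discrimination")
  fit <- train_patch_model(tr, va, cfg)
  expect_gte(fit$record$best_val_accuracy, 0.95)
  expect_equal(length(fit$record$trace), fit$record$epochs_trained)
  te <- assign_patch_labels(ds, man[man$role == "test", ], "discrimination")
  P <- predict_patch(fit$model, te)
  acc <- mean(max.col(P) == te$labels)
  expect_gt(acc, 0.9)
})

test_that("training is deterministic given the config seed", {
  ds <- separable_dataset(seed = 78)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 3)
  man <- split_subdatasets(subs)[[1]]
  cfg <- training_config(seed = 11, max_epochs = 3)
  tr <- assign_patch_labels(ds, man[man$role == "train", ], "detection")
  va <- assign_patch_labels(ds, man[man$role == "val", ], "detection")
  f1 <- train_patch_model(tr, va, cfg)
  f2 <- train_patch_model(tr, va, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$record$trace, f2$record$trace)
})

test_that("prediction rows are normalized, deterministic, shape-checked", {
  ds <- separable_dataset(seed = 79)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 3)
  man <- split_subdatasets(subs)[[1]]
  cfg <- training_config(seed = 7, max_epochs = 2)
  fit <- train_patch_model(
    assign_patch_labels(ds, man[man$role == "train", ], "detection"),
    assign_patch_labels(ds, man[man$role == "val", ], "detection"), cfg)
  X <- ds$pixels[, c(1, 1, 5), drop = FALSE]  # duplicated patch
  P <- predict_patch(fit$model, X)
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-6)
  expect_identical(P[1, ], P[2, ])
  expect_identical(P, predict_patch(fit$model, X))
  expect_error(predict_patch(fit$model, matrix(0.5, 10, 2)),
               class = "invalid_argument")

  FF <- extract_features(fit$model, X)
  expect_identical(FF[1, ], FF[2, ])
  expect_equal(ncol(FF), fit$model$feature_dim)
  expect_true(all(is.finite(FF)))
})

test_that("penultimate features separate distant cohorts", {
  ds <- separable_dataset(seed = 80)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 3)
  man <- split_subdatasets(subs)[[1]]
  cfg <- training_config(seed = 7, max_epochs = 10)
  fit <- train_patch_model(
    assign_patch_labels(ds, man[man$role == "train", ], "discrimination"),
    assign_patch_labels(ds, man[man$role == "val", ], "discrimination"), cfg)
  te <- assign_patch_labels(ds, man[man$role == "test", ], "discrimination")
  FF <- extract_features(fit$model, te)
  D <- as.matrix(dist(FF))
  same <- outer(te$labels, te$labels, "==")
  within <- mean(D[same & upper.tri(D)])
  between <- mean(D[!same & upper.tri(D)])
  expect_gt(between, within)
})

test_that("a constant-label stream stops after exactly 1 + patience epochs", {
  ds <- tiny_dataset(n_cohorts = 2, seed = 14)
  neg_slides <- ds$slides[ds$slides$label == 0 & ds$slides$cohort == "C01", ]
  st <- assign_patch_labels(ds, neg_slides, "detection")
  cfg <- training_config(seed = 3, patience_epochs = 4, max_epochs = 30)
  fit <- train_patch_model(st, st, cfg)
  expect_equal(fit$record$epochs_trained, 1 + 4)
  expect_false(fit$record$truncated)
})

test_that("degenerate inputs are rejected and truncation is flagged", {
  ds <- separable_dataset(seed = 81)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 3)
  man <- split_subdatasets(subs)[[1]]
  tr <- assign_patch_labels(ds, man[man$role == "train", ], "detection")
  empty <- assign_patch_labels(ds, ds$slides[0, ], "detection")
  expect_error(train_patch_model(empty, tr), class = "invalid_argument")
  cfg <- training_config(seed = 3, max_epochs = 2)
  fit <- train_patch_model(tr, tr, cfg)
  expect_true(fit$record$truncated)
  expect_equal(fit$record$epochs_trained, 2)
})
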