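uniform_model <- function(n_classes, class_levels, size = 8, d_in = 11,
                          hidden = 4) {
  structure(list(
    task = "discrimination", n_classes = n_classes,
    class_levels = class_levels, feature_dim = hidden, patch_size = size,
    params = list(W1 = matrix(0, d_in, hidden), b1 = rep(0, hidden),
                  W2 = matrix(0, hidden, n_classes), b2 = rep(0, n_classes)),
    f_mu = rep(0, d_in), f_sd = rep(1, d_in),
    config = training_config()), class = "trained_patch_model")
}

test_that("similarity matrices enforce their declared invariants", {
  ok <- similarity_matrix(diag(2) * 0.5 + 0.25, "detection_C", c("a", "b"))
  expect_s3_class(ok, "similarity_matrix")
  expect_error(similarity_matrix(matrix(2, 2, 2), "detection_C", c("a", "b")),
               class = "invalid_argument")
  expect_error(similarity_matrix(matrix(0.3, 2, 2), "disc_general",
                                 c("a", "b")),
               class = "invalid_argument")
  row_stochastic <- matrix(c(0.7, 0.2, 0.3, 0.8), 2)
  m <- similarity_matrix(row_stochastic, "disc_negative", c("a", "b"))
  expect_equal(attr(m, "row_semantics"), "origin cohort i")
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_equal(td$value[td$origin == "a" & td$predicted == "b"], 0.3)
})

test_that("a uniform-probability model yields the flat confusion matrix", {
  ds <- tiny_dataset(n_cohorts = 3, seed = 91)
  subs <- tiny_subdatasets(ds, n_subdatasets = 2, seed = 5)
  disc <- tibble::tibble(
    sub_index = 1:2,
    fit = lapply(1:2, function(i) list(
      model = uniform_model(3, sort(unique(ds$slides$cohort))),
      record = NULL)))
  M <- discrimination_confidence_matrix(disc, ds, subs, "negative",
                                        patches_per_slide = 4, seed = 1)
  expect_equal(unname(unclass(M)), matrix(1 / 3, 3, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("evaluation patch budgets match the counting identity", {
  ds <- tiny_dataset(n_cohorts = 3, seed = 92)
  subs <- tiny_subdatasets(ds, n_subdatasets = 2, seed = 6)
  disc <- tibble::tibble(
    sub_index = 1:2,
    fit = lapply(1:2, function(i) list(
      model = uniform_model(3, sort(unique(ds$slides$cohort))),
      record = NULL)))
  n_val_slides <- 2  # heldout 4 per class -> val 2 of the class
  M <- discrimination_confidence_matrix(disc, ds, subs, "positive",
                                        patches_per_slide = 3, seed = 2)
  expect_equal(attr(M, "n_patches_used"),
               discrimination_patch_budget(3, n_val_slides, 2, 3))
  # short slides trigger replacement sampling with a warning
  expect_warning(
    discrimination_confidence_matrix(disc, ds, subs, "positive",
                                     patches_per_slide = 10, seed = 2),
    regexp = "replacement")
})

test_that("the H-divergence proxy is the affine error-rate map", {
  expect_equal(hdivergence_proxy(0.5), 0)
  expect_equal(hdivergence_proxy(0), 2)
  expect_equal(hdivergence_proxy(0.25), 1)
  eps <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(hdivergence_proxy(eps)) < 0))
  expect_equal(hdivergence_proxy(eps), 2 * (1 - 2 * eps))
  expect_error(hdivergence_proxy(0.6), class = "invalid_argument")
  expect_error(hdivergence_proxy(-0.1), class = "invalid_argument")
})

test_that("similarity matrices survive the CSV round trip", {
  V <- matrix(c(0.6, 0.3, 0.4, 0.7), 2, dimnames = NULL)
  m <- similarity_matrix(V, "disc_general", c("C01", "C02"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(m, path)
  m2 <- read_similarity_csv(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
  expect_equal(attr(m2, "kind"), "disc_general")
})

test_that("discriminator training streams respect the condition filter", {
  ds <- tiny_dataset(n_cohorts = 2, seed = 93)
  subs <- tiny_subdatasets(ds, n_subdatasets = 1, seed = 7)
  cfg <- training_config(seed = 1, max_epochs = 2)
  fit <- train_cohort_discriminator(ds, subs, "negative", 1, cfg)
  expect_equal(fit$model$n_classes, 2)
  expect_equal(fit$model$class_levels, c("C01", "C02"))
  expect_error(train_cohort_discriminator(ds, subs, "sideways", 1, cfg))
})
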