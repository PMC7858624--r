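small_experiment_config <- function(outdir = NULL, seed = 5) {
  experiment_config(
    n_cohorts = 4,
    generation = tiny_generation(n_pos = 10, n_neg = 10),
    training = training_config(seed = seed, max_epochs = 3),
    matrix_kinds = c("detection_C", "disc_general"),
    S_values = c(1, 2, 4),
    n_subdatasets = 2, n_train = 4, n_heldout = 4,
    seed = seed, outdir = outdir)
}

test_that("the orchestrated experiment emits a complete report bundle", {
  outdir <- withr::local_tempdir()
  res <- run_experiment(small_experiment_config(outdir))
  expect_named(res$matrices, c("detection_C", "disc_general"))
  expect_equal(nrow(res$selection$table), 2 * 3)
  expect_true(any(res$selection$table$qualifies))
  for (f in c("slides.csv", "subdatasets.csv", "detection_C.csv",
              "disc_general.csv", "detection_C.nwk", "tradeoff.csv",
              "selection.json", "summary.txt", "planted_hierarchy.nwk")) {
    expect_true(file.exists(file.path(outdir, f)), label = f)
  }
  sel <- jsonlite::read_json(file.path(outdir, "selection.json"))
  expect_true(is.numeric(sel$reference_lower))
  # the S = N sweep entry reproduces the reference configuration's AUROC
  tabN <- res$selection$table[res$selection$table$S == 4, ]
  expect_equal(unique(round(tabN$mean_auroc, 10)),
               round(res$reference$mean_auroc, 10))
})

test_that("resuming a finished run is a stage-level no-op", {
  outdir <- withr::local_tempdir()
  cfg <- small_experiment_config(outdir)
  res1 <- run_experiment(cfg)
  before <- unclass(file.mtime(file.path(outdir, "dataset.rds")))
  res2 <- run_experiment(cfg, resume = TRUE)
  after <- unclass(file.mtime(file.path(outdir, "dataset.rds")))
  expect_equal(before, after)
  expect_identical(res1$dataset$digest, res2$dataset$digest)
  expect_equal(unclass(res1$matrices$detection_C),
               unclass(res2$matrices$detection_C), tolerance = 1e-12)
})

test_that("experiment configs validate eagerly and read from YAML", {
  expect_error(experiment_config(n_cohorts = 1), class = "invalid_argument")
  expect_error(experiment_config(matrix_kinds = "nope"),
               class = "invalid_argument")
  expect_error(experiment_config(S_values = 99), class = "invalid_argument")
  expect_error(
    experiment_config(generation = tiny_generation(n_pos = 5, n_neg = 5)),
    class = "invalid_argument")
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cohorts: 4", "seed: 9", "n_train: 4", "n_heldout: 4",
               "generation:", "  n_pos: 10", "  n_neg: 10",
               "  patches_per_slide: 4", "  patch_size: 8"), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$n_cohorts, 4)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$generation$n_pos, 10)
})

test_that("feature embedding is decorative, shaped, and optional", {
  withr::with_seed(3, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    X[31:60, ] <- X[1:30, ]  # duplicated rows
    co <- embed_features(X, method = "pca")
    expect_equal(dim(co), c(60, 2))
    expect_equal(co[1:30, ], co[31:60, ], ignore_attr = TRUE)
    expect_error(embed_features(X[1:2, , drop = FALSE], method = "pca"),
                 class = "invalid_argument")
    expect_error(embed_features(X[1:10, , drop = FALSE], n_neighbors = 20),
                 class = "invalid_argument")
    if (requireNamespace("uwot", quietly = TRUE)) {
      um <- embed_features(X, n_neighbors = 5, seed = 1)
      expect_equal(dim(um), c(60, 2))
    } else {
      expect_message(out <- embed_features(X), regexp = "skip")
      expect_null(out)
    }
  })
})

test_that("plot builders return ggplot objects without evaluation errors", {
  V <- matrix(c(0.6, 0.3, 0.4, 0.7), 2)
  m <- similarity_matrix(V, "disc_general", c("C01", "C02"))
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
  tab <- tibble::tibble(kind = "detection_C", S = 1:2,
                        mean_auroc = c(0.8, 0.9), ci_halfwidth = 0.01,
                        total_epochs = c(10, 20), qualifies = TRUE)
  expect_s3_class(plot_tradeoff(tab), "ggplot")
})
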