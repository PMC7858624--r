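#' Construct a cohort similarity matrix
#'
#' A square matrix over cohorts with declared row/column semantics. Rows index
#' the origin (target) cohort `i`, columns the source/predicted cohort `j`.
#' For the detection kind, entries are cross-cohort AUROCs in `[0, 1]`; for
#' discrimination kinds, each row is a mean softmax over patches and sums
#' to 1.
#'
#' @param values numeric N x N matrix.
#' @param kind one of `"detection_C"`, `"disc_negative"`, `"disc_positive"`,
#'   `"disc_general"`.
#' @param cohort_names length-N unique cohort names.
#' @return a classed matrix with `kind`, `row_semantics`, `col_semantics`
#'   attributes.
#' @export
similarity_matrix <- function(values, kind = c("detection_C", "disc_negative",
                                               "disc_positive", "disc_general"),
                              cohort_names = rownames(values)) {
  kind <- match.arg(kind)
  assert_that(is.matrix(values) && nrow(values) == ncol(values),
              "values must be square")
  assert_that(all(is.finite(values)), "values must be finite")
  assert_that(!is.null(cohort_names) && !anyDuplicated(cohort_names),
              "cohort names must be unique")
  if (kind == "detection_C") {
    assert_that(all(values >= 0 & values <= 1),
                "detection entries must be AUROCs in [0, 1]")
  } else {
    assert_that(all(abs(rowSums(values) - 1) < 1e-6),
                "discrimination rows must sum to 1")
  }
  dimnames(values) <- list(cohort_names, cohort_names)
  structure(values, class = c("similarity_matrix", "matrix"), kind = kind,
            row_semantics = if (kind == "detection_C")
              "target (validation) cohort i" else "origin cohort i",
            col_semantics = if (kind == "detection_C")
              "source (train) cohort j" else "predicted cohort j")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity matrix [", attr(x, "kind"), "], rows = ",
      attr(x, "row_semantics"), ", cols = ", attr(x, "col_semantics"), "\n",
      sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    origin = rep(rownames(m), times = ncol(m)),
    predicted = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    kind = attr(x, "kind"))
}

# --- detection-model engine -------------------------------------------------

group_signature <- function(members) paste(sort(members), collapse = "+")

#' Train one cancer-detection model for a cohort group
#'
#' The single engine behind cohort-specific models (singleton group),
#' the universal model (all cohorts) and super-cohort models: pools the
#' training/validation slides of the member cohorts for one sub-dataset and
#' trains a detection patch model. The model seed is derived from the master
#' seed, the sorted member signature and the sub-dataset index, so a
#' singleton group reproduces the cohort-specific model bit for bit.
#'
#' @param dataset a `multicohort_dataset`.
#' @param subs a `subdataset_manifest`.
#' @param members character vector of member cohorts.
#' @param sub_index which sub-dataset to train on.
#' @param cfg a [training_config()]; its `seed` is the master seed.
#' @param aug an [augmentation_config()].
#' @param cache optional environment memoizing fits by (members, sub_index).
#' @return list with `model` and `record`.
#' @export
train_group_detection_model <- function(dataset, subs, members, sub_index,
                                        cfg = training_config(),
                                        aug = augmentation_config(),
                                        cache = NULL) {
  sig <- group_signature(members)
  key <- paste(sig, sub_index, sep = "@")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  man <- filter(as_tibble(subs), sub_index == !!sub_index, cohort %in% members)
  cfg$seed <- substream_seed(cfg$seed, "detection", sig, sub_index)
  fit <- train_patch_model(
    assign_patch_labels(dataset, filter(man, role == "train"), "detection"),
    assign_patch_labels(dataset, filter(man, role == "val"), "detection"),
    cfg, aug)
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

#' Train cohort-specific detection models
#'
#' One model per cohort per sub-dataset (the fully specialized, `S = N`
#' configuration).
#'
#' @inheritParams train_group_detection_model
#' @return a tibble: `cohort`, `sub_index`, `fit` (list of model + record).
#' @export
train_single_models <- function(dataset, subs, cfg = training_config(),
                                aug = augmentation_config(), cache = NULL) {
  cohorts <- sort(unique(subs$cohort))
  n_subs <- attr(subs, "n_subdatasets") %||% max(subs$sub_index)
  grid <- expand.grid(cohort = cohorts, sub_index = seq_len(n_subs),
                      stringsAsFactors = FALSE)
  grid$fit <- pmap(grid, function(cohort, sub_index) {
    train_group_detection_model(dataset, subs, cohort, sub_index, cfg, aug,
                                cache)
  })
  as_tibble(grid)
}

#' Cross-cohort detection similarity matrix
#'
#' Entry `v_ij` is the slide-level AUROC on target cohort `i` of the
#' cohort-specific model trained on source cohort `j`, averaged over the
#' sub-datasets, scored on the validation split (held out from training but
#' distinct from the final test slides used for partition evaluation).
#'
#' @param single_models output of [train_single_models()].
#' @param dataset a `multicohort_dataset`.
#' @param subs the `subdataset_manifest` the models were trained on.
#' @param split which held-out split to score (default `"val"`).
#' @return a `similarity_matrix` of kind `"detection_C"`.
#' @export
cross_cohort_detection_matrix <- function(single_models, dataset, subs,
                                          split = "val") {
  cohorts <- sort(unique(subs$cohort))
  n <- length(cohorts)
  acc <- matrix(0, n, n, dimnames = list(cohorts, cohorts))
  n_subs <- length(unique(single_models$sub_index))
  for (s in unique(single_models$sub_index)) {
    eval_man <- filter(as_tibble(subs), sub_index == s, role == split)
    for (j in seq_len(n)) {
      fit <- filter(single_models, cohort == cohorts[j], sub_index == s)$fit
      assert_that(length(fit) == 1, "missing model for a cohort/sub pair")
      model <- fit[[1]]$model
      for (i in seq_len(n)) {
        man_i <- filter(eval_man, cohort == cohorts[i])
        acc[i, j] <- acc[i, j] + detection_auroc(model, dataset, man_i)
      }
    }
  }
  similarity_matrix(acc / n_subs, "detection_C", cohorts)
}

# --- discrimination models --------------------------------------------------

#' Train a cohort-discrimination model
#'
#' A multi-class patch model predicting a patch's cohort of origin, trained
#' only on slides passing the condition filter (negative slides, positive
#' slides, or both for the general condition) of one sub-dataset.
#'
#' @param dataset a `multicohort_dataset`.
#' @param subs a `subdataset_manifest`.
#' @param condition `"negative"`, `"positive"` or `"general"`.
#' @param sub_index which sub-dataset to train on.
#' @param cfg a [training_config()].
#' @param aug an [augmentation_config()].
#' @return list with `model` and `record`.
#' @export
train_cohort_discriminator <- function(dataset, subs,
                                       condition = c("negative", "positive",
                                                     "general"),
                                       sub_index = 1,
                                       cfg = training_config(),
                                       aug = augmentation_config()) {
  condition <- match.arg(condition)
  assert_that(length(unique(subs$cohort)) >= 2, "need at least two cohorts")
  man <- build_discrimination_splits(subs, condition)
  man <- filter(as_tibble(man), sub_index == !!sub_index)
  cfg$seed <- substream_seed(cfg$seed, "discriminator", condition, sub_index)
  train_patch_model(
    assign_patch_labels(dataset, filter(man, role == "train"),
                        "discrimination"),
    assign_patch_labels(dataset, filter(man, role == "val"),
                        "discrimination"),
    cfg, aug)
}

#' Train discriminators for all sub-datasets
#'
#' @inheritParams train_cohort_discriminator
#' @return a tibble: `sub_index`, `fit`.
#' @export
train_cohort_discriminators <- function(dataset, subs, condition,
                                        cfg = training_config(),
                                        aug = augmentation_config()) {
  n_subs <- attr(subs, "n_subdatasets") %||% max(subs$sub_index)
  tibble(
    sub_index = seq_len(n_subs),
    fit = map(seq_len(n_subs), function(s) {
      train_cohort_discriminator(dataset, subs, condition, s, cfg, aug)
    }))
}

#' Discrimination confidence similarity matrix
#'
#' Entry `v_ij` is the mean predicted probability of cohort `j` over patches
#' sampled from slides originating in cohort `i`, pooled across sub-datasets.
#' Each evaluation slide contributes `patches_per_slide` patches, sampled
#' with replacement (with a warning) when a slide holds fewer. Rows sum
#' to 1.
#'
#' @param discriminators output of [train_cohort_discriminators()].
#' @param dataset a `multicohort_dataset`.
#' @param subs the `subdataset_manifest` the models were trained on.
#' @param condition the discrimination condition of the models.
#' @param patches_per_slide patches sampled per evaluation slide
#'   (default 100).
#' @param split held-out split to evaluate on (default `"val"`).
#' @param seed seed for patch sampling.
#' @return a `similarity_matrix` of kind `disc_<condition>`, with attribute
#'   `n_patches_used`.
#' @export
discrimination_confidence_matrix <- function(discriminators, dataset, subs,
                                             condition,
                                             patches_per_slide = 100,
                                             split = "val", seed = 1L) {
  condition <- match.arg(condition, c("negative", "positive", "general"))
  cohorts <- sort(unique(subs$cohort))
  n <- length(cohorts)
  man_all <- build_discrimination_splits(subs, condition)
  prob_sum <- matrix(0, n, n, dimnames = list(cohorts, cohorts))
  patch_count <- stats::setNames(numeric(n), cohorts)
  short_slides <- 0L
  for (s in discriminators$sub_index) {
    model <- filter(discriminators, sub_index == s)$fit[[1]]$model
    assert_that(model$n_classes == n,
                "model class count does not match cohort count")
    eval_man <- filter(as_tibble(man_all), sub_index == s, role == split)
    pt <- filter(dataset$patches, slide_id %in% eval_man$slide_id)
    rows <- integer(0); origin <- character(0)
    withr::local_seed(substream_seed(seed, "disc-matrix", condition, s))
    for (sl in unique(pt$slide_id)) {
      pr <- pt$row[pt$slide_id == sl]
      if (length(pr) < patches_per_slide) short_slides <- short_slides + 1L
      take <- if (length(pr) >= patches_per_slide)
        sample(pr, patches_per_slide) else
        sample(pr, patches_per_slide, replace = TRUE)
      rows <- c(rows, take)
      origin <- c(origin, rep(pt$cohort[match(sl, pt$slide_id)],
                              patches_per_slide))
    }
    P <- predict_patch(model, dataset$pixels[, rows, drop = FALSE])
    P <- P[, cohorts, drop = FALSE]
    agg <- rowsum(P, origin)
    prob_sum[rownames(agg), ] <- prob_sum[rownames(agg), ] + agg
    cnt <- table(origin)
    patch_count[names(cnt)] <- patch_count[names(cnt)] + as.numeric(cnt)
  }
  if (short_slides > 0) {
    warn(sprintf(
      "%d slide draws held fewer than %d patches; sampled with replacement",
      short_slides, patches_per_slide))
  }
  V <- sweep(prob_sum, 1, patch_count, "/")
  out <- similarity_matrix(V, paste0("disc_", condition), cohorts)
  attr(out, "n_patches_used") <- sum(patch_count)
  out
}

#' Empirical H-divergence proxy from a discrimination error rate
#'
#' The standard finite-sample estimator `2 * (1 - 2 * error_rate)` mapping
#' the best achievable pairwise cohort-discrimination error (0.5 =
#' indistinguishable, 0 = perfectly separable) onto a divergence in
#' `[0, 2]`.
#'
#' @param binary_error_rate error rate in `[0, 0.5]`.
#' @return a real in `[0, 2]`.
#' @export
hdivergence_proxy <- function(binary_error_rate) {
  assert_that(all(binary_error_rate >= 0 & binary_error_rate <= 0.5),
              "error rate must lie in [0, 0.5]")
  2 * (1 - 2 * binary_error_rate)
}

#' Write a similarity matrix as CSV with a JSON sidecar
#'
#' @param x a `similarity_matrix`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(x, path) {
  write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  jsonlite::write_json(
    list(kind = attr(x, "kind"), row_semantics = attr(x, "row_semantics"),
         col_semantics = attr(x, "col_semantics"),
         n_patches_used = attr(x, "n_patches_used")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_csv()]
#'
#' @param path CSV path.
#' @return a `similarity_matrix`.
#' @export
read_similarity_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  similarity_matrix(as.matrix(df), meta$kind, rownames(df))
}
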