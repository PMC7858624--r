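#' Training configuration
#'
#' The training protocol: Adam, mini-batches of 32 patches, an epoch defined
#' as a fixed number of training iterations, validation on a fixed random
#' sample of patches at the end of every epoch, and early stopping once the
#' best validation accuracy has not improved for `patience_epochs` consecutive
#' epochs. Two profiles are provided: `"paper"` keeps the full-scale protocol
#' (1000 iterations per epoch = 32,000 patches, 6400 validation patches),
#' `"desk"` scales the same rules down for laptop-sized synthetic data.
#'
#' @param profile `"desk"` (default) or `"paper"`.
#' @param learning_rate Adam learning rate; the paper profile uses `1e-3`,
#'   the desk profile `1e-2` (the small network on summary features needs a
#'   larger step than a deep CNN to converge within desk-scale epochs).
#' @param batch_size patches per iteration.
#' @param iterations_per_epoch iterations in one epoch.
#' @param val_patches_per_epoch validation patches scored each epoch.
#' @param patience_epochs epochs without improvement before stopping.
#' @param max_epochs hard cap (a truncation flag is set when reached).
#' @param improvement_tol minimum accuracy gain counted as an improvement
#'   (paper profile 0; desk profile 0.002, one validation patch in 512).
#' @param hidden_units width of the hidden layer (the penultimate feature
#'   dimension).
#' @param augment logical; apply training-time augmentation.
#' @param seed integer seed governing init, batch order and augmentation.
#' @return a classed list.
#' @export
training_config <- function(profile = c("desk", "paper"),
                            learning_rate = NULL, batch_size = 32,
                            iterations_per_epoch = NULL,
                            val_patches_per_epoch = NULL,
                            patience_epochs = 5, max_epochs = NULL,
                            improvement_tol = NULL, hidden_units = 16,
                            augment = TRUE, seed = 1L) {
  profile <- match.arg(profile)
  learning_rate <- learning_rate %||%
    switch(profile, desk = 1e-2, paper = 1e-3)
  # desk validation samples are small (512 patches), so a strict zero
  # tolerance lets sampling noise reset the patience clock indefinitely
  improvement_tol <- improvement_tol %||%
    switch(profile, desk = 0.002, paper = 0)
  iterations_per_epoch <- iterations_per_epoch %||%
    switch(profile, desk = 50, paper = 1000)
  val_patches_per_epoch <- val_patches_per_epoch %||%
    switch(profile, desk = 512, paper = 6400)
  max_epochs <- max_epochs %||% switch(profile, desk = 30, paper = 200)
  assert_that(learning_rate > 0 && batch_size >= 1 &&
                iterations_per_epoch >= 1 && val_patches_per_epoch >= 1 &&
                patience_epochs >= 1 && max_epochs >= 1,
              "training settings must be positive")
  structure(as.list(environment()), class = "training_config")
}

#' Build a labeled patch stream for a task
#'
#' Labels come from slide-level metadata only: the detection task labels every
#' patch with its slide's label (noisy on positive slides, where some patches
#' are latently normal), and the discrimination task labels every patch with
#' its cohort of origin. The latent per-patch state is never consulted.
#'
#' @param dataset a `multicohort_dataset`.
#' @param manifest rows of a `subdataset_manifest` selecting slides (one
#'   sub-dataset and role); only `slide_id` is used.
#' @param task `"detection"` or `"discrimination"`.
#' @param class_levels for discrimination, the cohort label set (defaults to
#'   all cohorts in the dataset, so streams from subsets keep a consistent
#'   class order).
#' @return a `patch_stream`: list with `rows` (indices into
#'   `dataset$pixels`), `labels` (integer class indices, 1-based),
#'   `class_levels`, `slide_id`, and the originating `dataset` reference.
#' @export
assign_patch_labels <- function(dataset, manifest,
                                task = c("detection", "discrimination"),
                                class_levels = NULL) {
  task <- match.arg(task)
  ids <- sort(unique(manifest$slide_id))
  pt <- filter(dataset$patches, slide_id %in% ids)
  pt <- arrange(pt, slide_id, patch_index)
  if (task == "detection") {
    levels <- c("0", "1")
    labels <- pt$assigned_label + 1L
  } else {
    levels <- class_levels %||% sort(unique(dataset$slides$cohort))
    labels <- match(pt$cohort, levels)
    assert_that(!anyNA(labels), "cohort outside class_levels")
  }
  structure(list(rows = pt$row, labels = labels, class_levels = levels,
                 slide_id = pt$slide_id, dataset = dataset, task = task),
            class = "patch_stream")
}

#' Replay the early-stopping rule on an accuracy trace
#'
#' Returns the epoch at which training stops for a given per-epoch validation
#' accuracy trace: the first epoch `e` such that none of the `patience` most
#' recent epochs improved the best accuracy seen so far by more than `tol`.
#' If the trace ends before saturation, its length is returned with
#' `truncated = TRUE`.
#'
#' @param trace numeric vector of per-epoch validation accuracies.
#' @param patience patience in epochs.
#' @param tol minimum improvement.
#' @return a list: `epochs_trained`, `best`, `best_epoch`, `truncated`.
#' @export
epochs_from_trace <- function(trace, patience = 5, tol = 0) {
  assert_that(length(trace) >= 1 && patience >= 1, "need a nonempty trace")
  best <- -Inf; best_epoch <- 0L; last_improve <- 0L
  for (e in seq_along(trace)) {
    if (trace[e] > best + tol) {
      best <- trace[e]; best_epoch <- e; last_improve <- e
    }
    if (e - last_improve >= patience) {
      return(list(epochs_trained = e, best = best, best_epoch = best_epoch,
                  truncated = FALSE))
    }
  }
  list(epochs_trained = length(trace), best = best, best_epoch = best_epoch,
       truncated = TRUE)
}

stream_matrix <- function(stream, rows) stream$dataset$pixels[, rows, drop = FALSE]

#' Train a patch-level classifier
#'
#' A small feed-forward network on deterministic patch summary features (one
#' ReLU hidden layer, softmax output) trained with hand-rolled Adam under the
#' fixed-iteration epoch protocol: each iteration draws `batch_size` patches
#' with replacement from the training stream, augments them, and takes one
#' Adam step on the cross-entropy; at the end of every epoch accuracy is
#' measured on a fixed random validation sample and the patience rule of
#' [epochs_from_trace()] decides termination. Deterministic given the config
#' seed.
#'
#' @param train_stream,val_stream `patch_stream`s from
#'   [assign_patch_labels()]; must agree on `class_levels`.
#' @param cfg a [training_config()].
#' @param aug an [augmentation_config()]; used only when `cfg$augment`.
#' @return a list with `model` (a `trained_patch_model`) and `record` (a
#'   `training_record`: `epochs_trained`, `best_val_accuracy`, `trace`,
#'   `truncated`).
#' @export
train_patch_model <- function(train_stream, val_stream,
                              cfg = training_config(),
                              aug = augmentation_config()) {
  assert_that(inherits(train_stream, "patch_stream") &&
                inherits(val_stream, "patch_stream"), "need patch streams")
  assert_that(length(train_stream$rows) > 0 && length(val_stream$rows) > 0,
              "empty patch stream")
  assert_that(identical(train_stream$class_levels, val_stream$class_levels),
              "train/val class levels differ")
  K <- length(train_stream$class_levels)
  assert_that(K >= 2, "need at least two classes")
  size <- train_stream$dataset$config$patch_size
  withr::local_seed(substream_seed(cfg$seed, "train"))

  # feature standardization moments from (a sample of) the raw training patches
  idx0 <- train_stream$rows
  if (length(idx0) > 4000) idx0 <- sample(idx0, 4000)
  F0 <- patch_features(stream_matrix(train_stream, idx0), size)
  f_mu <- colMeans(F0)
  f_sd <- pmax(apply(F0, 2, sd), 1e-8)
  d_in <- ncol(F0)
  H <- cfg$hidden_units

  W1 <- matrix(rnorm(d_in * H, sd = sqrt(2 / d_in)), d_in, H)
  b1 <- numeric(H)
  W2 <- matrix(rnorm(H * K, sd = sqrt(2 / H)), H, K)
  b2 <- numeric(K)
  adam <- list(m = list(W1 * 0, b1 * 0, W2 * 0, b2 * 0),
               v = list(W1 * 0, b1 * 0, W2 * 0, b2 * 0), t = 0)

  # fixed validation sample for the whole run
  vidx <- sample(seq_along(val_stream$rows), cfg$val_patches_per_epoch,
                 replace = length(val_stream$rows) < cfg$val_patches_per_epoch)
  Vx <- standardize(patch_features(
    stream_matrix(val_stream, val_stream$rows[vidx]), size), f_mu, f_sd)
  vy <- val_stream$labels[vidx]

  forward <- function(Xs) {
    A1 <- relu(sweep(Xs %*% W1, 2, b1, "+"))
    Z2 <- sweep(A1 %*% W2, 2, b2, "+")
    Z2 <- Z2 - apply(Z2, 1, max)
    E <- exp(Z2)
    list(A1 = A1, P = E / rowSums(E))
  }

  trace <- numeric(0)
  best <- -Inf; best_epoch <- 0L; last_improve <- 0L
  truncated <- FALSE
  lr <- cfg$learning_rate; b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  for (epoch in seq_len(cfg$max_epochs)) {
    for (it in seq_len(cfg$iterations_per_epoch)) {
      bi <- sample.int(length(train_stream$rows), cfg$batch_size,
                       replace = TRUE)
      Xb <- stream_matrix(train_stream, train_stream$rows[bi])
      if (isTRUE(cfg$augment)) Xb <- augment_batch(Xb, aug, size)
      Xs <- standardize(patch_features(Xb, size), f_mu, f_sd)
      yb <- train_stream$labels[bi]
      fw <- forward(Xs)
      n <- nrow(Xs)
      dZ2 <- fw$P
      dZ2[cbind(seq_len(n), yb)] <- dZ2[cbind(seq_len(n), yb)] - 1
      dZ2 <- dZ2 / n
      gW2 <- crossprod(fw$A1, dZ2); gb2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(W2)
      dA1[fw$A1 <= 0] <- 0
      gW1 <- crossprod(Xs, dA1); gb1 <- colSums(dA1)
      adam$t <- adam$t + 1
      gs <- list(gW1, gb1, gW2, gb2)
      ps <- list(W1, b1, W2, b2)
      for (k in 1:4) {
        adam$m[[k]] <- b1m * adam$m[[k]] + (1 - b1m) * gs[[k]]
        adam$v[[k]] <- b2m * adam$v[[k]] + (1 - b2m) * gs[[k]]^2
        mh <- adam$m[[k]] / (1 - b1m^adam$t)
        vh <- adam$v[[k]] / (1 - b2m^adam$t)
        ps[[k]] <- ps[[k]] - lr * mh / (sqrt(vh) + eps)
      }
      W1 <- ps[[1]]; b1 <- ps[[2]]; W2 <- ps[[3]]; b2 <- ps[[4]]
    }
    acc <- mean(max.col(forward(Vx)$P, ties.method = "first") == vy)
    trace <- c(trace, acc)
    if (acc > best + cfg$improvement_tol) {
      best <- acc; best_epoch <- epoch; last_improve <- epoch
      best_params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    }
    if (epoch - last_improve >= cfg$patience_epochs) break
    if (epoch == cfg$max_epochs) truncated <- TRUE
  }
  if (!exists("best_params", inherits = FALSE)) {
    best_params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  model <- structure(list(
    task = train_stream$task, n_classes = K,
    class_levels = train_stream$class_levels,
    feature_dim = H, patch_size = size,
    params = best_params, f_mu = f_mu, f_sd = f_sd,
    config = cfg), class = "trained_patch_model")
  record <- structure(list(
    epochs_trained = length(trace), best_val_accuracy = best,
    best_epoch = best_epoch, trace = trace, truncated = truncated),
    class = "training_record")
  list(model = model, record = record)
}

standardize <- function(F, mu, sdv) sweep(sweep(F, 2, mu, "-"), 2, sdv, "/")

model_forward <- function(model, pixels) {
  F <- standardize(patch_features(pixels, model$patch_size),
                   model$f_mu, model$f_sd)
  A1 <- relu(sweep(F %*% model$params$W1, 2, model$params$b1, "+"))
  Z2 <- sweep(A1 %*% model$params$W2, 2, model$params$b2, "+")
  Z2 <- Z2 - apply(Z2, 1, max)
  E <- exp(Z2)
  list(A1 = A1, P = E / rowSums(E))
}

#' Patch-level class probabilities
#'
#' @param model a `trained_patch_model`.
#' @param patches a pixel matrix (one flat patch per column), a single flat
#'   patch, or a `patch_stream`.
#' @return a probability matrix, one row per patch, columns named by class;
#'   rows sum to 1. Deterministic (no test-time augmentation).
#' @export
predict_patch <- function(model, patches) {
  pixels <- resolve_pixels(model, patches)
  P <- model_forward(model, pixels)$P
  colnames(P) <- model$class_levels
  P
}

#' Penultimate-layer features of patches
#'
#' The hidden-layer activations of the classifier, used for qualitative
#' embedding of cohort morphology.
#'
#' @inheritParams predict_patch
#' @return a matrix, one row per patch, `model$feature_dim` columns.
#' @export
extract_features <- function(model, patches) {
  pixels <- resolve_pixels(model, patches)
  model_forward(model, pixels)$A1
}

resolve_pixels <- function(model, patches) {
  if (inherits(patches, "patch_stream")) {
    return(stream_matrix(patches, patches$rows))
  }
  if (is.null(dim(patches))) patches <- matrix(patches, ncol = 1)
  assert_that(nrow(patches) == 3 * model$patch_size^2,
              "patch length does not match the model's patch size")
  patches
}

#' @export
print.trained_patch_model <- function(x, ...) {
  cat("Patch model:", x$task, "task,", x$n_classes, "classes, hidden dim",
      x$feature_dim, "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.trained_patch_model <- function(x, ...) {
  tibble(task = x$task, n_classes = x$n_classes, feature_dim = x$feature_dim,
         patch_size = x$patch_size)
}

#' @export
glance.training_record <- function(x, ...) {
  tibble(epochs_trained = x$epochs_trained,
         best_val_accuracy = x$best_val_accuracy,
         best_epoch = x$best_epoch, truncated = x$truncated)
}

#' @export
tidy.training_record <- function(x, ...) {
  tibble(epoch = seq_along(x$trace), val_accuracy = x$trace)
}
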