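#' Ward dendrogram over similarity-matrix columns
#'
#' Agglomerative clustering of the cohorts using Ward's minimum-variance
#' method on the Euclidean distances between the matrix's column vectors:
#' two cohorts whose columns look alike (models trained on them behave alike,
#' or they are confused alike) merge low.
#'
#' @param matrix a `similarity_matrix`.
#' @return a `cohort_dendrogram`: list with `hc` (an [stats::hclust] tree,
#'   `ward.D2` linkage) and the source `kind`.
#' @export
build_dendrogram <- function(matrix) {
  assert_that(inherits(matrix, "similarity_matrix") ||
                (is.matrix(matrix) && nrow(matrix) == ncol(matrix)),
              "need a square similarity matrix")
  assert_that(all(is.finite(matrix)), "matrix entries must be finite")
  m <- unclass(matrix)
  hc <- hclust(dist(t(m)), method = "ward.D2")
  structure(list(hc = hc, kind = attr(matrix, "kind") %||% "unknown"),
            class = "cohort_dendrogram")
}

#' @export
print.cohort_dendrogram <- function(x, ...) {
  cat("Cohort dendrogram (Ward/Euclidean on columns of", x$kind, ")\n")
  cat("  merge heights:", paste(signif(x$hc$height, 3), collapse = " "), "\n")
  invisible(x)
}

#' Cut a dendrogram into S super-cohorts
#'
#' Removes the `S - 1` highest merges, leaving `S` disjoint groups covering
#' all cohorts. `S = 1` is the universal configuration, `S = N` the fully
#' specialized (cohort-specific) one.
#'
#' @param dendrogram a `cohort_dendrogram` (or `planted_hierarchy`).
#' @param S number of super-cohorts, `1 <= S <= N`.
#' @return a `supercohort_partition` tibble: `cohort`, `group`, with
#'   attributes `S` and `kind`.
#' @export
cut_to_supercohorts <- function(dendrogram, S) {
  hc <- if (inherits(dendrogram, "cohort_dendrogram")) dendrogram$hc
        else if (inherits(dendrogram, "planted_hierarchy")) dendrogram$hc
        else abort("need a dendrogram", class = "invalid_argument")
  n <- length(hc$labels)
  assert_that(S >= 1 && S <= n, "S out of range")
  g <- cutree(hc, k = as.integer(S))
  structure(tibble(cohort = names(g), group = as.integer(g)),
            class = c("supercohort_partition", class(tibble())),
            S = as.integer(S),
            kind = if (inherits(dendrogram, "cohort_dendrogram"))
              dendrogram$kind else "planted")
}

partition_groups <- function(partition) {
  split(partition$cohort, partition$group)
}

#' Train one detection model per super-cohort
#'
#' For every group of the partition and every sub-dataset, trains a detection
#' model on the pooled training slides of the group's member cohorts, via the
#' same engine as the cohort-specific and universal models — so `S = N`
#' reproduces the cohort-specific fits bit for bit and `S = 1` the universal
#' fit, at shared seeds.
#'
#' @param partition a `supercohort_partition`.
#' @param dataset a `multicohort_dataset`.
#' @param subs a `subdataset_manifest`.
#' @param cfg a [training_config()].
#' @param aug an [augmentation_config()].
#' @param cache optional environment shared across partitions to reuse fits
#'   of identical groups.
#' @return a tibble: `group`, `sub_index`, `members` (list), `fit` (list).
#' @export
train_supercohort_models <- function(partition, dataset, subs,
                                     cfg = training_config(),
                                     aug = augmentation_config(),
                                     cache = NULL) {
  groups <- partition_groups(partition)
  n_subs <- attr(subs, "n_subdatasets") %||% max(subs$sub_index)
  grid <- expand.grid(group = seq_along(groups), sub_index = seq_len(n_subs))
  out <- pmap(grid, function(group, sub_index) {
    members <- groups[[group]]
    fit <- train_group_detection_model(dataset, subs, members, sub_index,
                                       cfg, aug, cache)
    tibble(group = group, sub_index = sub_index, members = list(members),
           fit = list(fit))
  })
  bind_rows(out)
}

#' Mean and t-based confidence-interval halfwidth
#'
#' @param values numeric vector, length at least 2.
#' @param level confidence level (default 0.95).
#' @return a list with `mean` and `halfwidth`
#'   (`t_{(1+level)/2, n-1} * sd / sqrt(n)`).
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  assert_that(n >= 2, "need at least two values for a confidence interval")
  hw <- qt((1 + level) / 2, df = n - 1) * sd(values) / sqrt(n)
  list(mean = mean(values), halfwidth = hw)
}

#' Evaluate a super-cohort partition
#'
#' Scores every cohort's test slides with its group's model, per sub-dataset;
#' reports per-cohort AUROC means over sub-datasets, the grand mean with its
#' 95% t-interval halfwidth over per-cohort means, and the total training
#' time: the sum over groups of the group's mean trained epochs across
#' sub-datasets.
#'
#' @param models output of [train_supercohort_models()].
#' @param partition the `supercohort_partition` the models were trained for.
#' @param dataset a `multicohort_dataset`.
#' @param subs the `subdataset_manifest`.
#' @param split evaluation split (default `"test"`).
#' @return a `partition_evaluation`: list with `per_cohort` (tibble),
#'   `per_sub` (tibble of cohort x sub AUROCs), `mean_auroc`,
#'   `ci_halfwidth`, `per_group_epochs` (tibble), `total_epochs`, `S`,
#'   `kind`.
#' @export
evaluate_partition <- function(models, partition, dataset, subs,
                               split = "test") {
  groups <- partition_groups(partition)
  covered <- sort(unname(unlist(groups)))
  assert_that(identical(covered, sort(unique(partition$cohort))) &&
                anyDuplicated(covered) == 0,
              "groups must disjointly cover the cohorts")
  rows <- list()
  for (r in seq_len(nrow(models))) {
    mrow <- models[r, ]
    model <- mrow$fit[[1]]$model
    eval_man <- filter(as_tibble(subs), sub_index == mrow$sub_index,
                       role == split)
    for (co in mrow$members[[1]]) {
      man_c <- filter(eval_man, cohort == co)
      rows[[length(rows) + 1L]] <- tibble(
        cohort = co, sub_index = mrow$sub_index, group = mrow$group,
        auroc = detection_auroc(model, dataset, man_c))
    }
  }
  per_sub <- bind_rows(rows)
  per_cohort <- summarise(group_by(per_sub, cohort),
                          mean_auroc = mean(auroc), .groups = "drop")
  ci <- mean_ci(per_cohort$mean_auroc)
  epochs <- summarise(
    group_by(mutate(models,
                    epochs = map_dbl(fit, ~ .x$record$epochs_trained)),
             group),
    mean_epochs = mean(epochs), .groups = "drop")
  structure(list(
    per_cohort = per_cohort, per_sub = per_sub,
    mean_auroc = ci$mean, ci_halfwidth = ci$halfwidth,
    per_group_epochs = epochs, total_epochs = sum(epochs$mean_epochs),
    S = attr(partition, "S") %||% length(groups),
    kind = attr(partition, "kind") %||% "unknown"),
    class = "partition_evaluation")
}

#' @export
print.partition_evaluation <- function(x, ...) {
  cat(sprintf("Partition evaluation [%s, S=%d]: mean AUROC %.4f +/- %.4f, total %.1f epochs\n",
              x$kind, x$S, x$mean_auroc, x$ci_halfwidth, x$total_epochs))
  invisible(x)
}

#' @export
tidy.partition_evaluation <- function(x, ...) {
  mutate(x$per_cohort, kind = x$kind, S = x$S)
}

#' @export
glance.partition_evaluation <- function(x, ...) {
  tibble(kind = x$kind, S = x$S, mean_auroc = x$mean_auroc,
         ci_halfwidth = x$ci_halfwidth, total_epochs = x$total_epochs)
}

#' Select super-cohort partitions under the CI gate
#'
#' Qualifying partitions have mean AUROC at least the reference's lower 95%
#' confidence bound (one-sided gate by default; set `two_sided = TRUE` to
#' require the looser within-interval reading). Among qualifiers, the minimum
#' training-time choice and the best-performance choice are reported; ties
#' break toward smaller `S`, then lexicographic kind.
#'
#' @param evaluations a list of `partition_evaluation`s (the sweep).
#' @param reference the `partition_evaluation` of the cohort-specific
#'   (`S = N`) configuration.
#' @param two_sided gate on both CI bounds instead of the lower bound only.
#' @return a list: `table` (tibble with `qualifies`), `qualifying`,
#'   `min_time_choice`, `best_performance_choice` (rows or `NULL` when no
#'   partition qualifies, with `empty = TRUE` flagged).
#' @export
select_partitions <- function(evaluations, reference, two_sided = FALSE) {
  tab <- bind_rows(lapply(evaluations, glance))
  lower <- reference$mean_auroc - reference$ci_halfwidth
  upper <- reference$mean_auroc + reference$ci_halfwidth
  tab$qualifies <- tab$mean_auroc >= lower
  if (two_sided) tab$qualifies <- tab$qualifies & tab$mean_auroc <= upper
  qual <- arrange(filter(tab, qualifies), S, kind)
  if (nrow(qual) == 0) {
    return(list(table = tab, qualifying = qual, min_time_choice = NULL,
                best_performance_choice = NULL, empty = TRUE,
                reference_lower = lower))
  }
  min_time <- slice(arrange(qual, total_epochs, S, kind), 1)
  best_perf <- slice(arrange(qual, dplyr::desc(mean_auroc), S, kind), 1)
  list(table = tab, qualifying = qual, min_time_choice = min_time,
       best_performance_choice = best_perf, empty = FALSE,
       reference_lower = lower)
}

#' Sweep super-cohort counts over one or more dendrograms
#'
#' Cuts each dendrogram at every requested `S`, trains the super-cohort
#' models (sharing a fit cache across cuts, so repeated groups — e.g. the
#' singletons of `S = N` — are trained once) and evaluates each partition.
#'
#' @param dendrograms named list of `cohort_dendrogram`s.
#' @param S_values integer vector of super-cohort counts.
#' @param dataset,subs,cfg,aug as in [train_supercohort_models()].
#' @param cache optional shared fit cache environment.
#' @return a list: `evaluations` (list of `partition_evaluation`),
#'   `partitions` (list), `table` (glance tibble).
#' @export
sweep_supercohorts <- function(dendrograms, S_values, dataset, subs,
                               cfg = training_config(),
                               aug = augmentation_config(),
                               cache = new.env(parent = emptyenv())) {
  evaluations <- list(); partitions <- list()
  for (kind in names(dendrograms)) {
    for (S in S_values) {
      part <- cut_to_supercohorts(dendrograms[[kind]], S)
      models <- train_supercohort_models(part, dataset, subs, cfg, aug, cache)
      ev <- evaluate_partition(models, part, dataset, subs)
      ev$kind <- kind
      key <- sprintf("%s_S%d", kind, S)
      evaluations[[key]] <- ev
      partitions[[key]] <- part
    }
  }
  list(evaluations = evaluations, partitions = partitions,
       table = bind_rows(lapply(evaluations, glance)))
}
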