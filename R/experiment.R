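#' Experiment configuration
#'
#' One validated object driving the end-to-end analysis: dataset generation,
#' sub-dataset preparation, model training, similarity matrices, dendrograms,
#' the super-cohort sweep and partition selection.
#'
#' @param n_cohorts number of synthetic cohorts.
#' @param layout hierarchy layout passed to [generate_planted_hierarchy()];
#'   default plants `n_cohorts / 2` tight pairs (requires even `n_cohorts`).
#' @param generation a [generation_config()].
#' @param training a [training_config()].
#' @param augmentation an [augmentation_config()].
#' @param matrix_kinds which similarity matrices to compute, a subset of
#'   `c("detection_C", "disc_negative", "disc_positive", "disc_general")`.
#' @param S_values super-cohort counts to sweep (default `1:n_cohorts`).
#' @param eval_patches_per_slide patch budget per slide for discrimination
#'   matrices; defaults to the generated patches per slide.
#' @param n_subdatasets,n_train,n_heldout sub-dataset demand per class.
#' @param two_sided_gate use the two-sided CI gate in selection.
#' @param seed master seed.
#' @param outdir output directory (`NULL` for no artifacts).
#' @return a classed list.
#' @export
experiment_config <- function(n_cohorts = 6, layout = NULL,
                              generation = generation_config(),
                              training = training_config(),
                              augmentation = augmentation_config(),
                              matrix_kinds = c("detection_C", "disc_negative",
                                               "disc_positive", "disc_general"),
                              S_values = NULL,
                              eval_patches_per_slide = NULL,
                              n_subdatasets = 5, n_train = 18, n_heldout = 18,
                              two_sided_gate = FALSE,
                              seed = 1L, outdir = NULL) {
  assert_that(n_cohorts >= 2, "n_cohorts must be >= 2")
  layout <- layout %||% planted_pairs_layout(n_cohorts)
  S_values <- S_values %||% seq_len(n_cohorts)
  eval_patches_per_slide <- eval_patches_per_slide %||%
    generation$patches_per_slide
  bad <- setdiff(matrix_kinds,
                 c("detection_C", "disc_negative", "disc_positive",
                   "disc_general"))
  assert_that(length(bad) == 0,
              paste("unknown matrix kinds:", paste(bad, collapse = ", ")))
  assert_that(all(S_values >= 1 & S_values <= n_cohorts), "S out of range")
  assert_that(generation$n_pos >= n_train + n_heldout &&
                generation$n_neg >= n_train + n_heldout,
              "generated slides per cohort cannot meet sub-dataset demand")
  structure(as.list(environment()), class = "experiment_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [experiment_config()]; nested
#' `generation` and `training` blocks override those constructors' defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen <- do.call(generation_config, raw$generation %||% list())
  trn <- do.call(training_config, raw$training %||% list())
  raw$generation <- NULL; raw$training <- NULL
  do.call(experiment_config, c(raw, list(generation = gen, training = trn)))
}

stage_path <- function(outdir, name) file.path(outdir, name)

run_stage <- function(name, outdir, resume, compute) {
  # stage checkpointing: a completed stage is re-loaded, not recomputed
  if (!is.null(outdir)) {
    cp <- stage_path(outdir, paste0(name, ".rds"))
    if (resume && file.exists(cp)) {
      inform(sprintf("[%s] resumed from checkpoint", name))
      return(readRDS(cp))
    }
    t0 <- Sys.time()
    value <- compute()
    saveRDS(value, cp)
    inform(sprintf("[%s] done in %.1fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    value
  } else {
    compute()
  }
}

#' Run the end-to-end cohort-aggregation experiment
#'
#' Generates the synthetic corpus, samples the sub-datasets, trains
#' cohort-specific and discrimination models, builds the requested similarity
#' matrices and their Ward dendrograms, sweeps super-cohort counts, and
#' applies the CI-gated selection against the cohort-specific reference.
#' With an `outdir`, writes the slide manifest, sub-dataset CSV, matrix CSVs,
#' Newick trees, the trade-off table and a selection JSON, and checkpoints
#' stages so a rerun with `resume = TRUE` is a no-op for completed stages.
#'
#' @param config an [experiment_config()].
#' @param resume reuse stage checkpoints found in `config$outdir`.
#' @return a report bundle: list with `dataset` summary, `subdatasets`,
#'   `matrices`, `dendrograms`, `sweep`, `reference`, `selection`.
#' @export
run_experiment <- function(config = experiment_config(), resume = FALSE) {
  assert_that(inherits(config, "experiment_config"), "not an experiment_config")
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  hierarchy <- generate_planted_hierarchy(config$n_cohorts, config$layout,
                                          seed = seed)
  dataset <- run_stage("dataset", outdir, resume, function() {
    generate_dataset(hierarchy, config$generation, seed = seed)
  })
  if (!is.null(outdir)) {
    write_manifest(dataset, stage_path(outdir, "slides.csv"))
    write_newick(hierarchy, stage_path(outdir, "planted_hierarchy.nwk"))
  }

  subs <- run_stage("subdatasets", outdir, resume, function() {
    sample_subdatasets(dataset, n_subdatasets = config$n_subdatasets,
                       n_train_pos = config$n_train,
                       n_train_neg = config$n_train,
                       n_heldout_pos = config$n_heldout,
                       n_heldout_neg = config$n_heldout,
                       seed = substream_seed(seed, "prepare"))
  })
  if (!is.null(outdir)) {
    write.csv(as_tibble(subs), stage_path(outdir, "subdatasets.csv"),
              row.names = FALSE)
  }

  cfg <- config$training
  cfg$seed <- seed
  aug <- config$augmentation
  cache <- new.env(parent = emptyenv())

  singles <- run_stage("single_models", outdir, resume, function() {
    train_single_models(dataset, subs, cfg, aug, cache)
  })
  if (resume && !is.null(outdir)) refill_cache(cache, singles)

  matrices <- run_stage("matrices", outdir, resume, function() {
    out <- list()
    if ("detection_C" %in% config$matrix_kinds) {
      out$detection_C <- cross_cohort_detection_matrix(singles, dataset, subs)
    }
    for (cond in c("negative", "positive", "general")) {
      kind <- paste0("disc_", cond)
      if (!kind %in% config$matrix_kinds) next
      disc <- train_cohort_discriminators(dataset, subs, cond, cfg, aug)
      out[[kind]] <- discrimination_confidence_matrix(
        disc, dataset, subs, cond,
        patches_per_slide = config$eval_patches_per_slide,
        seed = substream_seed(seed, "matrix", cond))
    }
    out
  })
  dendrograms <- lapply(matrices, build_dendrogram)
  if (!is.null(outdir)) {
    for (kind in names(matrices)) {
      write_similarity_csv(matrices[[kind]],
                           stage_path(outdir, paste0(kind, ".csv")))
      write_newick(dendrograms[[kind]],
                   stage_path(outdir, paste0(kind, ".nwk")))
    }
  }

  sweep <- run_stage("sweep", outdir, resume, function() {
    sweep_supercohorts(dendrograms, config$S_values, dataset, subs, cfg, aug,
                       cache)
  })

  reference <- run_stage("reference", outdir, resume, function() {
    part <- structure(
      tibble(cohort = sort(unique(subs$cohort)),
             group = seq_along(sort(unique(subs$cohort)))),
      class = c("supercohort_partition", class(tibble())),
      S = config$n_cohorts, kind = "single")
    models <- train_supercohort_models(part, dataset, subs, cfg, aug, cache)
    evaluate_partition(models, part, dataset, subs)
  })

  selection <- select_partitions(sweep$evaluations, reference,
                                 two_sided = config$two_sided_gate)
  if (!is.null(outdir)) {
    write.csv(selection$table, stage_path(outdir, "tradeoff.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(reference = glance(reference),
           reference_lower = selection$reference_lower,
           qualifying = selection$qualifying,
           min_time_choice = selection$min_time_choice,
           best_performance_choice = selection$best_performance_choice),
      stage_path(outdir, "selection.json"),
      dataFrame = "rows", auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(report_summary(dataset, subs, selection, reference),
               stage_path(outdir, "summary.txt"))
  }
  list(hierarchy = hierarchy, dataset = dataset, subdatasets = subs,
       singles = singles, matrices = matrices, dendrograms = dendrograms,
       sweep = sweep, reference = reference, selection = selection,
       cache = cache)
}

# repopulate the fit cache from a resumed single-model stage so later stages
# reuse the checkpointed fits
refill_cache <- function(cache, singles) {
  for (r in seq_len(nrow(singles))) {
    key <- paste(group_signature(singles$cohort[r]), singles$sub_index[r],
                 sep = "@")
    cache[[key]] <- singles$fit[[r]]
  }
}

report_summary <- function(dataset, subs, selection, reference) {
  c(sprintf("Cohorts: %d; slides: %d; patches: %d",
            dataset$hierarchy$n_cohorts, nrow(dataset$slides),
            nrow(dataset$patches)),
    sprintf("Cohort-specific reference: mean AUROC %.4f +/- %.4f, %.1f epochs",
            reference$mean_auroc, reference$ci_halfwidth,
            reference$total_epochs),
    sprintf("Qualifying partitions (mean AUROC >= %.4f): %d",
            selection$reference_lower, nrow(selection$qualifying)),
    if (!selection$empty) {
      c(sprintf("Min-time choice: %s S=%d (%.4f AUROC, %.1f epochs)",
                selection$min_time_choice$kind, selection$min_time_choice$S,
                selection$min_time_choice$mean_auroc,
                selection$min_time_choice$total_epochs),
        sprintf("Best-performance choice: %s S=%d (%.4f AUROC, %.1f epochs)",
                selection$best_performance_choice$kind,
                selection$best_performance_choice$S,
                selection$best_performance_choice$mean_auroc,
                selection$best_performance_choice$total_epochs))
    } else "No partition qualified under the CI gate.")
}

#' 2-D embedding of patch features
#'
#' Decorative qualitative embedding of penultimate-layer features (UMAP when
#' the optional uwot package is installed, otherwise the call is skipped with
#' a message; a deterministic PCA method is always available). No downstream
#' computation depends on it.
#'
#' @param features numeric matrix, one row per patch.
#' @param n_neighbors UMAP neighborhood size (default 20).
#' @param min_dist UMAP minimum distance (default 0.5).
#' @param method `"umap"` or `"pca"`.
#' @param seed seed for the stochastic embedding.
#' @return an `n x 2` coordinate matrix, or `NULL` when UMAP is requested but
#'   uwot is unavailable.
#' @export
embed_features <- function(features, n_neighbors = 20, min_dist = 0.5,
                           method = c("umap", "pca"), seed = 1L) {
  method <- match.arg(method)
  assert_that(is.matrix(features) && nrow(features) >= 3,
              "need a feature matrix with at least 3 rows")
  if (method == "umap") {
    assert_that(nrow(features) >= n_neighbors + 1,
                "need at least n_neighbors + 1 rows")
    if (!requireNamespace("uwot", quietly = TRUE)) {
      inform("uwot not installed; skipping UMAP embedding")
      return(NULL)
    }
    withr::local_seed(substream_seed(seed, "umap"))
    co <- uwot::umap(features, n_neighbors = n_neighbors, min_dist = min_dist)
  } else {
    co <- prcomp(features, rank. = 2)$x[, 1:2, drop = FALSE]
  }
  colnames(co) <- c("dim1", "dim2")
  co
}
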