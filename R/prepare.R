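#' Sample balanced, patient-exclusive sub-datasets
#'
#' For every cohort, draws `n_subdatasets` resampled splits, each holding
#' `n_train_pos + n_train_neg` training slides and the same held-out demand,
#' under three criteria: (1) train and held-out sets share no patient,
#' (2) per patient at most one positive and one negative slide appear in a
#' sub-dataset, (3) the held-out set is halved into validation and test with
#' equal class counts (stratified within cohort). Sampling is independent
#' between sub-datasets — a slide may recur across sub-datasets but never
#' within one.
#'
#' @param dataset a `multicohort_dataset` (or any list with a `slides` tibble
#'   holding `slide_id`, `patient_id`, `cohort`, `label`).
#' @param n_subdatasets number of resampled splits (default 5).
#' @param n_train_pos,n_train_neg training slides per class per cohort.
#' @param n_heldout_pos,n_heldout_neg held-out slides per class per cohort;
#'   must be even so validation and test halves balance.
#' @param seed integer seed; splits are deterministic given it.
#' @return a `subdataset_manifest` tibble: `sub_index`, `cohort`, `slide_id`,
#'   `patient_id`, `label`, `role` in `{"train", "val", "test"}`, with the
#'   demand recorded in attributes.
#' @export
sample_subdatasets <- function(dataset, n_subdatasets = 5,
                               n_train_pos = 18, n_train_neg = 18,
                               n_heldout_pos = 18, n_heldout_neg = 18,
                               seed = 1L) {
  slides <- if (is.data.frame(dataset)) dataset else dataset$slides
  assert_that(n_heldout_pos %% 2 == 0 && n_heldout_neg %% 2 == 0,
              "held-out demands must be even to halve into val/test")
  cohorts <- unique(slides$cohort)
  out <- list()
  for (sub in seq_len(n_subdatasets)) {
    for (co in cohorts) {
      cs <- filter(slides, cohort == co)
      pick <- sample_one_cohort_split(
        cs, n_train_pos, n_train_neg, n_heldout_pos, n_heldout_neg,
        seed = substream_seed(seed, "subdataset", sub, co), cohort_name = co)
      out[[length(out) + 1L]] <- mutate(pick, sub_index = sub, .before = 1)
    }
  }
  man <- bind_rows(out)
  structure(man,
            class = c("subdataset_manifest", class(man)),
            task = "cancer_detection",
            demand = c(n_train_pos = n_train_pos, n_train_neg = n_train_neg,
                       n_heldout_pos = n_heldout_pos, n_heldout_neg = n_heldout_neg),
            n_subdatasets = n_subdatasets)
}

# one cohort, one sub-dataset: walk a shuffled patient order, each patient
# contributing at most one slide per class, filling train first then held-out
sample_one_cohort_split <- function(cs, n_train_pos, n_train_neg,
                                    n_heldout_pos, n_heldout_neg,
                                    seed, cohort_name) {
  withr::local_seed(seed)
  patients <- sample(unique(cs$patient_id))
  need <- list(train = c(pos = n_train_pos, neg = n_train_neg),
               held = c(pos = n_heldout_pos, neg = n_heldout_neg))
  taken <- list(train = character(0), held = character(0))
  for (pt in patients) {
    mine <- filter(cs, patient_id == pt)
    has <- c(pos = any(mine$label == 1L), neg = any(mine$label == 0L))
    # commit the whole patient to one side so train/held-out never share one
    side <- if (any(need$train > 0 & has)) "train"
            else if (any(need$held > 0 & has)) "held"
            else next
    for (cls in c("pos", "neg")) {
      if (!has[cls] || need[[side]][cls] == 0) next
      lab <- if (cls == "pos") 1L else 0L
      cand <- mine$slide_id[mine$label == lab]
      sl <- if (length(cand) == 1) cand else sample(cand, 1)
      taken[[side]] <- c(taken[[side]], sl)
      need[[side]][cls] <- need[[side]][cls] - 1
    }
    if (all(need$train == 0) && all(need$held == 0)) break
  }
  if (!all(need$train == 0) || !all(need$held == 0)) {
    abort(sprintf("cohort %s has too few eligible slides for one sub-dataset",
                  cohort_name),
          class = "cohort_too_small")
  }
  held <- filter(cs, slide_id %in% taken$held)
  val_ids <- unlist(lapply(c(1L, 0L), function(lab) {
    ids <- sample(held$slide_id[held$label == lab])
    ids[seq_len(length(ids) %/% 2)]
  }))
  res <- filter(cs, slide_id %in% c(taken$train, taken$held))
  res$role <- ifelse(res$slide_id %in% taken$train, "train",
                     ifelse(res$slide_id %in% val_ids, "val", "test"))
  select(res, cohort, slide_id, patient_id, label, role)
}

#' Restrict sub-datasets to a cohort-discrimination condition
#'
#' The negative and positive conditions keep only slides of that class (18
#' train slides per cohort under the default demand); the general condition
#' keeps both classes (36). Held-out slides remain halved into validation and
#' test.
#'
#' @param subdatasets a `subdataset_manifest` from [sample_subdatasets()].
#' @param condition `"negative"`, `"positive"`, or `"general"`.
#' @return a filtered `subdataset_manifest` with attribute `condition`.
#' @export
build_discrimination_splits <- function(subdatasets,
                                        condition = c("negative", "positive",
                                                      "general")) {
  condition <- match.arg(condition)
  keep <- switch(condition,
                 negative = subdatasets$label == 0L,
                 positive = subdatasets$label == 1L,
                 general = rep(TRUE, nrow(subdatasets)))
  out <- subdatasets[keep, ]
  attr(out, "task") <- paste0("discrimination_", condition)
  attr(out, "condition") <- condition
  out
}

#' Check a sub-dataset against the three sampling criteria
#'
#' Report-only: never throws. Criterion 1 is patient-level train/held-out
#' disjointness, criterion 2 the at-most-one-slide-per-class-per-patient rule,
#' criterion 3 equal class counts in validation and test.
#'
#' @param sub rows of a `subdataset_manifest` for a single `sub_index`.
#' @return a tibble: `criterion`, `pass`, `offenders` (list-column of ids).
#' @export
validate_subdataset <- function(sub) {
  train_pt <- unique(sub$patient_id[sub$role == "train"])
  held_pt <- unique(sub$patient_id[sub$role != "train"])
  c1_off <- intersect(train_pt, held_pt)
  dup <- count(sub, patient_id, label)
  c2_off <- dup$patient_id[dup$n > 1]
  bal <- summarise(group_by(filter(sub, role != "train"), role),
                   n_pos = sum(label == 1L), n_neg = sum(label == 0L))
  c3_off <- bal$role[bal$n_pos != bal$n_neg]
  if (!setequal(unique(sub$role), c("train", "val", "test")) ||
      sum(sub$role == "val") != sum(sub$role == "test")) {
    c3_off <- union(c3_off, "val/test size mismatch")
  }
  tibble(
    criterion = c("patient_disjoint_train_heldout",
                  "one_slide_per_patient_per_class",
                  "equal_classes_val_test"),
    pass = c(length(c1_off) == 0, length(c2_off) == 0, length(c3_off) == 0),
    offenders = list(c1_off, unique(c2_off), c3_off)
  )
}

#' Split a manifest into one tibble per sub-dataset
#' @param subdatasets a `subdataset_manifest`.
#' @return a named list of tibbles, one per `sub_index`.
#' @export
split_subdatasets <- function(subdatasets) {
  split(as_tibble(subdatasets), subdatasets$sub_index)
}

#' Counting helper: evaluation patch budget of a discrimination matrix
#'
#' The number of patches a discrimination confidence matrix consumes:
#' `patches_per_slide * slides_per_cohort * n_cohorts * n_subdatasets`.
#'
#' @param n_cohorts,slides_per_cohort,n_subdatasets,patches_per_slide integers.
#' @return an integer patch count.
#' @export
discrimination_patch_budget <- function(n_cohorts, slides_per_cohort,
                                        n_subdatasets = 5,
                                        patches_per_slide = 100) {
  as.integer(n_cohorts) * as.integer(slides_per_cohort) *
    as.integer(n_subdatasets) * as.integer(patches_per_slide)
}
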