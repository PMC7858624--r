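#' Generate a planted cohort similarity hierarchy
#'
#' Builds the rooted binary merge tree that plays the role of the unknown true
#' relatedness between cancer cohorts. Cohort parameters are later diffused
#' along this tree so that cohorts merging low share morphology, and the
#' clustering stages of the pipeline can be scored against the planted truth.
#'
#' @param n_cohorts number of cohorts (leaves), at least 2.
#' @param layout `"balanced"` (complete binary agglomeration with unit height
#'   steps, leaf order shuffled by `seed`), `"random"` (uniformly random
#'   agglomeration order with increasing heights), or an explicit list with
#'   components `merge` (an [stats::hclust()]-style merge matrix) and `height`
#'   (nondecreasing merge heights).
#' @param seed integer seed; the tree is deterministic given `(layout, seed)`.
#'
#' @return A `planted_hierarchy`: a classed [stats::hclust()] tree whose leaves
#'   are cohorts `C01..Cnn`, with [partition_at()] and [ape::as.phylo()]
#'   support.
#' @examples
#' h <- generate_planted_hierarchy(4, layout = planted_pairs_layout(4), seed = 1)
#' partition_at(h, 2)
#' @export
generate_planted_hierarchy <- function(n_cohorts, layout = "balanced", seed = 1L) {
  assert_that(is.numeric(n_cohorts) && n_cohorts >= 2, "n_cohorts must be >= 2")
  n_cohorts <- as.integer(n_cohorts)
  if (is.list(layout)) {
    merge <- layout$merge
    height <- as.numeric(layout$height)
    assert_that(is.matrix(merge) && nrow(merge) == n_cohorts - 1L,
                "explicit layout needs an (n-1) x 2 merge matrix")
    assert_that(length(height) == n_cohorts - 1L && !is.unsorted(height),
                "explicit heights must be nondecreasing, one per merge")
  } else if (identical(layout, "balanced")) {
    withr::local_seed(substream_seed(seed, "hierarchy", "balanced"))
    perm <- sample.int(n_cohorts)
    groups <- as.list(-perm)          # hclust convention: negatives are leaves
    heights <- numeric(0)
    merge <- matrix(0L, 0, 2)
    level <- 1
    next_id <- 1L
    while (length(groups) > 1) {
      nxt <- list()
      i <- 1
      while (i <= length(groups)) {
        if (i == length(groups)) { nxt[[length(nxt) + 1L]] <- groups[[i]]; break }
        merge <- rbind(merge, c(groups[[i]][1], groups[[i + 1]][1]))
        heights <- c(heights, level)
        nxt[[length(nxt) + 1L]] <- next_id
        next_id <- next_id + 1L
        i <- i + 2
      }
      groups <- nxt
      level <- level + 1
    }
    height <- heights
  } else if (identical(layout, "random")) {
    withr::local_seed(substream_seed(seed, "hierarchy", "random"))
    ids <- as.list(-seq_len(n_cohorts))
    merge <- matrix(0L, 0, 2)
    height <- numeric(0)
    h <- 0
    next_id <- 1L
    while (length(ids) > 1) {
      pick <- sample.int(length(ids), 2)
      h <- h + stats::rexp(1)
      merge <- rbind(merge, c(ids[[pick[1]]][1], ids[[pick[2]]][1]))
      height <- c(height, h)
      ids[pick] <- NULL
      ids[[length(ids) + 1L]] <- next_id
      next_id <- next_id + 1L
    }
  } else {
    abort("unknown layout", class = "invalid_argument")
  }
  hc <- structure(
    list(merge = matrix(as.integer(merge), ncol = 2), height = height,
         order = seq_len(n_cohorts), labels = cohort_labels(n_cohorts),
         method = "planted", call = NULL, dist.method = "planted"),
    class = "hclust")
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))
  structure(list(hc = hc, n_cohorts = n_cohorts),
            class = "planted_hierarchy")
}

#' Layout helper: adjacent planted pairs
#'
#' Convenience explicit layout pairing cohorts (1,2), (3,4), ... at a common
#' low height, then joining the pair clusters at well separated heights. Used
#' to plant a ground truth with `n_cohorts / 2` tight pairs.
#'
#' @param n_cohorts an even number of cohorts.
#' @param pair_height height at which each planted pair merges.
#' @param step height increment between successive upper merges; the first
#'   upper merge sits at `pair_height + step`.
#' @return a list suitable for `generate_planted_hierarchy(layout = )`.
#' @export
planted_pairs_layout <- function(n_cohorts, pair_height = 0.1, step = 1) {
  assert_that(n_cohorts >= 2 && n_cohorts %% 2 == 0, "n_cohorts must be even")
  n_pairs <- n_cohorts %/% 2
  merge <- matrix(0L, 0, 2)
  for (p in seq_len(n_pairs)) merge <- rbind(merge, c(-(2 * p - 1), -(2 * p)))
  height <- rep(pair_height, n_pairs)
  if (n_pairs > 1) {
    acc <- 1L
    for (k in seq_len(n_pairs - 1)) {
      merge <- rbind(merge, c(acc, k + 1L))
      height <- c(height, pair_height + step * k)
      acc <- n_pairs + k
    }
  }
  list(merge = merge, height = height)
}

#' Ground-truth grouping at a requested number of groups
#'
#' Cuts the planted tree into `S` groups by removing the `S - 1` highest
#' merges; `S = 1` is one group of all cohorts and `S = n_cohorts` all
#' singletons.
#'
#' @param hierarchy a `planted_hierarchy`.
#' @param S requested group count, `1 <= S <= n_cohorts`.
#' @return integer group membership named by cohort.
#' @export
partition_at <- function(hierarchy, S) {
  assert_that(inherits(hierarchy, "planted_hierarchy"), "not a planted_hierarchy")
  assert_that(S >= 1 && S <= hierarchy$n_cohorts, "S out of range")
  cutree(hierarchy$hc, k = as.integer(S))
}

#' @export
print.planted_hierarchy <- function(x, ...) {
  cat("Planted hierarchy over", x$n_cohorts, "cohorts\n")
  cat("  merge heights:", paste(signif(x$hc$height, 3), collapse = " "), "\n")
  invisible(x)
}

#' Convert a planted hierarchy to an ape phylogeny
#'
#' The ultrametric tree whose cophenetic distances equal the merge heights;
#' used for Brownian diffusion of cohort parameters and for Newick export.
#'
#' @param x a `planted_hierarchy`.
#' @param ... unused.
#' @export
as.phylo.planted_hierarchy <- function(x, ...) ape::as.phylo(x$hc)

#' Write a hierarchy or dendrogram as Newick
#'
#' @param x a `planted_hierarchy` or `cohort_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  tr <- if (inherits(x, "planted_hierarchy")) ape::as.phylo(x$hc)
        else if (inherits(x, "cohort_dendrogram")) ape::as.phylo(x$hc)
        else abort("cannot convert to Newick", class = "invalid_argument")
  ape::write.tree(tr, file = path)
  invisible(path)
}
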