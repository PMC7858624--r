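# independent AUROC oracle: count positive/negative pairs, half credit on ties
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

test_that("slide confidences are channel-wise patch sums that conserve mass", {
  conf <- slide_confidence(rbind(c(0.9, 0.1), c(0.8, 0.2)))
  expect_equal(unname(conf$p_hat), c(1.7, 0.3))
  expect_equal(conf$n_patches, 2)
  one <- slide_confidence(matrix(c(0.5, 0.5), 1))
  expect_equal(unname(one$p_hat), c(0.5, 0.5))
  withr::with_seed(4, {
    for (i in 1:10) {
      n <- sample(1:30, 1)
      P <- matrix(runif(n * 2), n)
      P <- P / rowSums(P)
      expect_equal(sum(slide_confidence(P)$p_hat), n, tolerance = 1e-9)
    }
  })
  expect_error(slide_confidence(matrix(numeric(0), 0, 2)),
               class = "invalid_argument")
})

test_that("the likelihood-ratio decision follows the threshold exactly", {
  c10 <- slide_confidence(rbind(c(0.85, 0.15), c(0.85, 0.15)))  # (1.7, 0.3)
  expect_equal(slide_lr_decision(c10, 1)$y_hat, 0L)
  c01 <- slide_confidence(rbind(c(0.15, 0.85), c(0.15, 0.85)))  # (0.3, 1.7)
  expect_equal(slide_lr_decision(c01, 1)$y_hat, 1L)
  expect_equal(slide_lr_decision(c10, 0)$y_hat, 1L)  # eta = 0: always positive
  degenerate <- structure(list(p_hat = c(0, 2), n_patches = 2),
                          class = "slide_confidence")
  expect_equal(slide_lr_decision(degenerate, 1e6)$y_hat, 1L)
  expect_error(slide_lr_decision(c10, -1), class = "invalid_argument")
})

test_that("the slide score is the normalized positive confidence", {
  c10 <- slide_confidence(rbind(c(0.85, 0.15), c(0.85, 0.15)))
  expect_equal(slide_score(c10), 0.15)
  degenerate <- structure(list(p_hat = c(0, 2), n_patches = 2),
                          class = "slide_confidence")
  expect_equal(slide_score(degenerate), 1)
})

test_that("score ranking and exhaustive eta sweeps give the same ROC", {
  withr::with_seed(9, {
    n <- 50
    P0 <- runif(n, 0.1, 5); P1 <- runif(n, 0.1, 5)
    labels <- rbinom(n, 1, 0.5); labels[1:2] <- c(0, 1)
    ratio <- P1 / P0
    score <- P1 / (P0 + P1)
    # the score is a strictly increasing transform of the ratio, so both
    # induce the same slide ordering, hence identical ROC curves; the sets of
    # decisions achievable by sweeping eta coincide
    expect_identical(order(ratio), order(score))
    for (eta in c(0, 0.5, 1, 2, max(ratio) + 1)) {
      d_ratio <- as.integer(ratio >= eta)
      accepted <- sum(d_ratio)
      # the same decision set arises from thresholding the score at the
      # (n - accepted)-th order statistic boundary
      d_score <- as.integer(rank(-score, ties.method = "first") <= accepted)
      expect_identical(d_ratio, d_score)
    }
    expect_equal(compute_auroc(score, labels), compute_auroc(ratio, labels),
                 tolerance = 1e-12)
  })
})

test_that("AUROC equals brute-force pair counting on random instances", {
  expect_equal(compute_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(compute_auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  withr::with_seed(15, {
    for (i in 1:25) {
      n <- sample(4:200, 1)
      scores <- sample(seq_len(20), n, replace = TRUE) / 7  # force ties
      labels <- rbinom(n, 1, 0.5)
      labels[1:2] <- c(0, 1)
      expect_equal(compute_auroc(scores, labels),
                   auroc_oracle(scores, labels), tolerance = 1e-12)
    }
  })
  expect_error(compute_auroc(1:3, c(1, 1, 1)), class = "undefined_metric")
})

test_that("AUROC is invariant under strictly increasing transforms", {
  withr::with_seed(16, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.4); labels[1:2] <- c(0, 1)
    a <- compute_auroc(scores, labels)
    expect_equal(compute_auroc(exp(scores), labels), a, tolerance = 1e-12)
    expect_equal(compute_auroc(100 + 3 * scores, labels), a,
                 tolerance = 1e-12)
  })
})
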