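#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of distinct pull slice rename count
#' @importFrom purrr map map_dbl map_int map2 pmap imap keep
#' @importFrom stats rnorm runif rpois qt sd predict dist hclust cutree
#'   as.dist prcomp
#' @importFrom utils head write.csv read.csv
#' @importFrom ape as.phylo
#' @importFrom generics tidy glance
#' @importFrom Rcpp evalCpp
#' @useDynLib supercohort, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Deterministic derived seed for a named random substream. Keeps every stage's
# randomness independent of the others while reproducible from one master seed.
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L) + 1L
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}


assert_that <- function(cond, msg, class = "invalid_argument") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}

cohort_labels <- function(n) sprintf("C%02d", seq_len(n))

# stable digest of a numeric payload without external packages: FNV-1a over
# the binary serialization, reported as hex
dataset_digest <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  # fold in strides for speed; collisions irrelevant at this use
  idx <- seq(1, length(raw), by = max(1L, length(raw) %/% 65536L))
  for (b in as.integer(raw[idx])) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x-%d", as.integer(h), length(raw))
}
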