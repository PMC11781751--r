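#' Derive a stage-specific seed from a top-level seed
#'
#' All randomness in the package flows from one user-supplied seed. Stages
#' (cohort generation, fold assignment per category, detector fitting, ...)
#' draw their own seed through this fixed affine rule so that adding a stage
#' never perturbs the random stream of another.
#'
#' @param seed top-level integer seed.
#' @param stage non-negative integer stage index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage), length(stage) == 1)
  as.integer((as.double(seed) + 10007 * as.double(stage)) %% 2147483647)
}

# Average unsuccessful-search path length in a binary search tree of n points:
# c(n) = 2 H(n-1) - 2 (n-1)/n, with the harmonic number evaluated exactly.
# c(1) = 0 and c(2) = 1 by convention; used both to terminate isolation-tree
# paths at multi-point leaves and to normalise the forest score.
#' Expected isolation path length adjustment c(n)
#'
#' @param n leaf sample size (vectorised).
#' @return numeric vector of adjustments; `c(0) = c(1) = 0`, `c(2) = 1`.
#' @export
avg_path_length <- function(n) {
  vapply(n, function(m) {
    if (m <= 1) return(0)
    2 * sum(1 / seq_len(m - 1)) - 2 * (m - 1) / m
  }, numeric(1))
}

# stable descending order: primary key -x, secondary key original index
stable_desc_order <- function(x) {
  order(-x, seq_along(x), method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_binary_labels <- function(labels) {
  if (length(labels) == 0 || !all(labels %in% c(0, 1))) {
    stop("labels must be a non-empty 0/1 vector", call. = FALSE)
  }
  invisible(as.integer(labels))
}
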