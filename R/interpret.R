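#' Per-column baseline means for attribution
#'
#' The attribution methods replace a feature by its mean value. The default
#' provenance computes those means from the normal rows of the training set
#' (no test leakage); test-set means are available as the alternative.
#'
#' @param x encoded numeric matrix.
#' @param rows optional row subset to average over (e.g. training-normal
#'   rows).
#' @param provenance label recorded with the baseline,
#'   `"training-normal"` (default) or `"test-set"`.
#' @return object of class `attribution_baseline` with per-encoded-column
#'   means `mu`.
#' @export
baseline_means <- function(x, rows = NULL,
                           provenance = c("training-normal", "test-set")) {
  provenance <- match.arg(provenance)
  x <- as.matrix(x)
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  structure(list(mu = colMeans(x), provenance = provenance),
            class = "attribution_baseline")
}

# Build, for each instance row, the stack [original; one row per source
# feature with that feature's encoded columns replaced by the baseline].
# Categorical features are perturbed as a block: all their one-hot columns
# move to the (fractional) baseline means together.
perturb_stack <- function(x, mu, feature_cols) {
  d <- length(feature_cols)
  out <- matrix(NA_real_, nrow(x) * (d + 1L), ncol(x))
  r <- 0L
  for (i in seq_len(nrow(x))) {
    out[r + 1L, ] <- x[i, ]
    for (f in seq_len(d)) {
      row <- x[i, ]
      cols <- feature_cols[[f]]
      row[cols] <- mu[cols]
      out[r + 1L + f, ] <- row
    }
    r <- r + d + 1L
  }
  out
}

feature_column_map <- function(meta, columns) {
  stopifnot(all(meta$column == columns))
  split(seq_along(columns), factor(meta$source, levels = unique(meta$source)))
}

make_attribution <- function(features, score, delta, method, instance = NA) {
  ranks <- rank(-abs(delta), ties.method = "average")
  structure(
    list(instance = instance, score = score, method = method,
         table = data.frame(feature = features, delta = delta,
                            abs_delta = abs(delta), rank = ranks,
                            stringsAsFactors = FALSE)),
    class = "attribution"
  )
}

#' Mean-substitution feature-perturbation attribution
#'
#' For each source feature i, the instance is copied with that feature's
#' encoded columns replaced by their baseline means, re-scored, and the
#' attribution is the score change `dS_i = S_o - S_{m,i}`. Under the
#' higher-is-more-anomalous score contract a positive `dS_i` means the
#' feature's observed value raised the anomaly score. Features are ranked
#' by `|dS_i|`, ties by average rank.
#'
#' @param model any fitted `ad_model`.
#' @param x one encoded instance (vector) or a matrix of instances.
#' @param baseline an [attribution_baseline][baseline_means()].
#' @param meta encoded-column metadata (the `meta` of a `feature_matrix`).
#' @return one `attribution` object, or a list of them for matrix input.
#'   Each holds the original score and a table of `delta`, `abs_delta` and
#'   `rank` per source feature.
#' @export
perturb_attribution <- function(model, x, baseline, meta) {
  stopifnot(inherits(model, "ad_model"), inherits(baseline, "attribution_baseline"))
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$columns) || length(baseline$mu) != ncol(x)) {
    stop("column mismatch between model, baseline and instances", call. = FALSE)
  }
  fmap <- feature_column_map(meta, model$columns)
  d <- length(fmap)
  stack <- perturb_stack(x, baseline$mu, fmap)
  s <- ad_score(model, stack)
  out <- lapply(seq_len(nrow(x)), function(i) {
    block <- s[((i - 1L) * (d + 1L) + 1L):(i * (d + 1L))]
    make_attribution(names(fmap), block[1],
                     delta = block[1] - block[-1],
                     method = "perturb", instance = i)
  })
  if (single) out[[1]] else out
}

#' Local depth-based isolation-forest attribution (Local-DIFFI)
#'
#' For an isolation forest only: the importance of feature i for instance x
#' is the mean over trees of the absolute path-length change
#' `|h(x,T) - h(x_i', T)|` when feature i is replaced by its baseline mean.
#' Features are ranked by importance, descending.
#'
#' @param model a fitted `ad_iforest` model.
#' @inheritParams perturb_attribution
#' @return one `attribution` object (the `delta` column holds the
#'   importances `I_i`, all non-negative), or a list for matrix input.
#' @export
local_diffi <- function(model, x, baseline, meta) {
  if (!inherits(model, "ad_iforest")) {
    stop("local_diffi requires the native isolation forest; ",
         "use perturb_attribution for other detectors", call. = FALSE)
  }
  stopifnot(inherits(baseline, "attribution_baseline"))
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$columns) || length(baseline$mu) != ncol(x)) {
    stop("column mismatch between model, baseline and instances", call. = FALSE)
  }
  fmap <- feature_column_map(meta, model$columns)
  d <- length(fmap)
  stack <- perturb_stack(x, baseline$mu, fmap)
  h <- iforest_path_lengths(model, stack)  # rows x trees
  s <- ad_score(model, x)
  out <- lapply(seq_len(nrow(x)), function(i) {
    base_row <- (i - 1L) * (d + 1L) + 1L
    h0 <- h[base_row, ]
    imp <- vapply(seq_len(d), function(f) {
      mean(abs(h0 - h[base_row + f, ]))
    }, numeric(1))
    make_attribution(names(fmap), s[i], delta = imp,
                     method = "diffi", instance = i)
  })
  if (single) out[[1]] else out
}

#' Select the outlier instances to aggregate attributions over
#'
#' @param labels 0/1 vector (used by mode `"label"`: the labelled positives).
#' @param scores anomaly scores (used by mode `"topk"`).
#' @param mode `"label"` or `"topk"`.
#' @param k number of top-scoring instances for mode `"topk"`.
#' @return integer row indices; erroring rather than returning an empty set.
#' @export
select_outlier_points <- function(labels = NULL, scores = NULL,
                                  mode = c("label", "topk"), k = NULL) {
  mode <- match.arg(mode)
  ids <- if (mode == "label") {
    assert_binary_labels(labels)
    which(labels == 1)
  } else {
    if (is.null(scores) || is.null(k)) {
      stop("mode 'topk' needs scores and k", call. = FALSE)
    }
    if (k > length(scores)) stop("k exceeds the number of instances", call. = FALSE)
    stable_desc_order(scores)[seq_len(k)]
  }
  if (length(ids) == 0) stop("outlier selection is empty", call. = FALSE)
  ids
}

#' Average feature ranks across outlier instances
#'
#' Aggregates per-instance attribution ranks into one mean rank per feature;
#' lower mean rank = more influential across the outlier set.
#'
#' @param attributions non-empty list of `attribution` objects sharing one
#'   feature set.
#' @return data.frame of `feature` and `mean_rank`, sorted ascending by
#'   `mean_rank`.
#' @export
average_feature_ranks <- function(attributions) {
  if (length(attributions) == 0) stop("no attributions supplied", call. = FALSE)
  feats <- attributions[[1]]$table$feature
  ranks <- vapply(attributions, function(a) {
    if (!identical(a$table$feature, feats)) {
      stop("attributions do not share a feature set", call. = FALSE)
    }
    a$table$rank
  }, numeric(length(feats)))
  ranks <- matrix(ranks, nrow = length(feats))
  out <- data.frame(feature = feats, mean_rank = rowMeans(ranks),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Write attributions as long-format CSV
#'
#' @param attributions list of `attribution` objects.
#' @param path output CSV path.
#' @param instance_ids optional original row ids, one per attribution.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(attributions, path, instance_ids = NULL) {
  rows <- lapply(seq_along(attributions), function(i) {
    a <- attributions[[i]]
    data.frame(instance = instance_ids[i] %||% a$instance,
               method = a$method, score = a$score, a$table,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
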