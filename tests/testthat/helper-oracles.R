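# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementations in R/: AUCs by
# exhaustive enumeration, kNN by a double loop over dist(), the isolation
# tree by a nested-list recursion replaying the same random draws.

# AUCROC by exhaustive (positive, negative) pair enumeration
brute_auc_roc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# average precision by step-by-step precision/recall tabulation on the
# descending-score ordering (stable in original index)
brute_auc_pr <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  tp <- 0
  precisions <- c()
  for (i in seq_along(ord)) {
    if (labels[ord[i]] == 1) {
      tp <- tp + 1
      precisions <- c(precisions, tp / i)
    }
  }
  mean(precisions)
}

# k-th nearest neighbour distance via the full dist() matrix
brute_knn_scores <- function(train, query, k) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    sort(d)[k]
  })
}

# Reference isolation tree: grown as a nested list with the identical
# random-draw sequence as the package builder (feature uniformly among
# varying columns, split uniform in (min, max), left = strictly below).
ref_grow_itree <- function(x, rows, depth, height_limit) {
  if (length(rows) <= 1L || depth >= height_limit) {
    return(list(leaf = TRUE, size = length(rows), depth = depth))
  }
  sub <- x[rows, , drop = FALSE]
  lo <- apply(sub, 2, min)
  hi <- apply(sub, 2, max)
  cand <- which(hi > lo)
  if (length(cand) == 0L) {
    return(list(leaf = TRUE, size = length(rows), depth = depth))
  }
  q <- cand[sample.int(length(cand), 1L)]
  p <- runif(1, lo[q], hi[q])
  go_left <- sub[, q] < p
  list(leaf = FALSE, feature = q, threshold = p, depth = depth,
       left = ref_grow_itree(x, rows[go_left], depth + 1L, height_limit),
       right = ref_grow_itree(x, rows[!go_left], depth + 1L, height_limit))
}

ref_path_length <- function(node, x_row) {
  if (node$leaf) {
    return(node$depth + lbwad::avg_path_length(node$size))
  }
  if (x_row[node$feature] < node$threshold) {
    ref_path_length(node$left, x_row)
  } else {
    ref_path_length(node$right, x_row)
  }
}

# small anomaly-bearing numeric fixture: normal rows ~ N(0,1), anomalous
# rows shifted on the first `n_informative` columns
toy_matrix <- function(n = 120, d = 5, n_anom = 12, shift = 3,
                       n_informative = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  labels <- rep(0L, n)
  anom <- seq_len(n_anom)
  labels[anom] <- 1L
  x[anom, seq_len(n_informative)] <- x[anom, seq_len(n_informative)] + shift
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, labels = labels)
}

toy_meta <- function(x) {
  data.frame(column = colnames(x), source = colnames(x),
             role = "numeric", level = NA_character_,
             stringsAsFactors = FALSE)
}

native_detectors <- c("iforest", "hbos", "ecod", "knn", "gmm", "pca")
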