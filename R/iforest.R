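# Native isolation forest.
#
# Each tree isolates a subsample of the training data by recursive random
# axis-aligned splits. The anomaly score of x is 2^(-E[h(x,T)] / c(psi)),
# where h(x,T) is the path length of x in tree T (edges traversed plus the
# c(leaf size) adjustment for unresolved leaves) and c(.) is the expected
# unsuccessful-search path length (see avg_path_length). Trees are stored
# flat (parallel node vectors) so that scoring routes whole row blocks
# through the node table instead of walking rows one at a time.

iforest_fit <- function(spec, x) {
  n <- nrow(x)
  d <- ncol(x)
  psi <- min(spec$params$psi, n)
  height_limit <- ceiling(log2(max(psi, 2)))
  set.seed(spec$seed)
  trees <- vector("list", spec$params$n_trees)
  for (t in seq_len(spec$params$n_trees)) {
    idx <- if (n > psi) sample.int(n, psi) else seq_len(n)
    trees[[t]] <- build_itree(x, idx, height_limit)
  }
  list(trees = trees, psi = psi, c_psi = avg_path_length(psi),
       height_limit = height_limit)
}

# Grow one isolation tree over x[idx, ] into flat parallel vectors.
# At each internal node a split feature is drawn uniformly from the features
# that still vary, then a split point uniformly between that feature's min
# and max; rows with value < split go left. A node becomes a leaf when it
# holds <= 1 row, hits the height limit, or no feature varies.
build_itree <- function(x, idx, height_limit) {
  cap <- 4L * length(idx) + 8L
  feature <- integer(cap); threshold <- numeric(cap)
  left <- integer(cap); right <- integer(cap)
  size <- integer(cap); depth <- integer(cap)
  n_nodes <- 0L

  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(feature)) {  # grow storage
      feature <<- c(feature, integer(cap)); threshold <<- c(threshold, numeric(cap))
      left <<- c(left, integer(cap)); right <<- c(right, integer(cap))
      size <<- c(size, integer(cap)); depth <<- c(depth, integer(cap))
    }
    n_nodes
  }

  grow <- function(rows, dep) {
    node <- new_node()
    depth[node] <<- dep
    size[node] <<- length(rows)
    if (length(rows) <= 1L || dep >= height_limit) {
      feature[node] <<- 0L
      return(node)
    }
    sub <- x[rows, , drop = FALSE]
    lo <- apply(sub, 2, min)
    hi <- apply(sub, 2, max)
    cand <- which(hi > lo)
    if (length(cand) == 0L) {
      feature[node] <<- 0L
      return(node)
    }
    q <- cand[sample.int(length(cand), 1L)]
    p <- stats::runif(1, lo[q], hi[q])
    go_left <- sub[, q] < p
    feature[node] <<- q
    threshold[node] <<- p
    left[node] <<- grow(rows[go_left], dep + 1L)
    right[node] <<- grow(rows[!go_left], dep + 1L)
    node
  }

  grow(idx, 0L)
  keep <- seq_len(n_nodes)
  list(feature = feature[keep], threshold = threshold[keep],
       left = left[keep], right = right[keep],
       size = size[keep], depth = depth[keep])
}

# Path length h(x,T) for every row of x in one flat tree: rows are routed
# through the node table in blocks (parents precede children by
# construction), then h = depth + c(leaf size).
itree_path_length <- function(tree, x) {
  n <- nrow(x)
  node_of <- integer(n); node_of[] <- 1L
  h <- numeric(n)
  for (node in seq_along(tree$feature)) {
    rows <- which(node_of == node)
    if (length(rows) == 0L) next
    if (tree$feature[node] == 0L) {
      h[rows] <- tree$depth[node] + avg_path_length(tree$size[node])
    } else {
      go_left <- x[rows, tree$feature[node]] < tree$threshold[node]
      node_of[rows[go_left]] <- tree$left[node]
      node_of[rows[!go_left]] <- tree$right[node]
    }
  }
  h
}

#' Per-tree isolation path lengths
#'
#' Exposes h(x, T) for every tree of a fitted isolation forest; the local
#' depth-based attribution method ([local_diffi()]) is built on it.
#'
#' @param model a fitted `ad_iforest` model.
#' @param x numeric vector or matrix of instances.
#' @return matrix of path lengths, rows = instances, columns = trees.
#' @export
iforest_path_lengths <- function(model, x) {
  stopifnot(inherits(model, "ad_iforest"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$columns)) {
    stop("column mismatch with training matrix", call. = FALSE)
  }
  h <- vapply(model$trees, itree_path_length, numeric(nrow(x)), x = x)
  matrix(h, nrow = nrow(x))
}

#' @export
ad_score.ad_iforest <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  h <- iforest_path_lengths(model, as.matrix(x))
  2^(-rowMeans(h) / model$c_psi)
}
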