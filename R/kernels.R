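# Native scoring kernels: HBOS, ECOD, kNN, GMM, PCA.
# All follow the one-class contract: fit on normal rows only, score returns
# higher values for rows deviating more from the training distribution.

# ---- HBOS ------------------------------------------------------------------
# Histogram-based outlier score under a feature-independence assumption:
# per feature, an equal-width histogram over the training range; the score
# is the sum over features of -log(normalised bin mass), with a smoothing
# floor of 0.1/n so empty bins (and out-of-range queries) stay finite.

hbos_fit <- function(spec, x) {
  n <- nrow(x)
  n_bins <- spec$params$n_bins %||% ceiling(sqrt(n))
  hists <- lapply(seq_len(ncol(x)), function(j) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi > lo) {
      breaks <- seq(lo, hi, length.out = n_bins + 1)
      bin <- pmin(pmax(findInterval(x[, j], breaks, rightmost.closed = TRUE), 1L),
                  n_bins)
      mass <- tabulate(bin, n_bins) / n
    } else {
      breaks <- c(lo, lo)
      mass <- 1
    }
    list(lo = lo, hi = hi, breaks = breaks, mass = mass)
  })
  list(hists = hists, floor = 0.1 / n, n_bins = n_bins)
}

#' @export
ad_score.ad_hbos <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  s <- numeric(nrow(x))
  for (j in seq_len(ncol(x))) {
    h <- model$hists[[j]]
    if (h$hi > h$lo) {
      inside <- x[, j] >= h$lo & x[, j] <= h$hi
      bin <- pmin(pmax(findInterval(x[, j], h$breaks, rightmost.closed = TRUE), 1L),
                  length(h$mass))
      m <- h$mass[bin]
      m[!inside] <- 0  # out-of-range: empty-bin treatment
    } else {
      m <- ifelse(x[, j] == h$lo, 1, 0)
    }
    s <- s - log(pmax(m, model$floor))
  }
  s
}

# ---- ECOD ------------------------------------------------------------------
# Empirical-CDF outlier detection, two-sided: per feature the tail mass is
# min(P(X <= x), P(X >= x)) with a 1/(n+1) floor; the score aggregates
# -log(tail) over features. (Side selection by skewness in the original
# method is deliberately simplified to the symmetric min-tail rule.)

ecod_fit <- function(spec, x) {
  list(sorted = lapply(seq_len(ncol(x)), function(j) sort(x[, j])),
       n = nrow(x))
}

#' @export
ad_score.ad_ecod <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  n <- model$n
  floor_p <- 1 / (n + 1)
  s <- numeric(nrow(x))
  for (j in seq_len(ncol(x))) {
    v <- model$sorted[[j]]
    le <- findInterval(x[, j], v) / n                  # P(X <= x)
    ge <- (n - findInterval(x[, j], v, left.open = TRUE)) / n  # P(X >= x)
    tail_p <- pmax(pmin(le, ge), floor_p)
    s <- s - log(tail_p)
  }
  s
}

# ---- kNN -------------------------------------------------------------------
# Distance-based outlier score: Euclidean distance from the query to its
# k-th nearest training row. Ties in distance are resolved by the sort
# order, which is stable in row index.

knn_fit <- function(spec, x) {
  k <- spec$params$k
  if (nrow(x) < k + 1) {
    stop("knn requires more than k = ", k, " training rows, got ", nrow(x),
         call. = FALSE)
  }
  list(train_t = t(x), k = k)
}

#' @export
ad_score.ad_knn <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  k <- model$k
  # one query row at a time: the squared-distance sum is then independent of
  # the batch shape, so batched and single-row scoring agree bitwise
  apply(x, 1, function(q) {
    d2 <- colSums((model$train_t - q)^2)
    sqrt(sort(d2, partial = k)[k])
  })
}

# ---- GMM -------------------------------------------------------------------
# Negative log-likelihood under a Gaussian mixture fitted by EM with full,
# ridge-regularised covariances. With one component (the default) the fit is
# closed-form; for k > 1, responsibilities are initialised from k-means
# under the spec seed and EM runs to convergence of the log-likelihood.

gmm_fit <- function(spec, x) {
  k <- spec$params$n_components
  ridge <- spec$params$ridge
  n <- nrow(x); d <- ncol(x)
  if (n <= d && k >= 1) {
    # still fine thanks to the ridge, but flag pathological shapes
    if (n < 2) stop("gmm requires at least 2 training rows", call. = FALSE)
  }
  if (k == 1) {
    mu <- colMeans(x)
    sigma <- stats::cov(x) * (n - 1) / n + diag(ridge, d)
    comp <- list(list(weight = 1, mu = mu, chol = chol(sigma)))
    return(list(components = comp, k = 1))
  }
  set.seed(spec$seed)
  km <- stats::kmeans(x, centers = k, nstart = 3, iter.max = 50)
  resp <- outer(km$cluster, seq_len(k), "==") * 1
  loglik_old <- -Inf
  comp <- NULL
  for (iter in seq_len(200)) {
    nk <- pmax(colSums(resp), 1e-8)
    comp <- lapply(seq_len(k), function(c_) {
      w <- resp[, c_] / nk[c_]
      mu <- colSums(x * w)
      xc <- sweep(x, 2, mu)
      sigma <- crossprod(xc * sqrt(w), xc * sqrt(w)) + diag(ridge, d)
      list(weight = nk[c_] / n, mu = mu, chol = chol(sigma))
    })
    logdens <- vapply(comp, function(cc) {
      log(cc$weight) + gauss_logdensity(x, cc$mu, cc$chol)
    }, numeric(n))
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    loglik <- sum(lse)
    resp <- exp(logdens - lse)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < 1e-8 * abs(loglik_old) + 1e-10) break
    loglik_old <- loglik
  }
  list(components = comp, k = k)
}

gauss_logdensity <- function(x, mu, cholS) {
  xc <- sweep(as.matrix(x), 2, mu)
  z <- backsolve(cholS, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(cholS))) - 0.5 * ncol(x) * log(2 * pi)
}

#' @export
ad_score.ad_gmm <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  n <- nrow(x)
  logdens <- vapply(model$components, function(cc) {
    log(cc$weight) + gauss_logdensity(x, cc$mu, cc$chol)
  }, numeric(n))
  logdens <- matrix(logdens, nrow = n)
  m <- apply(logdens, 1, max)
  -(m + log(rowSums(exp(logdens - m))))
}

# ---- PCA -------------------------------------------------------------------
# Reconstruction-error score: project a centred query onto the top-q
# principal components of the training covariance (q = fewest components
# explaining var_explained of the variance) and score by the squared
# residual norm.

pca_fit <- function(spec, x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  var_comp <- sv$d^2
  total <- sum(var_comp)
  q <- if (total == 0) 1L else which(cumsum(var_comp) / total >= spec$params$var_explained)[1]
  list(mu = mu, v = sv$v[, seq_len(q), drop = FALSE], q = q)
}

#' @export
ad_score.ad_pca <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xc <- sweep(as.matrix(x), 2, model$mu)
  proj <- xc %*% model$v
  resid <- xc - proj %*% t(model$v)
  rowSums(resid^2)
}
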