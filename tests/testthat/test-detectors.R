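test_that("spec validation rejects unknown detectors and hyperparameters", {
  expect_error(ad_spec("nosuch"), "unknown detector")
  expect_error(ad_spec("knn", bogus = 1), "unknown hyperparameters")
  sp <- ad_spec("knn", k = 3, seed = 9)
  expect_equal(sp$params$k, 3)
  expect_equal(sp$seed, 9L)
})

test_that("isolation forest fitting is deterministic and columns are checked", {
  x <- toy_matrix(100, 5)$x
  m1 <- ad_fit(ad_spec("iforest", seed = 4), x)
  m2 <- ad_fit(ad_spec("iforest", seed = 4), x)
  expect_identical(m1$trees, m2$trees)
  expect_identical(ad_score(m1, x), ad_score(m2, x))
  expect_error(ad_score(m1, x[, 1:3]), "column mismatch")
})

test_that("c(n) matches the closed-form harmonic expression up to n = 1000", {
  for (n in c(1, 2, 3, 10, 257, 1000)) {
    expected <- if (n <= 1) 0 else {
      h <- sum(1 / seq_len(n - 1))
      2 * h - 2 * (n - 1) / n
    }
    expect_equal(avg_path_length(n), expected)
  }
  expect_equal(avg_path_length(2), 1)
})

test_that("single-tree path lengths match a replayed reference build", {
  # <= 8 training points in 1-D, single tree; the reference grows a
  # nested-list tree with the same random draw sequence
  for (seed in 1:10) {
    x <- matrix(c(0.1, 0.3, 0.35, 0.6, 0.62, 0.8, 0.9, 0.95), ncol = 1)
    m <- ad_fit(ad_spec("iforest", n_trees = 1, psi = 8, seed = seed), x)
    set.seed(seed)
    ref <- ref_grow_itree(x, 1:8, 0L, ceiling(log2(8)))
    queries <- matrix(seq(0, 1, by = 0.05), ncol = 1)
    h_pkg <- iforest_path_lengths(m, queries)[, 1]
    h_ref <- apply(queries, 1, function(q) ref_path_length(ref, q))
    expect_equal(h_pkg, h_ref)
  }
})

test_that("leaf path lengths include the c(leaf size) adjustment", {
  # depth-1 leaf of size 1 -> h = 1 + c(1) = 1; size-2 leaf at depth 2 ->
  # h = 2 + c(2) = 3
  expect_equal(1 + avg_path_length(1), 1)
  expect_equal(2 + avg_path_length(2), 3)
  # degenerate training data (all identical): every point sits in the root
  # leaf, h = c(n) for all, score exactly 2^(-c(n)/c(n)) = 0.5
  x <- matrix(rep(1, 8), ncol = 1)
  m <- ad_fit(ad_spec("iforest", n_trees = 5, psi = 8, seed = 1), x)
  h <- iforest_path_lengths(m, matrix(1))
  expect_equal(as.vector(h), rep(avg_path_length(8), 5))
  expect_equal(as.vector(ad_score(m, matrix(1))), 0.5)
})

test_that("knn score equals brute-force all-pairs distances", {
  toy <- toy_matrix(150, 4, seed = 7)
  train <- toy$x[1:100, ]
  query <- toy$x[101:150, ]
  for (k in c(1, 5)) {
    m <- ad_fit(ad_spec("knn", k = k), train)
    expect_equal(unname(ad_score(m, query)),
                 unname(brute_knn_scores(train, query, k)),
                 tolerance = 1e-12)
  }
  # k = 1 on 1-D points {0, 1, 2}: query 10 is 8 away from its neighbour
  m1 <- ad_fit(ad_spec("knn", k = 1), matrix(c(0, 1, 2), ncol = 1))
  expect_equal(as.vector(ad_score(m1, matrix(10))), 8)
  expect_error(ad_fit(ad_spec("knn", k = 5), matrix(rnorm(4), ncol = 1)),
               "training rows")
})

test_that("ecod applies the 1/(n+1) tail floor beyond the training range", {
  x <- matrix(1:99, ncol = 1)
  m <- ad_fit(ad_spec("ecod"), x)
  expect_equal(as.vector(ad_score(m, matrix(0))), -log(0.01))
  expect_equal(as.vector(ad_score(m, matrix(1000))), -log(0.01))
  # interior point: tail = min(P(X<=50), P(X>=50)) = 50/99
  expect_equal(as.vector(ad_score(m, matrix(50))), -log(50 / 99))
})

test_that("hbos scores empty bins strictly above populated bins", {
  set.seed(3)
  x <- matrix(runif(400), ncol = 1)
  m <- ad_fit(ad_spec("hbos"), x)
  s <- ad_score(m, rbind(0.5, 10))  # populated bin vs far outside
  expect_lt(s[1], s[2])
  expect_true(all(is.finite(ad_score(m, x))))
})

test_that("gmm score is minimised at the training mean", {
  toy <- toy_matrix(200, 3, n_anom = 0, seed = 5)
  m <- ad_fit(ad_spec("gmm"), toy$x)
  mu <- colMeans(toy$x)
  s_mu <- ad_score(m, mu)
  for (i in 1:20) {
    expect_lte(s_mu, ad_score(m, mu + rnorm(3)))
  }
})

test_that("gmm with several components is deterministic and finite", {
  toy <- toy_matrix(300, 3, n_anom = 0, seed = 6)
  m1 <- ad_fit(ad_spec("gmm", n_components = 2, seed = 8), toy$x)
  m2 <- ad_fit(ad_spec("gmm", n_components = 2, seed = 8), toy$x)
  expect_equal(ad_score(m1, toy$x), ad_score(m2, toy$x))
  expect_true(all(is.finite(ad_score(m1, toy$x))))
})

test_that("full-rank pca reconstructs training rows exactly", {
  toy <- toy_matrix(50, 4, n_anom = 0, seed = 2)
  m <- ad_fit(ad_spec("pca", var_explained = 1), toy$x)
  expect_equal(max(abs(ad_score(m, toy$x))), 0, tolerance = 1e-20)
  # reduced rank: off-subspace points score higher than on-subspace points
  m9 <- ad_fit(ad_spec("pca", var_explained = 0.5), toy$x)
  expect_true(all(ad_score(m9, toy$x + 10 * rnorm(4)) >= 0))
})

test_that("scores are equivariant under row permutation", {
  toy <- toy_matrix(120, 4, seed = 9)
  perm <- sample(nrow(toy$x))
  for (nm in native_detectors) {
    m <- ad_fit(ad_spec(nm, seed = 3), toy$x[toy$labels == 0, ])
    s <- ad_score(m, toy$x)
    expect_equal(unname(ad_score(m, toy$x[perm, ])), unname(s[perm]),
                 info = nm)
  }
})

test_that("every native detector scores shifted anomalies above chance", {
  aucs <- matrix(NA_real_, 5, length(native_detectors),
                 dimnames = list(NULL, native_detectors))
  for (s in 1:5) {
    toy <- toy_matrix(250, 6, n_anom = 25, shift = 2.5, seed = s)
    for (nm in native_detectors) {
      m <- ad_fit(ad_spec(nm, seed = s), toy$x[toy$labels == 0, ])
      aucs[s, nm] <- auc_roc(ad_score(m, toy$x), toy$labels)
    }
  }
  for (nm in native_detectors) expect_gt(mean(aucs[, nm]), 0.5)
})

test_that("adapters enforce orientation and registry uniqueness", {
  nm <- paste0("testmean_", as.integer(stats::runif(1, 1, 1e8)))
  # a 'normality' scorer: higher = closer to the training mean
  fit_fn <- function(x, spec) colMeans(x)
  score_fn <- function(state, x) -sqrt(colSums((t(x) - state)^2))
  expect_error(register_adapter(nm, fit_fn, score_fn), "orientation")
  register_adapter(nm, fit_fn, score_fn, orientation = "normal")
  expect_error(register_adapter(nm, fit_fn, score_fn, orientation = "normal"),
               "already registered")
  toy <- toy_matrix(100, 3, n_anom = 10, shift = 3, seed = 4)
  m <- ad_fit(ad_spec(paste0("adapter:", nm)), toy$x[toy$labels == 0, ])
  s <- ad_score(m, toy$x)
  # negation restores the higher-is-anomalous contract: AUC above chance and
  # identical to manually negating the raw convention
  expect_equal(auc_roc(s, toy$labels),
               1 - auc_roc(-s, toy$labels))
  expect_gt(auc_roc(s, toy$labels), 0.5)
  expect_error(ad_score(m, toy$x[, 1:2]), "column mismatch")
  expect_error(ad_fit(ad_spec("adapter:unregistered_name"), toy$x),
               "no adapter registered")
})
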