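#' Stratified fold plan for repeated cross-validation
#'
#' Assigns every row to one test fold per repeat, spreading the rare
#' positives as evenly as possible so every test fold contains both classes.
#'
#' @param labels 0/1 vector (1 = anomalous).
#' @param repeats number of independently seeded repetitions (default 2).
#' @param folds folds per repetition (default 5).
#' @param seed integer seed.
#' @param category optional name used in error messages.
#' @return object of class `fold_plan`: `assignment` is an n x repeats
#'   integer matrix of fold ids.
#' @export
make_folds <- function(labels, repeats = 2L, folds = 5L, seed = 0L,
                       category = NULL) {
  assert_binary_labels(labels)
  npos <- sum(labels == 1)
  if (npos < folds) {
    stop("category ", category %||% "(unnamed)", ": ", npos,
         " positive rows cannot be spread over ", folds,
         " folds; reduce the fold count or enlarge the cohort", call. = FALSE)
  }
  n <- length(labels)
  assignment <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    set.seed(stage_seed(seed, r))
    for (cls in c(1L, 0L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx, r] <- rep_len(seq_len(folds), length(idx))
    }
  }
  structure(list(assignment = assignment, repeats = as.integer(repeats),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly drawn positive outscores a uniformly drawn
#' negative, with ties credited 0.5; computed from average ranks.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUCROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("auc_roc requires both classes in the input", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Mean of the precision evaluated at each positive's rank when instances
#' are sorted by descending score (ties broken stably by original index).
#' Its chance level equals the positive prevalence.
#'
#' @inheritParams auc_roc
#' @return average precision in `(0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("auc_pr requires both classes in the input", call. = FALSE)
  }
  ord <- stable_desc_order(scores)
  y <- labels[ord]
  cum_pos <- cumsum(y)
  prec_at_pos <- (cum_pos / seq_along(y))[y == 1]
  mean(prec_at_pos)
}

#' Normal-only-training cross-validated evaluation
#'
#' For every repeat x fold of the plan: fit each detector on the normal rows
#' of the non-held-out folds, score every row of the held-out fold, and
#' record AUCROC and AUCPR. A detector failure on a fold is recorded (with
#' its condition message) and excluded from the means, with a warning.
#'
#' @param x preprocessed numeric matrix (rows = instances).
#' @param labels 0/1 vector aligned with `x`.
#' @param specs one [ad_spec()] or a list of them.
#' @param plan a [fold_plan][make_folds()].
#' @return object of class `eval_report` with `folds` (one row per detector
#'   x repeat x fold) and `summary` (per-detector means).
#' @export
cross_validate <- function(x, labels, specs, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  x <- as.matrix(x)
  assert_binary_labels(labels)
  if (inherits(specs, "ad_spec")) specs <- list(specs)
  rows <- list()
  for (spec in specs) {
    for (r in seq_len(plan$repeats)) {
      fa <- plan$assignment[, r]
      for (f in seq_len(plan$folds)) {
        split <- normal_only_split(labels, fa, f)
        res <- tryCatch({
          model <- ad_fit(spec, x[split$train, , drop = FALSE])
          s <- ad_score(model, x[split$test, , drop = FALSE])
          yl <- labels[split$test]
          c(auc_roc(s, yl), auc_pr(s, yl))
        }, error = function(e) {
          warning("detector ", spec$name, " failed on repeat ", r, " fold ",
                  f, ": ", conditionMessage(e), call. = FALSE)
          c(NA_real_, NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          detector = spec$name, rep = r, fold = f,
          aucroc = res[1], aucpr = res[2], stringsAsFactors = FALSE
        )
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(split(folds_df, folds_df$detector), function(d) {
    data.frame(detector = d$detector[1],
               mean_aucroc = mean(d$aucroc, na.rm = TRUE),
               mean_aucpr = mean(d$aucpr, na.rm = TRUE),
               n_folds = sum(!is.na(d$aucroc)), stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  structure(list(folds = folds_df, summary = summary_df),
            class = "eval_report")
}

#' Cross-validated evaluation straight from a raw cohort
#'
#' Adds the preprocessing choice to [cross_validate()]: `"global"` fits the
#' imputation/encoding/scaling transform once on the full cohort (the
#' conventional pipeline, which lets test-fold statistics leak into the
#' transform), while `"fold-safe"` refits the transform per fold on the
#' training-fold normal rows only.
#'
#' @param cohort cohort data.frame (features + `weight` not required here).
#' @param schema feature schema.
#' @param labels 0/1 vector aligned with the cohort rows.
#' @param specs one [ad_spec()] or a list.
#' @param plan a [fold_plan][make_folds()].
#' @param mode `"global"` or `"fold-safe"`.
#' @return an `eval_report` (see [cross_validate()]).
#' @export
cross_validate_cohort <- function(cohort, schema, labels, specs, plan,
                                  mode = c("global", "fold-safe")) {
  mode <- match.arg(mode)
  if (mode == "global") {
    fm <- preprocess_apply(preprocess_fit(cohort, schema), cohort)
    return(cross_validate(fm$x, labels, specs, plan))
  }
  if (inherits(specs, "ad_spec")) specs <- list(specs)
  rows <- list()
  for (r in seq_len(plan$repeats)) {
    fa <- plan$assignment[, r]
    for (f in seq_len(plan$folds)) {
      split <- normal_only_split(labels, fa, f)
      tf <- preprocess_fit(cohort, schema, rows = split$train)
      x_train <- preprocess_apply(tf, cohort[split$train, , drop = FALSE])$x
      x_test <- preprocess_apply(tf, cohort[split$test, , drop = FALSE])$x
      yl <- labels[split$test]
      for (spec in specs) {
        res <- tryCatch({
          model <- ad_fit(spec, x_train)
          s <- ad_score(model, x_test)
          c(auc_roc(s, yl), auc_pr(s, yl))
        }, error = function(e) {
          warning("detector ", spec$name, " failed on repeat ", r, " fold ",
                  f, ": ", conditionMessage(e), call. = FALSE)
          c(NA_real_, NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          detector = spec$name, rep = r, fold = f,
          aucroc = res[1], aucpr = res[2], stringsAsFactors = FALSE
        )
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  folds_df <- folds_df[order(folds_df$detector, folds_df$rep, folds_df$fold), ]
  rownames(folds_df) <- NULL
  summary_df <- do.call(rbind, lapply(split(folds_df, folds_df$detector), function(d) {
    data.frame(detector = d$detector[1],
               mean_aucroc = mean(d$aucroc, na.rm = TRUE),
               mean_aucpr = mean(d$aucpr, na.rm = TRUE),
               n_folds = sum(!is.na(d$aucroc)), stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  structure(list(folds = folds_df, summary = summary_df),
            class = "eval_report")
}

#' One-way ANOVA F-test across detectors' fold-level metrics
#'
#' Groups are the per-fold AUC values of each detector; the F statistic
#' compares between-detector to within-detector variability. A fully
#' degenerate input (zero between- and within-group variance) is defined to
#' give F = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per detector; at least two
#'   groups of at least two values each.
#' @return object of class `ftest_result`: `statistic`, `p_value`, `df`.
#' @export
anova_f <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("anova_f needs >= 2 groups with >= 2 values each", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (any(is.na(values))) {
    groups <- lapply(groups, function(g) g[!is.na(g)])
    if (any(lengths(groups) < 2)) {
      stop("anova_f needs >= 2 non-missing values per group", call. = FALSE)
    }
    values <- unlist(groups, use.names = FALSE)
  }
  k <- length(groups)
  n_total <- length(values)
  grand <- mean(values)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n_total - k
  if (ssb <= .Machine$double.eps * max(1, sum(values^2)) && ssw <= .Machine$double.eps * max(1, sum(values^2))) {
    f_stat <- 0; p <- 1
  } else if (ssw == 0) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = f_stat, p_value = p, df = c(df1 = df1, df2 = df2),
                 groups = names(groups) %||% paste0("group", seq_len(k))),
            class = "ftest_result")
}

#' Write an evaluation report as long-format CSV
#'
#' @param report an `eval_report`.
#' @param path output CSV path.
#' @param category optional category name added as a column.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, category = NA_character_) {
  long <- report$folds
  long <- data.frame(category = category, long, stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
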