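#' Infer a feature schema from a cohort data.frame
#'
#' Numeric columns are `numeric`; character/factor columns whose observed
#' values are a subset of {Yes, No} (or {0, 1}) are `binary`; the rest are
#' `categorical` with lexicographically ordered levels. The `weight` column
#' is never a feature.
#'
#' @param cohort cohort data.frame.
#' @return schema data.frame with columns `name`, `kind`, `levels`.
#' @export
infer_schema <- function(cohort) {
  nms <- setdiff(names(cohort), "weight")
  kind <- character(length(nms))
  levels <- vector("list", length(nms))
  for (i in seq_along(nms)) {
    col <- cohort[[nms[i]]]
    obs <- unique(col[!is.na(col)])
    if (is.numeric(col) && !all(obs %in% c(0, 1))) {
      kind[i] <- "numeric"
    } else if (all(obs %in% c("Yes", "No")) || all(obs %in% c(0, 1))) {
      kind[i] <- "binary"
    } else {
      kind[i] <- "categorical"
      levels[[i]] <- sort(unique(as.character(obs)))
    }
  }
  out <- data.frame(name = nms, kind = kind, stringsAsFactors = FALSE)
  out$levels <- levels
  out
}

#' Stratify birth weights at a threshold
#'
#' @param weights vector of birth weights in grams; must be finite and
#'   positive (screen rows first with [drop_invalid_weight()]).
#' @param threshold threshold in grams.
#' @return integer 0/1 vector; 1 where `weight < threshold` (strictly).
#' @export
stratify_by_weight <- function(weights, threshold) {
  if (any(is.na(weights)) || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be finite and positive; drop invalid rows first",
         call. = FALSE)
  }
  as.integer(weights < threshold)
}

#' Nested birth-weight category labels
#'
#' @param weights vector of birth weights in grams.
#' @return list of 0/1 vectors `lbw` (<2500 g), `vlbw` (<1500 g),
#'   `elbw` (<1000 g); nested by construction.
#' @export
category_labels <- function(weights) {
  list(
    lbw = stratify_by_weight(weights, 2500),
    vlbw = stratify_by_weight(weights, 1500),
    elbw = stratify_by_weight(weights, 1000)
  )
}

#' Drop rows whose outcome weight is missing or non-positive
#'
#' @param cohort cohort data.frame with a `weight` column.
#' @return the cohort with invalid rows removed; the number dropped is
#'   reported via `message()`.
#' @export
drop_invalid_weight <- function(cohort) {
  bad <- is.na(cohort$weight) | !is.finite(cohort$weight) | cohort$weight <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) dropped: missing or non-positive weight")
    cohort <- cohort[!bad, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  cohort
}

#' Positive-class fraction of a label vector
#'
#' @param labels 0/1 vector.
#' @return positives / total.
#' @export
prevalence <- function(labels) {
  assert_binary_labels(labels)
  sum(labels == 1) / length(labels)
}

#' Impute a single column by observed mean (numeric) or mode
#'
#' Mode ties are broken by the lexicographically smallest value so that the
#' result is deterministic.
#'
#' @param column vector with possible `NA`s.
#' @param kind one of `"numeric"`, `"binary"`, `"categorical"`.
#' @param value optional pre-fitted imputation value (replay mode).
#' @return list with the imputed `column` and the `value` used.
#' @export
impute_column <- function(column, kind, value = NULL) {
  obs <- column[!is.na(column)]
  if (is.null(value)) {
    if (length(obs) == 0) stop("column is all-missing", call. = FALSE)
    value <- if (kind == "numeric") {
      mean(obs)
    } else {
      tab <- table(as.character(obs))
      cand <- names(tab)[tab == max(tab)]
      sort(cand)[1]
    }
  }
  column[is.na(column)] <- value
  list(column = column, value = value)
}

#' Encode an imputed column numerically
#'
#' Binary Yes/No becomes a single 0/1 column (already-numeric 0/1 passes
#' through); a categorical with k schema levels becomes k indicator columns
#' in schema level order. Unseen categories are a hard error.
#'
#' @param column imputed vector (no `NA`s).
#' @param kind `"numeric"`, `"binary"` or `"categorical"`.
#' @param name source feature name (used for output column names).
#' @param levels schema level order for categoricals.
#' @return numeric matrix with one or k columns.
#' @export
encode_column <- function(column, kind, name, levels = NULL) {
  if (kind == "numeric") {
    m <- matrix(as.numeric(column), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  if (kind == "binary") {
    v <- if (is.numeric(column)) {
      if (!all(column %in% c(0, 1))) {
        stop("binary column '", name, "' contains values outside {0,1}",
             call. = FALSE)
      }
      as.numeric(column)
    } else {
      if (!all(column %in% c("Yes", "No"))) {
        stop("binary column '", name, "' contains values outside {Yes,No}",
             call. = FALSE)
      }
      as.numeric(column == "Yes")
    }
    m <- matrix(v, ncol = 1)
    colnames(m) <- name
    return(m)
  }
  column <- as.character(column)
  unseen <- setdiff(unique(column), levels)
  if (length(unseen)) {
    stop("unseen categories in '", name, "': ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(levels, function(lv) as.numeric(column == lv),
              numeric(length(column)))
  m <- matrix(m, ncol = length(levels))
  colnames(m) <- paste(name, levels, sep = ".")
  m
}

#' Fit a min-max transform per column
#'
#' @param x numeric matrix, no missing values.
#' @return list of per-column `min` and `max`.
#' @export
minmax_fit <- function(x) {
  if (any(!is.finite(x))) stop("minmax_fit requires a finite matrix", call. = FALSE)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' Apply a fitted min-max transform
#'
#' Values are mapped by `(x - min) / (max - min)`; values outside the fitted
#' range are clipped into `[0, 1]`; a constant fitted column maps to 0.
#'
#' @param params list from [minmax_fit()].
#' @param x numeric matrix with matching columns.
#' @return matrix with every entry in `[0, 1]`.
#' @export
minmax_apply <- function(params, x) {
  if (is.null(params$min)) stop("minmax transform has not been fitted", call. = FALSE)
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  scale <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2, scale, "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Fit the full preprocessing transform on (a subset of) a cohort
#'
#' Implements the tabular pipeline: per-feature mean/mode imputation,
#' Yes/No and one-hot encoding, then min-max scaling to `[0, 1]`. Fitting on
#' `rows` (e.g. the normal rows of the training folds) gives the leakage-free
#' mode; fitting on all rows reproduces the conventional global pipeline.
#'
#' @param cohort cohort data.frame (feature columns, optional `weight`).
#' @param schema schema data.frame (see [infer_schema()], [default_schema()]).
#' @param rows integer row indices to fit on (default: all rows).
#' @return an object of class `lbw_transform` holding imputation values,
#'   category orders and min/max per encoded column.
#' @export
preprocess_fit <- function(cohort, schema = infer_schema(cohort), rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cohort))
  fit_part <- cohort[rows, , drop = FALSE]
  impute_values <- list()
  blocks <- list()
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    if (!nm %in% names(fit_part)) stop("cohort lacks feature '", nm, "'", call. = FALSE)
    imp <- impute_column(fit_part[[nm]], schema$kind[j])
    impute_values[[nm]] <- imp$value
    blocks[[nm]] <- encode_column(imp$column, schema$kind[j], nm,
                                  schema$levels[[j]])
  }
  enc <- do.call(cbind, blocks)
  mm <- minmax_fit(enc)
  structure(
    list(schema = schema, impute_values = impute_values, minmax = mm),
    class = "lbw_transform"
  )
}

#' Apply a fitted preprocessing transform to a cohort
#'
#' @param transform an `lbw_transform` from [preprocess_fit()].
#' @param cohort cohort data.frame.
#' @return a `feature_matrix`: list with the scaled numeric matrix `x` and
#'   `meta`, a data.frame mapping each encoded column to its source feature,
#'   encoding role and (for one-hot columns) level.
#' @export
preprocess_apply <- function(transform, cohort) {
  stopifnot(inherits(transform, "lbw_transform"))
  schema <- transform$schema
  blocks <- list()
  meta <- list()
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    kind <- schema$kind[j]
    imp <- impute_column(cohort[[nm]], kind, value = transform$impute_values[[nm]])
    b <- encode_column(imp$column, kind, nm, schema$levels[[j]])
    blocks[[nm]] <- b
    meta[[nm]] <- data.frame(
      column = colnames(b),
      source = nm,
      role = if (kind == "categorical") "onehot" else kind,
      level = if (kind == "categorical") schema$levels[[j]] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  enc <- do.call(cbind, blocks)
  x <- minmax_apply(transform$minmax, enc)
  structure(
    list(x = x, meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         transform = transform),
    class = "feature_matrix"
  )
}

#' Normal-only training split for one held-out fold
#'
#' @param labels 0/1 label vector (1 = anomalous).
#' @param fold_assignment integer fold id per row.
#' @param heldout the fold id to hold out for testing.
#' @return list of row indices: `train` (normal rows of all other folds) and
#'   `test` (every row of the held-out fold).
#' @export
normal_only_split <- function(labels, fold_assignment, heldout) {
  assert_binary_labels(labels)
  stopifnot(length(labels) == length(fold_assignment))
  test <- which(fold_assignment == heldout)
  train <- which(fold_assignment != heldout & labels == 0)
  list(train = train, test = test)
}

#' Serialise a fitted transform to JSON for exact replay
#'
#' @param transform an `lbw_transform`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  obj <- list(
    schema = list(name = transform$schema$name, kind = transform$schema$kind,
                  levels = transform$schema$levels),
    impute_values = transform$impute_values,
    minmax = transform$minmax
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
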