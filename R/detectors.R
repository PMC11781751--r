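#' Anomaly scorer specification
#'
#' Names a detector and fixes its hyperparameters and seed. Native detectors:
#' `iforest`, `hbos`, `ecod`, `knn`, `gmm`, `pca`. External detectors are
#' addressed as `adapter:<name>` after [register_adapter()].
#'
#' Native hyperparameters (with defaults):
#' \describe{
#'   \item{iforest}{`n_trees = 100`, `psi = 256` (subsample size, capped at
#'     the training size).}
#'   \item{hbos}{`n_bins = NULL` (per-feature equal-width bins, default
#'     `ceiling(sqrt(n))`), smoothing floor `0.1/n` on normalised height.}
#'   \item{ecod}{two-sided empirical tails with floor `1/(n+1)`.}
#'   \item{knn}{`k = 5` (distance to the k-th nearest training row).}
#'   \item{gmm}{`n_components = 1`, `ridge = 1e-6` covariance regularisation.}
#'   \item{pca}{`var_explained = 0.9` (components kept).}
#' }
#'
#' @param name detector name.
#' @param ... hyperparameter overrides.
#' @param seed integer seed for any randomness in fitting.
#' @return an object of class `ad_spec`.
#' @export
ad_spec <- function(name, ..., seed = 0L) {
  native <- c("iforest", "hbos", "ecod", "knn", "gmm", "pca")
  is_adapter <- grepl("^adapter:", name)
  if (!is_adapter && !name %in% native) {
    stop("unknown detector '", name, "'; native detectors: ",
         paste(native, collapse = ", "), call. = FALSE)
  }
  params <- list(...)
  defaults <- switch(
    if (is_adapter) "adapter" else name,
    iforest = list(n_trees = 100L, psi = 256L),
    hbos = list(n_bins = NULL),
    ecod = list(),
    knn = list(k = 5L),
    gmm = list(n_components = 1L, ridge = 1e-6),
    pca = list(var_explained = 0.9),
    adapter = list()
  )
  unknown <- setdiff(names(params), c(names(defaults), if (is_adapter) names(params)))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", name, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "ad_spec")
}

#' Fit an anomaly scorer on a normal-only training matrix
#'
#' @param spec an [ad_spec()].
#' @param x numeric training matrix (rows = normal instances), no missing
#'   values.
#' @return a fitted model of class `c("ad_<name>", "ad_model")`; scoring it
#'   returns higher values for more anomalous rows.
#' @export
ad_fit <- function(spec, x) {
  stopifnot(inherits(spec, "ad_spec"))
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("training matrix is empty", call. = FALSE)
  if (any(!is.finite(x))) stop("training matrix must be finite", call. = FALSE)
  if (grepl("^adapter:", spec$name)) return(adapter_fit(spec, x))
  fitter <- switch(spec$name,
    iforest = iforest_fit, hbos = hbos_fit, ecod = ecod_fit,
    knn = knn_fit, gmm = gmm_fit, pca = pca_fit
  )
  model <- fitter(spec, x)
  model$spec <- spec
  model$columns <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  model$n_train <- nrow(x)
  class(model) <- c(paste0("ad_", sub(":.*$", "", spec$name)), "ad_model")
  model
}

#' Score instances with a fitted anomaly model
#'
#' Higher scores indicate stronger deviation from the training (normal)
#' class, for every detector and adapter alike.
#'
#' @param model a fitted `ad_model`.
#' @param x numeric vector (one instance) or matrix with the training column
#'   count.
#' @return numeric score per row, all finite.
#' @export
ad_score <- function(model, x) {
  stopifnot(inherits(model, "ad_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$columns)) {
    stop("column mismatch: model was trained on ", length(model$columns),
         " columns, got ", ncol(x), call. = FALSE)
  }
  UseMethod("ad_score")
}

#' @export
ad_score.default <- function(model, x) {
  stop("no scoring method for class ", paste(class(model), collapse = "/"),
       call. = FALSE)
}

# ---- adapter registry ------------------------------------------------------

.adapter_registry <- new.env(parent = emptyenv())

#' Register an external detector behind the scorer contract
#'
#' Wraps an arbitrary `fit_fn(x, spec)` / `score_fn(state, x)` pair. The
#' caller must declare the score orientation; scorers whose convention is
#' "higher = more normal" are negated so the package-wide contract (higher =
#' more anomalous) always holds.
#'
#' @param name adapter name; addressed as `"adapter:<name>"` in [ad_spec()].
#' @param fit_fn function of (training matrix, spec) returning fitted state.
#' @param score_fn function of (state, matrix) returning one score per row.
#' @param orientation `"anomalous"` (higher score = more anomalous) or
#'   `"normal"` (inverted convention; output is negated).
#' @param overwrite replace an existing registration of the same name.
#' @return the adapter name, invisibly.
#' @export
register_adapter <- function(name, fit_fn, score_fn,
                             orientation = c("anomalous", "normal"),
                             overwrite = FALSE) {
  if (missing(orientation)) {
    stop("orientation must be declared explicitly for adapter '", name, "'",
         call. = FALSE)
  }
  orientation <- match.arg(orientation)
  if (!overwrite && exists(name, envir = .adapter_registry)) {
    stop("adapter '", name, "' is already registered", call. = FALSE)
  }
  assign(name, list(fit_fn = fit_fn, score_fn = score_fn,
                    orientation = orientation),
         envir = .adapter_registry)
  invisible(name)
}

#' List registered external adapters
#' @return character vector of adapter names.
#' @export
list_adapters <- function() ls(.adapter_registry)

adapter_fit <- function(spec, x) {
  key <- sub("^adapter:", "", spec$name)
  if (!exists(key, envir = .adapter_registry)) {
    stop("no adapter registered under '", key, "'", call. = FALSE)
  }
  entry <- get(key, envir = .adapter_registry)
  set.seed(spec$seed)
  state <- entry$fit_fn(x, spec)
  structure(
    list(state = state, entry = entry, spec = spec,
         columns = colnames(x) %||% paste0("V", seq_len(ncol(x))),
         n_train = nrow(x)),
    class = c("ad_adapter", "ad_model")
  )
}

#' @export
ad_score.ad_adapter <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  s <- as.numeric(model$entry$score_fn(model$state, as.matrix(x)))
  if (model$entry$orientation == "normal") s <- -s
  s
}
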