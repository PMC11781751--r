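#' Build an experiment configuration
#'
#' Assembles the whole pipeline configuration: input (a synthetic-cohort
#' config or a cohort CSV), the nested weight categories to evaluate, the
#' detector roster, cross-validation settings, preprocessing mode, and the
#' interpretation settings.
#'
#' @param synth a [synth_config()] to generate the input cohort, or `NULL`
#'   when reading from file.
#' @param cohort_csv path to a cohort CSV (ignored when `synth` is given).
#' @param categories subset of `c("lbw", "vlbw", "elbw")`.
#' @param detectors character vector of detector names, or a list of
#'   [ad_spec()]-style lists `list(name =, params =)`.
#' @param repeats,folds cross-validation layout (default 2 x 5).
#' @param mode preprocessing mode: `"global"` (transform fitted on the full
#'   cohort) or `"fold-safe"` (refit per fold on training-normal rows).
#' @param interpret_method `"perturb"`, `"diffi"` or `"both"`.
#' @param interpret_detector detector whose model is explained (must be
#'   `"iforest"` for the depth-based method).
#' @param baseline_provenance `"training-normal"` or `"test-set"`.
#' @param outlier_mode `"label"` or `"topk"`; `outlier_k` for the latter.
#' @param seed top-level seed; every stage derives its own stream from it.
#' @param outdir output directory.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              cohort_csv = NULL,
                              categories = c("lbw", "vlbw", "elbw"),
                              detectors = c("iforest", "hbos", "ecod",
                                            "knn", "gmm", "pca"),
                              repeats = 2L, folds = 5L,
                              mode = c("global", "fold-safe"),
                              interpret_method = c("both", "perturb", "diffi"),
                              interpret_detector = "iforest",
                              baseline_provenance = "training-normal",
                              outlier_mode = "label", outlier_k = 50L,
                              seed = 0L, outdir = tempfile("lbwad_run_")) {
  mode <- match.arg(mode)
  interpret_method <- match.arg(interpret_method)
  categories <- match.arg(categories, c("lbw", "vlbw", "elbw"),
                          several.ok = TRUE)
  if (length(detectors) == 0) stop("at least one detector required", call. = FALSE)
  structure(
    list(synth = synth, cohort_csv = cohort_csv, categories = categories,
         detectors = detectors, repeats = as.integer(repeats),
         folds = as.integer(folds), mode = mode,
         interpret_method = interpret_method,
         interpret_detector = interpret_detector,
         baseline_provenance = baseline_provenance,
         outlier_mode = outlier_mode, outlier_k = as.integer(outlier_k),
         seed = as.integer(seed), outdir = outdir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   [experiment_config()], with `synth` given as a nested mapping of
#'   [synth_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    y$synth$prevalence <- unlist(y$synth$prevalence)
    y$synth <- do.call(synth_config, y$synth)
  }
  do.call(experiment_config, y)
}

resolve_specs <- function(detectors, seed) {
  lapply(detectors, function(d) {
    if (is.character(d)) return(ad_spec(d, seed = seed))
    do.call(ad_spec, c(list(name = d$name), d$params %||% list(),
                       list(seed = seed)))
  })
}

#' Run the full detection-and-attribution experiment
#'
#' End-to-end pipeline: obtain the cohort (generate or read), derive the
#' nested weight-category labels, preprocess, run the normal-only repeated
#' cross-validation for every configured detector and category, compute the
#' cross-detector F-tests on the fold-level AUCROC and AUCPR values, then
#' fit the interpretation detector on all normal rows and aggregate
#' per-instance attributions over the selected outlier points. All tabular
#' artifacts are written under `config$outdir` and are byte-identical across
#' reruns with the same seed.
#'
#' @param config an [experiment_config()].
#' @return (invisibly) a list with `reports`, `ftests`, `mean_ranks` and
#'   the output directory.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", sprintf(...), "\n",
        file = log_path, append = TRUE)
  }

  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$synth)) {
    sc <- config$synth
    sc$seed <- stage_seed(config$seed, 100)
    gen <- generate_cohort(sc)
    cohort <- gen$cohort
    write_cohort(cohort, gen$truth, file.path(config$outdir, "cohort.csv"))
    logf("generated synthetic cohort: %d rows", nrow(cohort))
  } else {
    cohort <- read_cohort(config$cohort_csv)
    logf("read cohort %s: %d rows", config$cohort_csv, nrow(cohort))
  }
  cohort <- drop_invalid_weight(cohort)
  labels_all <- category_labels(cohort$weight)
  schema <- infer_schema(cohort)

  transform <- preprocess_fit(cohort, schema)
  fm <- preprocess_apply(transform, cohort)
  write_transform(transform, file.path(config$outdir, "transform.json"))
  utils::write.csv(data.frame(fm$x, check.names = FALSE),
                   file.path(config$outdir, "matrix.csv"), row.names = FALSE)
  logf("preprocessed: %d encoded columns (%s mode for CV)",
       ncol(fm$x), config$mode)

  specs <- resolve_specs(config$detectors, stage_seed(config$seed, 200))
  reports <- list()
  ftests <- list()
  for (ci in seq_along(config$categories)) {
    cat_name <- config$categories[ci]
    labels <- labels_all[[cat_name]]
    plan <- make_folds(labels, config$repeats, config$folds,
                       seed = stage_seed(config$seed, 300 + ci),
                       category = cat_name)
    report <- if (config$mode == "global") {
      cross_validate(fm$x, labels, specs, plan)
    } else {
      cross_validate_cohort(cohort, schema, labels, specs, plan,
                            mode = "fold-safe")
    }
    reports[[cat_name]] <- report
    write_eval_report(report, file.path(config$outdir,
                                        paste0("metrics_", cat_name, ".csv")),
                      category = cat_name)
    utils::write.csv(report$summary,
                     file.path(config$outdir,
                               paste0("summary_", cat_name, ".csv")),
                     row.names = FALSE)
    for (metric in c("aucroc", "aucpr")) {
      groups <- split(report$folds[[metric]], report$folds$detector)
      ft <- anova_f(groups)
      ftests[[paste(cat_name, metric, sep = "_")]] <- data.frame(
        category = cat_name, metric = metric, f = ft$statistic,
        p = ft$p_value, df1 = ft$df[["df1"]], df2 = ft$df[["df2"]],
        stringsAsFactors = FALSE
      )
    }
    logf("category %s: evaluated %d detectors over %dx%d folds", cat_name,
         length(specs), config$repeats, config$folds)
  }
  ftest_df <- do.call(rbind, c(ftests, list(make.row.names = FALSE)))
  utils::write.csv(ftest_df, file.path(config$outdir, "ftests.csv"),
                   row.names = FALSE)

  # interpretation: fit the chosen detector on all normal rows of each
  # category and aggregate attributions over its outlier points
  mean_ranks <- list()
  int_spec <- resolve_specs(list(config$interpret_detector),
                            stage_seed(config$seed, 400))[[1]]
  methods <- if (config$interpret_method == "both") c("perturb", "diffi") else config$interpret_method
  for (cat_name in config$categories) {
    labels <- labels_all[[cat_name]]
    normal_rows <- which(labels == 0)
    model <- ad_fit(int_spec, fm$x[normal_rows, , drop = FALSE])
    scores <- ad_score(model, fm$x)
    bl_rows <- if (config$baseline_provenance == "training-normal") normal_rows else NULL
    baseline <- baseline_means(fm$x, rows = bl_rows,
                               provenance = config$baseline_provenance)
    ids <- select_outlier_points(labels = labels, scores = scores,
                                 mode = config$outlier_mode,
                                 k = config$outlier_k)
    for (method in methods) {
      attrs <- if (method == "perturb") {
        perturb_attribution(model, fm$x[ids, , drop = FALSE], baseline, fm$meta)
      } else {
        local_diffi(model, fm$x[ids, , drop = FALSE], baseline, fm$meta)
      }
      write_attributions(attrs,
                         file.path(config$outdir,
                                   paste0("attributions_", cat_name, "_",
                                          method, ".csv")),
                         instance_ids = ids)
      mr <- average_feature_ranks(attrs)
      mean_ranks[[paste(cat_name, method, sep = "_")]] <- mr
      utils::write.csv(mr,
                       file.path(config$outdir,
                                 paste0("mean_ranks_", cat_name, "_",
                                        method, ".csv")),
                       row.names = FALSE)
    }
    logf("category %s: attributions for %d outlier points", cat_name,
         length(ids))
  }

  resolved <- unclass(config)
  resolved$synth <- if (!is.null(config$synth)) unclass(config$synth)
  yaml::write_yaml(resolved, file.path(config$outdir, "resolved_config.yaml"))
  logf("done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(list(reports = reports, ftests = ftest_df,
                 mean_ranks = mean_ranks, outdir = config$outdir))
}
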