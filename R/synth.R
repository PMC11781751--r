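#' Default synthetic first-trimester feature schema
#'
#' Twenty-two mixed-type features emulating the shape of a first-trimester
#' antenatal record: 12 numeric, 6 binary (Yes/No) and 4 categorical with
#' 3-5 levels. Names are suggestive only; the marginal distributions are
#' simple parametric stand-ins, not calibrated obstetric distributions.
#'
#' @return a data.frame with columns `name`, `kind` and (for categoricals)
#'   a `levels` list-column; suitable as the `schema` argument of the
#'   preprocessing functions.
#' @export
default_schema <- function() {
  numeric_names <- c(
    "maternal_age", "bmi", "systolic_bp", "diastolic_bp", "hemoglobin",
    "fasting_glucose", "weight_gain_t1", "fundal_height", "serum_hcg",
    "papp_a", "tsh", "ferritin"
  )
  binary_names <- c(
    "smoking", "chronic_hypertension", "pregestational_diabetes",
    "prior_lbw", "multiple_gestation", "folate_supplement"
  )
  cat_names <- c("parity_class", "education", "bmi_class", "conception_mode")
  cat_levels <- list(
    c("multipara", "nullipara", "primipara"),
    c("none", "primary", "secondary", "tertiary"),
    c("normal", "obese", "overweight", "underweight"),
    c("art", "ovulation_induction", "spontaneous")
  )
  schema <- data.frame(
    name = c(numeric_names, binary_names, cat_names),
    kind = c(
      rep("numeric", length(numeric_names)),
      rep("binary", length(binary_names)),
      rep("categorical", length(cat_names))
    ),
    stringsAsFactors = FALSE
  )
  schema$levels <- c(
    rep(list(NULL), length(numeric_names) + length(binary_names)),
    cat_levels
  )
  schema
}

# Generation parameters for the default schema: marginal means/sds for the
# numeric block, Bernoulli rates for the binary block, level probabilities
# for the categorical block. Fixed constants of the generator.
synth_params <- function() {
  list(
    numeric_mean = c(
      maternal_age = 29, bmi = 26, systolic_bp = 112, diastolic_bp = 71,
      hemoglobin = 12.2, fasting_glucose = 4.8, weight_gain_t1 = 1.6,
      fundal_height = 12, serum_hcg = 95, papp_a = 2.9, tsh = 1.7,
      ferritin = 45
    ),
    numeric_sd = c(
      maternal_age = 5.5, bmi = 4.5, systolic_bp = 10, diastolic_bp = 8,
      hemoglobin = 1.1, fasting_glucose = 0.5, weight_gain_t1 = 0.9,
      fundal_height = 1.4, serum_hcg = 30, papp_a = 1.1, tsh = 0.8,
      ferritin = 20
    ),
    # direction of the anomalous mean shift for numeric features, in units
    # of one feature standard deviation
    numeric_dir = c(
      maternal_age = 1, bmi = -1, systolic_bp = 1, diastolic_bp = 1,
      hemoglobin = -1, fasting_glucose = 1, weight_gain_t1 = -1,
      fundal_height = -1, serum_hcg = -1, papp_a = -1, tsh = 1,
      ferritin = -1
    ),
    binary_p = c(
      smoking = 0.08, chronic_hypertension = 0.06,
      pregestational_diabetes = 0.1, prior_lbw = 0.12,
      multiple_gestation = 0.03, folate_supplement = 0.7
    ),
    # binary shift applied on the logit scale; negative for protective flags
    binary_dir = c(
      smoking = 1, chronic_hypertension = 1, pregestational_diabetes = 1,
      prior_lbw = 1, multiple_gestation = 1, folate_supplement = -1
    ),
    categorical_p = list(
      parity_class = c(multipara = 0.45, nullipara = 0.35, primipara = 0.20),
      education = c(none = 0.05, primary = 0.20, secondary = 0.40, tertiary = 0.35),
      bmi_class = c(normal = 0.45, obese = 0.18, overweight = 0.27, underweight = 0.10),
      conception_mode = c(art = 0.06, ovulation_induction = 0.09, spontaneous = 0.85)
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_samples number of pregnancies to simulate (default 3509).
#' @param prevalence named fractions `c(lbw=, vlbw=, elbw=)` of rows whose
#'   birth weight falls below 2500/1500/1000 g. Must be strictly nested
#'   (`elbw <= vlbw <= lbw`). Defaults `0.116 / 0.0128 / 0.0054`.
#' @param severity non-negative mean shift, in feature standard deviations,
#'   applied to the informative features of anomalous rows. Rows in deeper
#'   tiers receive a larger multiple of the shift (1x / 1.5x / 2x for
#'   LBW-only / VLBW-only / ELBW rows).
#' @param informative_features names of features carrying the anomaly signal;
#'   default picks 6 of the 22 schema features (4 numeric, 2 binary), leaving
#'   16 nuisance features.
#' @param missing_rate fraction of feature cells (never the weight column)
#'   set to missing completely at random.
#' @param seed integer seed; the full cohort is deterministic given the config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 3509,
                         prevalence = c(lbw = 0.116, vlbw = 0.0128, elbw = 0.0054),
                         severity = 1.5,
                         informative_features = c(
                           "bmi", "hemoglobin", "fundal_height", "papp_a",
                           "smoking", "chronic_hypertension"
                         ),
                         missing_rate = 0.05,
                         seed = 0L) {
  prevalence <- unlist(prevalence)
  if (!all(c("lbw", "vlbw", "elbw") %in% names(prevalence))) {
    names(prevalence) <- c("lbw", "vlbw", "elbw")[seq_along(prevalence)]
  }
  if (any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("prevalence fractions must lie in (0, 1)", call. = FALSE)
  }
  if (!(prevalence[["elbw"]] <= prevalence[["vlbw"]] &&
        prevalence[["vlbw"]] <= prevalence[["lbw"]])) {
    stop("prevalences must respect nesting: elbw <= vlbw <= lbw", call. = FALSE)
  }
  if (severity < 0) stop("severity must be non-negative", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  schema <- default_schema()
  bad <- setdiff(informative_features, schema$name)
  if (length(bad)) {
    stop("unknown informative features: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_samples * prevalence[["elbw"]] < 1) {
    warning("n_samples * elbw prevalence < 1; expected positive count below one")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      prevalence = prevalence[c("lbw", "vlbw", "elbw")],
      severity = severity,
      informative_features = informative_features,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic maternal cohort with nested birth-weight labels
#'
#' Each row carries a latent standard-normal risk score. Birth weight is a
#' strictly decreasing piecewise map of that risk whose knots sit at the
#' normal quantiles of the configured prevalences, so that thresholding the
#' weight at 2500/1500/1000 g recovers approximately those fractions and the
#' three label vectors are nested by construction. Informative features of
#' anomalous rows are mean-shifted (numeric), logit-shifted (binary) or
#' re-tilted (categorical) by `severity`, scaled up for the deeper tiers.
#'
#' @param config a [synth_config()].
#' @return a list with components `cohort` (data.frame: 22 feature columns
#'   plus `weight` in grams) and `truth` (list: nested label vectors `lbw`,
#'   `vlbw`, `elbw`; `latent_risk`; `informative_features`; the echoed
#'   `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  schema <- default_schema()
  pars <- synth_params()
  n <- config$n_samples
  set.seed(config$seed)

  risk <- stats::rnorm(n)
  weight <- risk_to_weight(risk, config$prevalence)

  lbw <- as.integer(weight < 2500)
  vlbw <- as.integer(weight < 1500)
  elbw <- as.integer(weight < 1000)
  # tier multiplier: deeper (more extreme) tiers get larger feature shifts
  mult <- lbw * 1 + vlbw * 0.5 + elbw * 0.5  # 0 / 1 / 1.5 / 2
  shift <- config$severity * mult

  cohort <- data.frame(row.names = seq_len(n))
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    kind <- schema$kind[j]
    informative <- nm %in% config$informative_features
    if (kind == "numeric") {
      mu <- pars$numeric_mean[[nm]]
      sdev <- pars$numeric_sd[[nm]]
      x <- stats::rnorm(n, mu, sdev)
      if (informative) x <- x + pars$numeric_dir[[nm]] * shift * sdev
      cohort[[nm]] <- x
    } else if (kind == "binary") {
      p0 <- pars$binary_p[[nm]]
      p <- if (informative) {
        stats::plogis(stats::qlogis(p0) + pars$binary_dir[[nm]] * shift)
      } else rep(p0, n)
      cohort[[nm]] <- ifelse(stats::runif(n) < p, "Yes", "No")
    } else {
      p0 <- pars$categorical_p[[nm]]
      lv <- names(p0)
      if (informative) {
        # tilt mass toward the last level proportionally to the shift
        w <- outer(shift, seq_along(lv) - 1, function(s, i) i / (length(lv) - 1) * s)
        probs <- exp(log(matrix(p0, n, length(lv), byrow = TRUE)) + w)
        probs <- probs / rowSums(probs)
        u <- stats::runif(n)
        idx <- rowSums(u > t(apply(probs, 1, cumsum))) + 1L
        cohort[[nm]] <- lv[pmin(idx, length(lv))]
      } else {
        cohort[[nm]] <- sample(lv, n, replace = TRUE, prob = p0)
      }
    }
  }
  cohort$weight <- weight

  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = stage_seed(config$seed, 1))
  }

  truth <- list(
    lbw = lbw, vlbw = vlbw, elbw = elbw,
    latent_risk = risk,
    informative_features = config$informative_features,
    config = config
  )
  list(cohort = cohort, truth = truth)
}

# Strictly decreasing piecewise map from latent risk to birth weight (grams).
# Knots at the normal quantiles of the three prevalences pin the thresholds:
# weight < 2500 iff risk > qnorm(1 - p_lbw), and likewise for 1500/1000 g.
risk_to_weight <- function(risk, prevalence) {
  t_lbw <- stats::qnorm(1 - prevalence[["lbw"]])
  t_vlbw <- stats::qnorm(1 - prevalence[["vlbw"]])
  t_elbw <- stats::qnorm(1 - prevalence[["elbw"]])
  w <- numeric(length(risk))
  lo <- risk <= t_lbw
  w[lo] <- 2500 + 600 * (t_lbw - risk[lo])
  mid <- risk > t_lbw & risk <= t_vlbw
  w[mid] <- 2500 - 1000 * (risk[mid] - t_lbw) / (t_vlbw - t_lbw)
  deep <- risk > t_vlbw & risk <= t_elbw
  w[deep] <- 1500 - 500 * (risk[deep] - t_vlbw) / (t_elbw - t_vlbw)
  xtr <- risk > t_elbw
  w[xtr] <- 1000 * exp(-0.5 * (risk[xtr] - t_elbw))
  round(w, 1)
}

#' Set feature cells missing completely at random
#'
#' Masks an expected fraction `rate` of feature cells; the `weight` column is
#' never touched. Deterministic under `seed`.
#'
#' @param cohort cohort data.frame containing a `weight` column.
#' @param rate fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return the cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(cohort, rate, seed = 0L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  feature_cols <- setdiff(names(cohort), "weight")
  set.seed(as.integer(seed))
  for (nm in feature_cols) {
    mask <- stats::runif(nrow(cohort)) < rate
    cohort[[nm]][mask] <- NA
  }
  cohort
}

#' Write a cohort CSV with its ground-truth JSON sidecar
#'
#' @param cohort cohort data.frame.
#' @param truth ground-truth list from [generate_cohort()] (or `NULL`).
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, truth, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    side <- truth
    side$config <- unclass(side$config)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path; empty cells become `NA`.
#' @return a cohort data.frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
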