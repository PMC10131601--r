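# Numeric design matrix for the propensity learners. Factor covariates are
# expanded to indicators; missing pharmacy PUPM gets an explicit
# missing-indicator column (availability is itself a matching segment, so
# imputation would blur it) and a zero fill.
encode_features <- function(features, schema = NULL) {
  need <- c("age", "sex", "location", "plan_type", "pharmacy_data_available",
            "comm_receptivity", "care_management", "member_advocacy",
            "chronic_count", "risk_score", "inpatient_visits_12m",
            "ed_visits_12m", "diag_code_count_12m", "procedure_count_12m",
            "pre_medical_pupm", "pre_pharmacy_pupm")
  absent <- setdiff(need, names(features))
  check_that(length(absent) == 0,
             paste0("feature schema mismatch; missing: ",
                    paste(absent, collapse = ", ")),
             class = "pupmatch_schema_error")
  x <- tibble::tibble(
    age = as.numeric(features$age),
    sex_female = as.numeric(features$sex == "female"),
    sex_nonbinary = as.numeric(features$sex == "nonbinary"),
    loc_suburban = as.numeric(features$location == "suburban"),
    loc_rural = as.numeric(features$location == "rural"),
    plan_self_insured = as.numeric(features$plan_type == "self_insured"),
    pharmacy_data_available = as.numeric(features$pharmacy_data_available),
    comm_receptivity = as.numeric(features$comm_receptivity),
    care_management = as.numeric(features$care_management),
    member_advocacy = as.numeric(features$member_advocacy),
    chronic_count = as.numeric(features$chronic_count),
    log_risk_score = log(pmax(as.numeric(features$risk_score), 1e-12)),
    inpatient_visits_12m = as.numeric(features$inpatient_visits_12m),
    ed_visits_12m = as.numeric(features$ed_visits_12m),
    diag_code_count_12m = as.numeric(features$diag_code_count_12m),
    procedure_count_12m = as.numeric(features$procedure_count_12m),
    pre_medical_pupm = as.numeric(features$pre_medical_pupm),
    pre_pharmacy_pupm = dplyr::coalesce(as.numeric(features$pre_pharmacy_pupm), 0),
    pharmacy_pupm_missing = as.numeric(is.na(features$pre_pharmacy_pupm))
  )
  m <- as.matrix(x)
  if (!is.null(schema)) {
    missing <- setdiff(schema, colnames(m))
    check_that(length(missing) == 0,
               paste0("feature schema mismatch; missing: ", paste(missing, collapse = ", ")),
               class = "pupmatch_schema_error")
    m <- m[, schema, drop = FALSE]
  }
  m
}

#' Fit an ensemble propensity model for enlistment
#'
#' Trains two heterogeneous base learners — a linear-logistic model
#' (`stats::glm`, binomial) and a gradient-boosted tree model
#' ([xgboost::xgb.train()]) — on anchored feature vectors, and predicts the
#' probability of enlistment as the arithmetic mean of the base-learner
#' probabilities. Fitting and scoring are deterministic for a fixed seed
#' (single-threaded boosting, no subsampling).
#'
#' @param features Feature tibble from [build_features()].
#' @param labels Logical (or 0/1) enlistment labels, one per row.
#' @param seed Integer seed for the boosted learner.
#' @param learners Character subset of `c("logistic", "xgboost")`, >= 1.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return An object of class `pupm_propensity`.
#' @export
fit_propensity <- function(features, labels, seed = 1L,
                           learners = c("logistic", "xgboost"),
                           nrounds = 50, max_depth = 3, eta = 0.3) {
  labels <- as.logical(labels)
  check_that(length(labels) == nrow(features), "one label per feature row required")
  check_that(dplyr::n_distinct(labels) >= 2,
             "cannot fit a propensity model on single-class labels",
             class = "pupmatch_fit_error")
  learners <- match.arg(learners, several.ok = TRUE)
  x <- encode_features(features)
  y <- as.numeric(labels)
  fits <- list()
  if ("logistic" %in% learners) {
    glm_fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, x), y, family = stats::binomial())
    )
    coefs <- glm_fit$coefficients
    coefs[is.na(coefs)] <- 0
    fits$logistic <- list(coefficients = coefs)
  }
  if ("xgboost" %in% learners) {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    fits$xgboost <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed,
                    tree_method = "hist", max_bin = 64),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
  }
  out <- list(
    base_learners = fits,
    feature_schema = colnames(x),
    training_meta = list(
      n_treated = sum(labels), n_comparison = sum(!labels), seed = seed,
      mean_score = NA_real_, auc = NA_real_
    )
  )
  class(out) <- "pupm_propensity"
  s <- score_propensity(out, features)
  out$training_meta$mean_score <- mean(s)
  out$training_meta$auc <- auc_rank(s, labels)
  out
}

#' Score members with a fitted propensity model
#'
#' Returns the ensemble enlistment probability (mean of base-learner
#' probabilities) per feature row, order-preserving, clipped to
#' `[1e-6, 1 - 1e-6]` so logits stay finite for matching distances.
#'
#' @param model A `pupm_propensity`.
#' @param features Feature tibble with the training schema's columns.
#' @return Numeric vector of scores in (0, 1).
#' @export
score_propensity <- function(model, features) {
  x <- encode_features(features, schema = model$feature_schema)
  preds <- lapply(names(model$base_learners), function(nm) {
    fit <- model$base_learners[[nm]]
    if (nm == "logistic") {
      as.numeric(stats::plogis(cbind(1, x) %*% fit$coefficients))
    } else {
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x)))
    }
  })
  clip_prob(Reduce(`+`, preds) / length(preds))
}

#' @rdname score_propensity
#' @param object A `pupm_propensity`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @export
predict.pupm_propensity <- function(object, newdata, ...) {
  score_propensity(object, newdata)
}

#' @method print pupm_propensity
#' @export
print.pupm_propensity <- function(x, ...) {
  cat("<pupm_propensity> ensemble of", length(x$base_learners), "learners (",
      paste(names(x$base_learners), collapse = " + "), ")\n")
  cat("  trained on", x$training_meta$n_treated, "treated /",
      x$training_meta$n_comparison, "comparison; training AUC",
      round(x$training_meta$auc, 3), "\n")
  invisible(x)
}

#' Tidy a fitted propensity model
#'
#' One row per (learner, term): logistic coefficients and boosted-tree gain
#' importance, in broom style.
#'
#' @param x A `pupm_propensity`.
#' @param ... Unused.
#' @return A tibble with columns `learner`, `term`, `estimate`.
#' @export
tidy.pupm_propensity <- function(x, ...) {
  out <- list()
  if (!is.null(x$base_learners$logistic)) {
    co <- x$base_learners$logistic$coefficients
    out$logistic <- tibble::tibble(learner = "logistic", term = names(co),
                                   estimate = as.numeric(co))
  }
  if (!is.null(x$base_learners$xgboost)) {
    imp <- xgboost::xgb.importance(model = x$base_learners$xgboost)
    out$xgboost <- tibble::tibble(learner = "xgboost", term = imp$Feature,
                                  estimate = imp$Gain)
  }
  dplyr::bind_rows(out)
}

#' Glance at a fitted propensity model
#'
#' @param x A `pupm_propensity`.
#' @param ... Unused.
#' @return One-row tibble: group sizes, training-data mean score (which
#'   should approximate the treated fraction — calibration in the large),
#'   training AUC, learner count.
#' @export
glance.pupm_propensity <- function(x, ...) {
  meta <- x$training_meta
  tibble::tibble(
    n_treated = meta$n_treated, n_comparison = meta$n_comparison,
    treated_fraction = meta$n_treated / (meta$n_treated + meta$n_comparison),
    mean_score = meta$mean_score, auc = meta$auc,
    n_learners = length(x$base_learners)
  )
}
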