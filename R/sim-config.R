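#' Default monthly spend model
#'
#' One row per cost category: the probability a member-month has no spend in
#' that category (`p_zero`), and the log-scale mean/sd of the claim amount in
#' USD when spend occurs. Amounts are drawn lognormal, then scaled by the
#' member's spend multiplier (`risk_score`). Parameters are synthetic
#' stand-ins shaped to give a right-skewed, zero-heavy monthly spend
#' distribution with a typical total around $450-600 per member per month,
#' with utilization rates for emergency-department (ED) and inpatient care of
#' roughly 0.18 and 0.16 visits per member-year.
#'
#' @param ed_rate Expected ED visits per member-year (sets `p_zero` for ED).
#' @param inpatient_rate Expected inpatient admissions per member-year.
#' @return A tibble with columns `category`, `p_zero`, `meanlog`, `sdlog`.
#' @export
default_spend_model <- function(ed_rate = 0.18, inpatient_rate = 0.16) {
  tibble::tribble(
    ~category,       ~p_zero,                 ~meanlog,    ~sdlog,
    "ED",            1 - ed_rate / 12,        log(900),    0.9,
    "specialist",    0.85,                    log(220),    0.7,
    "mental_health", 0.96,                    log(180),    0.6,
    "inpatient",     1 - inpatient_rate / 12, log(6000),   0.8,
    "radiology",     0.95,                    log(350),    0.8,
    "primary_care",  0.88,                    log(140),    0.5,
    "ambulatory",    0.92,                    log(400),    1.0,
    "laboratory",    0.90,                    log(80),     0.8,
    "home_health",   0.995,                   log(800),    0.9,
    "medical_rx",    0.97,                    log(600),    1.2,
    "total_rx",      0.45,                    log(120),    1.1
  )
}

#' Cost categories recognized by the pipeline
#'
#' `total_rx` is the pharmacy benefit; all other categories are medical.
#' @return Character vector of category names.
#' @export
spend_categories <- function() default_spend_model()$category

#' Pharmacy cost categories
#' @return Character vector (currently just `total_rx`).
#' @export
pharmacy_categories <- function() "total_rx"

#' Configuration for the synthetic claims generator
#'
#' Bundles every data-generating assumption: the population size and study
#' calendar, the self-selection (enrollment) logit, the zero-inflated
#' lognormal monthly spend model, and the injectable post-enlistment
#' treatment effect.
#'
#' Selection covariates entering the enrollment logit, with the coefficient
#' names used in `selection_coefs`:
#' * `intercept` — 1.
#' * `age` — `(age - 40) / 10`.
#' * `sex` — indicator of female.
#' * `chronic_count` — number of chronic conditions.
#' * `baseline_spend` — `log(risk_score)`, the member's log expected-spend
#'   multiplier. `risk_score = exp(z + chronic_log_mult * chronic_count)`
#'   with `z ~ Normal(0, spend_sd_log)` is the synthetic stand-in for a
#'   predicted-use score and *is* the member's true spend scale, so selection
#'   on baseline spend is selection on an observable matching feature.
#' * `comm_receptivity` — indicator of communication receptivity.
#'
#' @param n_members Number of members to simulate.
#' @param n_months Study calendar length in months (0-based month indices
#'   `0 .. n_months - 1`). Must be >= 24 to leave room for a 12-month pre
#'   window and a >= 7-month post window.
#' @param enroll_window Inclusive month-index range in which enlistment can
#'   occur. Defaults to `c(12, n_months - 8)` so every enrolled member has 12
#'   observable pre months and >= 7 post months.
#' @param selection_coefs Named numeric coefficients of the enrollment logit
#'   (see Details). Defaults emulate self-selection of younger, female,
#'   less-chronic, lower-spend, communication-receptive members.
#' @param treatment_effect_pupm Additive expected change, USD per user per
#'   month (typically negative), applied to impactable spend in enrolled
#'   members' post-enlistment months.
#' @param spend_model Tibble from [default_spend_model()] (or same shape).
#' @param chronic_prevalence Target marginal probability of >= 1 chronic
#'   condition; chronic counts are Poisson with
#'   `lambda = -log(1 - chronic_prevalence)`.
#' @param chronic_log_mult Log-scale spend multiplier per chronic condition.
#' @param spend_sd_log SD of the member-level log spend multiplier `z`.
#' @param occ_chronic_coef Chronic-count scaling of ED/inpatient occurrence
#'   intensity (Poisson-thinning multiplier `exp(coef * chronic_count)`).
#' @param ed_rate Expected ED visits per member-year.
#' @param inpatient_rate Expected inpatient admissions per member-year.
#' @param nonimpactable_rate Probability a claim line is flagged
#'   non-impactable.
#' @param pregnancy_rate Probability a claim line of a female member aged
#'   18-45 is flagged pregnancy-related.
#' @param pharmacy_share Probability a member has pharmacy data available
#'   (a data-sharing agreement); members without it emit no `total_rx` lines.
#' @param sex_probs,location_probs,race_probs,plan_probs Named sampling
#'   probabilities for the categorical demographics.
#' @param comm_rate Probability of communication receptivity.
#' @param seed Integer seed; fixed seed gives bitwise-reproducible output.
#' @return A list with class `pupm_sim_config`.
#' @export
sim_config <- function(n_members,
                       n_months = 30,
                       enroll_window = NULL,
                       selection_coefs = c(
                         intercept = -2.2, age = -0.25, sex = 0.3,
                         chronic_count = -0.35, baseline_spend = -0.5,
                         comm_receptivity = 0.5
                       ),
                       treatment_effect_pupm = -10,
                       spend_model = NULL,
                       chronic_prevalence = 0.36,
                       chronic_log_mult = 0.25,
                       spend_sd_log = 0.6,
                       occ_chronic_coef = 0.2,
                       ed_rate = 0.18,
                       inpatient_rate = 0.16,
                       nonimpactable_rate = 0.08,
                       pregnancy_rate = 0.02,
                       pharmacy_share = 0.7,
                       sex_probs = c(male = 0.4789, female = 0.5210, nonbinary = 1e-04),
                       location_probs = c(urban = 0.3978, suburban = 0.2427, rural = 0.3595),
                       race_probs = c(
                         white = 0.3143, missing = 0.3921, unanswered = 0.1062,
                         multiple = 0.0461, black = 0.0451, asian = 0.0430,
                         unknown = 0.0349, other = 0.0145,
                         alaska_native_american_indian = 0.0027,
                         native_hawaiian_pacific_islander = 0.0012
                       ),
                       plan_probs = c(fully_insured = 0.5, self_insured = 0.5),
                       comm_rate = 0.6,
                       seed = 1L) {
  if (is.null(spend_model)) {
    spend_model <- default_spend_model(ed_rate = ed_rate, inpatient_rate = inpatient_rate)
  }
  cfg <- list(
    n_members = as.integer(n_members), n_months = as.integer(n_months),
    enroll_window = if (is.null(enroll_window)) c(12L, as.integer(n_months) - 8L) else as.integer(enroll_window),
    selection_coefs = selection_coefs,
    treatment_effect_pupm = treatment_effect_pupm,
    spend_model = spend_model,
    chronic_prevalence = chronic_prevalence,
    chronic_lambda = -log(1 - chronic_prevalence),
    chronic_log_mult = chronic_log_mult,
    spend_sd_log = spend_sd_log,
    occ_chronic_coef = occ_chronic_coef,
    ed_rate = ed_rate, inpatient_rate = inpatient_rate,
    nonimpactable_rate = nonimpactable_rate,
    pregnancy_rate = pregnancy_rate,
    pharmacy_share = pharmacy_share,
    sex_probs = sex_probs, location_probs = location_probs,
    race_probs = race_probs, plan_probs = plan_probs,
    comm_rate = comm_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "pupm_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    rlang::abort(
      paste0("invalid sim_config field `", field, "`: ", why),
      class = "pupmatch_config_error"
    )
  }
  if (!isTRUE(cfg$n_members >= 1)) bad("n_members", "must be a positive integer")
  if (!isTRUE(cfg$n_months >= 24)) {
    bad("n_months", "must be >= 24 (12 pre months plus >= 7 post months)")
  }
  ew <- cfg$enroll_window
  if (length(ew) != 2 || ew[1] > ew[2]) bad("enroll_window", "must be an inclusive lo <= hi range")
  if (ew[1] < 12 || ew[2] > cfg$n_months - 8) {
    bad("enroll_window", "must lie within [12, n_months - 8] so pre/post windows fit")
  }
  need <- c("intercept", "age", "sex", "chronic_count", "baseline_spend", "comm_receptivity")
  if (!all(need %in% names(cfg$selection_coefs))) {
    bad("selection_coefs", paste0("must name ", paste(need, collapse = ", ")))
  }
  sm <- cfg$spend_model
  if (!all(c("category", "p_zero", "meanlog", "sdlog") %in% names(sm))) {
    bad("spend_model", "needs columns category, p_zero, meanlog, sdlog")
  }
  if (any(sm$p_zero < 0 | sm$p_zero > 1)) bad("spend_model", "p_zero must be in [0, 1]")
  if (any(sm$sdlog <= 0)) bad("spend_model", "sdlog must be > 0")
  if (!isTRUE(cfg$chronic_prevalence >= 0 && cfg$chronic_prevalence < 1)) {
    bad("chronic_prevalence", "must be in [0, 1)")
  }
  for (f in c("nonimpactable_rate", "pregnancy_rate", "pharmacy_share", "comm_rate")) {
    if (!isTRUE(cfg[[f]] >= 0 && cfg[[f]] <= 1)) bad(f, "must be a probability in [0, 1]")
  }
  if (!isTRUE(cfg$spend_sd_log > 0)) bad("spend_sd_log", "must be > 0")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields in the YAML override [sim_config()] defaults; `n_members`
#' is required.
#'
#' @param path Path to a YAML file.
#' @return A `pupm_sim_config`.
#' @export
read_sim_config <- function(path) {
  rlang::check_installed("yaml")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$selection_coefs)) raw$selection_coefs <- unlist(raw$selection_coefs)
  for (f in c("sex_probs", "location_probs", "race_probs", "plan_probs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$spend_model)) raw$spend_model <- tibble::as_tibble(raw$spend_model)
  do.call(sim_config, raw)
}

#' @method print pupm_sim_config
#' @export
print.pupm_sim_config <- function(x, ...) {
  cat("<pupm_sim_config>\n")
  cat("  members:", x$n_members, " months:", x$n_months,
      " enroll window: [", x$enroll_window[1], ",", x$enroll_window[2], "]\n")
  cat("  treatment effect:", x$treatment_effect_pupm, "USD PUPM  seed:", x$seed, "\n")
  invisible(x)
}
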