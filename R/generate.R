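#' Generate a synthetic member roster
#'
#' Draws `n_members` plan members with demographics, plan attributes, chronic
#' conditions, a predicted-use style `risk_score` (the member's true expected
#' spend multiplier), and self-selected enlistment: each member enrolls with
#' probability `sigmoid(selection_coefs . covariates)` (see [sim_config()]
#' for the covariate coding). Enrolled members receive an enlistment month
#' uniform over the admissible part of `enroll_window`, guaranteeing 12
#' observable pre months and >= 7 post months.
#'
#' Output is bitwise-reproducible for a fixed config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A tibble of members, one row per member (see field list in the
#'   package vignette): `member_id`, `age`, `sex`, `race`, `location`,
#'   `plan_type`, `pharmacy_data_available`, `comm_receptivity`,
#'   `care_management`, `member_advocacy`, `chronic_count`, `risk_score`,
#'   `enrolled`, `enroll_month` (NA when not enrolled), `eligibility_start`,
#'   `eligibility_end`.
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_members
  set.seed(config$seed)

  age <- pmax(18L, as.integer(round(stats::rnorm(n, 42, 13))))
  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  race <- sample(names(config$race_probs), n, replace = TRUE, prob = config$race_probs)
  location <- sample(names(config$location_probs), n, replace = TRUE, prob = config$location_probs)
  plan_type <- sample(names(config$plan_probs), n, replace = TRUE, prob = config$plan_probs)
  pharmacy_data_available <- stats::runif(n) < config$pharmacy_share
  comm_receptivity <- stats::runif(n) < config$comm_rate
  chronic_count <- stats::rpois(n, config$chronic_lambda)
  z <- stats::rnorm(n, 0, config$spend_sd_log)
  risk_score <- exp(z + config$chronic_log_mult * chronic_count)
  care_management <- stats::runif(n) < stats::plogis(-2.2 + 0.45 * chronic_count)
  member_advocacy <- stats::runif(n) < stats::plogis(-2.9 + 0.40 * chronic_count)

  b <- config$selection_coefs
  eta <- b[["intercept"]] +
    b[["age"]] * (age - 40) / 10 +
    b[["sex"]] * (sex == "female") +
    b[["chronic_count"]] * chronic_count +
    b[["baseline_spend"]] * log(risk_score) +
    b[["comm_receptivity"]] * comm_receptivity
  enrolled <- stats::runif(n) < sigmoid(eta)

  eligibility_start <- rep(0L, n)
  eligibility_end <- rep(config$n_months - 1L, n)
  lo <- pmax(eligibility_start + 12L, config$enroll_window[1])
  hi <- pmin(eligibility_end - 7L, config$enroll_window[2])
  u <- stats::runif(n) # fixed RNG consumption regardless of enrollment
  enroll_month <- ifelse(enrolled & lo <= hi, lo + floor(u * (hi - lo + 1)), NA_integer_)
  enrolled <- enrolled & !is.na(enroll_month)

  tibble::tibble(
    member_id = sprintf("M%07d", seq_len(n)),
    age, sex, race, location, plan_type,
    pharmacy_data_available, comm_receptivity,
    care_management, member_advocacy,
    chronic_count = as.integer(chronic_count),
    risk_score,
    enrolled,
    enroll_month = as.integer(enroll_month),
    eligibility_start, eligibility_end
  )
}

#' Expected monthly spend implied by the generator
#'
#' Closed-form expectation of a member's monthly spend under a
#' [sim_config()]'s zero-inflated lognormal model:
#' `sum_c q_c(i) * exp(meanlog_c + sdlog_c^2 / 2) * risk_score_i`, restricted
#' to categories the member can emit (pharmacy only with a data-sharing
#' agreement) and, optionally, to the impactable (unflagged) share. Used to
#' calibrate the injected treatment effect so the expected PUPM change equals
#' `treatment_effect_pupm` exactly.
#'
#' @param members Roster from [generate_population()].
#' @param config The matching [sim_config()].
#' @param impactable_only If `TRUE`, scale by the probability a claim is
#'   neither non-impactable nor pregnancy-related.
#' @return Numeric vector, USD per month, one element per member.
#' @export
expected_monthly_spend <- function(members, config, impactable_only = TRUE) {
  sm <- config$spend_model
  occ_mult <- exp(config$occ_chronic_coef * members$chronic_count)
  total <- numeric(nrow(members))
  for (k in seq_len(nrow(sm))) {
    cat_k <- sm$category[k]
    q <- occurrence_prob(sm$p_zero[k], cat_k, occ_mult)
    e_amt <- exp(sm$meanlog[k] + sm$sdlog[k]^2 / 2) * members$risk_score
    avail <- if (cat_k %in% pharmacy_categories()) members$pharmacy_data_available else TRUE
    total <- total + q * e_amt * avail
  }
  if (impactable_only) {
    p_preg <- pregnancy_prob(members, config)
    total <- total * (1 - config$nonimpactable_rate) * (1 - p_preg)
  }
  total
}

# Member-month occurrence probability for a category; ED and inpatient
# occurrence intensity scales with chronic count (Poisson thinning).
occurrence_prob <- function(p_zero, category, occ_mult) {
  if (category %in% c("ED", "inpatient")) 1 - p_zero^occ_mult else rep(1 - p_zero, length(occ_mult))
}

pregnancy_prob <- function(members, config) {
  ifelse(members$sex == "female" & members$age <= 45, config$pregnancy_rate, 0)
}

#' Generate synthetic claim lines
#'
#' For every member-month within the eligibility span and every cost
#' category, spend occurs with probability `1 - p_zero` (ED/inpatient
#' occurrence scales with chronic count) and, when it occurs, the amount is
#' `exp(Normal(meanlog + log(risk_score), sdlog))` USD. Claim lines are
#' flagged non-impactable / pregnancy-related at the configured rates; ED
#' lines carry a diagnosis code sampled from the shipped ED probability
#' table. For enrolled members' post-enlistment months, impactable amounts
#' are scaled by a per-member factor calibrated against
#' [expected_monthly_spend()] so the expected change in observed impactable
#' spend equals `treatment_effect_pupm` USD per user per month.
#'
#' @param members Roster from [generate_population()] with the same config.
#' @param config The [sim_config()] used to generate `members`.
#' @return A tibble of claim lines: `member_id`, `month`, `category`,
#'   `amount_cents`, `nonimpactable`, `pregnancy_related`, `ed_diag_code`
#'   (NA except for ED lines), sorted by member, month, category.
#' @export
generate_claims <- function(members, config) {
  validate_sim_config(config)
  bad <- !is.na(members$enroll_month) & !members$enrolled
  check_that(!any(bad),
    paste0("members with enroll_month but enrolled = FALSE: ",
           paste(utils::head(members$member_id[bad], 5), collapse = ", ")),
    class = "pupmatch_data_error")

  set.seed(config$seed + 1L)
  n <- nrow(members)
  m <- config$n_months
  sm <- config$spend_model
  occ_mult <- exp(config$occ_chronic_coef * members$chronic_count)
  p_preg <- pregnancy_prob(members, config)

  # Treatment-effect calibration: scale impactable post-enlistment amounts.
  e_imp <- expected_monthly_spend(members, config, impactable_only = TRUE)
  r <- ifelse(members$enrolled, pmax(0, 1 + config$treatment_effect_pupm / pmax(e_imp, 1e-9)), 1)
  log_r <- log(pmax(r, 1e-12))

  months <- 0:(m - 1)
  in_span <- outer(members$eligibility_start, months, `<=`) &
    outer(members$eligibility_end, months, `>=`)
  post <- members$enrolled & !is.na(members$enroll_month)
  post_mat <- matrix(FALSE, n, m)
  if (any(post)) {
    post_mat[post, ] <- outer(members$enroll_month[post], months, `<`)
  }
  ed_codes <- ed_probability_table()$diag_code

  out <- vector("list", nrow(sm))
  for (k in seq_len(nrow(sm))) {
    cat_k <- sm$category[k]
    q <- occurrence_prob(sm$p_zero[k], cat_k, occ_mult)
    avail <- if (cat_k %in% pharmacy_categories()) members$pharmacy_data_available else rep(TRUE, n)
    occ <- matrix(stats::runif(n * m), n, m) < q # q recycles down columns
    occ <- occ & in_span & avail
    idx <- which(occ)
    if (length(idx) == 0) {
      out[[k]] <- NULL
      next
    }
    i <- (idx - 1L) %% n + 1L
    mo <- (idx - 1L) %/% n # 0-based month
    nonimpactable <- stats::runif(length(idx)) < config$nonimpactable_rate
    pregnancy_related <- stats::runif(length(idx)) < p_preg[i]
    diag_code <- if (cat_k == "ED") {
      sample(ed_codes, length(idx), replace = TRUE)
    } else {
      rep(NA_character_, length(idx))
    }
    impact <- !nonimpactable & !pregnancy_related
    shift <- ifelse(post_mat[idx] & impact, log_r[i], 0)
    amt <- exp(stats::rnorm(length(idx), sm$meanlog[k] + log(members$risk_score[i]) + shift, sm$sdlog[k]))
    out[[k]] <- tibble::tibble(
      member_id = members$member_id[i],
      month = as.integer(mo),
      category = cat_k,
      amount_cents = round(amt * 100),
      nonimpactable, pregnancy_related,
      ed_diag_code = diag_code
    )
  }
  claims <- dplyr::bind_rows(out)
  if (nrow(claims) == 0) {
    return(tibble::tibble(
      member_id = character(), month = integer(), category = character(),
      amount_cents = numeric(), nonimpactable = logical(),
      pregnancy_related = logical(), ed_diag_code = character()
    ))
  }
  dplyr::arrange(claims, .data$member_id, .data$month, .data$category)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [generate_population()] then [generate_claims()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `members` and `claims`.
#' @export
simulate_cohort <- function(config) {
  members <- generate_population(config)
  claims <- generate_claims(members, config)
  list(members = members, claims = claims)
}
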