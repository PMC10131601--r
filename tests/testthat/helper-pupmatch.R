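# Shared fixtures built in code.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# A small hand-built roster; defaults satisfy every eligibility rule.
make_member <- function(member_id = "A", age = 40L, sex = "female",
                        race = "white", location = "urban",
                        plan_type = "fully_insured",
                        pharmacy_data_available = TRUE,
                        comm_receptivity = TRUE, care_management = FALSE,
                        member_advocacy = FALSE, chronic_count = 0L,
                        risk_score = 1, enrolled = FALSE,
                        enroll_month = NA_integer_,
                        eligibility_start = 0L, eligibility_end = 29L) {
  tibble::tibble(
    member_id = member_id, age = age, sex = sex, race = race,
    location = location, plan_type = plan_type,
    pharmacy_data_available = pharmacy_data_available,
    comm_receptivity = comm_receptivity, care_management = care_management,
    member_advocacy = member_advocacy, chronic_count = chronic_count,
    risk_score = risk_score, enrolled = enrolled,
    enroll_month = as.integer(enroll_month),
    eligibility_start = eligibility_start, eligibility_end = eligibility_end
  )
}

make_claim <- function(member_id, month, category = "primary_care",
                       amount_usd = 100, nonimpactable = FALSE,
                       pregnancy_related = FALSE, ed_diag_code = NA_character_) {
  tibble::tibble(
    member_id = member_id, month = as.integer(month), category = category,
    amount_cents = round(amount_usd * 100), nonimpactable = nonimpactable,
    pregnancy_related = pregnancy_related, ed_diag_code = ed_diag_code
  )
}

empty_claims <- function() make_claim(character(), integer())[0, ]

# Minimal spend-summary rows for the effect estimators.
make_summaries <- function(changes, group) {
  tibble::tibble(
    member_id = paste0(substr(group, 1, 1), seq_along(changes)),
    group = group, anchor_month = 15L, pre_months = 12L, post_months = 12L,
    pre_pupm = 100, post_pupm = 100 + changes, change = changes
  )
}

# Independent brute-force implementation of the greedy segment-matching
# policy: treated in descending score (ties: ascending id); each scans every
# remaining control for the minimum |logit| distance (ties: lower score,
# then lower id). Used as the equivalence oracle.
brute_force_greedy <- function(treated, controls) {
  lg <- function(p) log(p / (1 - p))
  t_ord <- order(-treated$score, treated$member_id)
  avail <- rep(TRUE, nrow(controls))
  out <- list()
  for (ti in t_ord) {
    if (!any(avail)) break
    d <- abs(lg(treated$score[ti]) - lg(controls$score))
    d[!avail] <- Inf
    best <- which(d == min(d))
    if (!is.finite(min(d))) next
    if (length(best) > 1) {
      best <- best[order(controls$score[best], controls$member_id[best])][1]
    }
    avail[best] <- FALSE
    out[[length(out) + 1]] <- tibble::tibble(
      treated_id = treated$member_id[ti],
      control_id = controls$member_id[best],
      distance = d[best]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(treated_id = character(), control_id = character(),
                          distance = numeric()))
  }
  dplyr::bind_rows(out)
}

random_match_instance <- function(seed) {
  set.seed(seed)
  nt <- sample(1:8, 1)
  nc <- sample(1:8, 1)
  list(
    treated = tibble::tibble(member_id = sprintf("t%02d", 1:nt),
                             score = round(runif(nt, 0.05, 0.95), 3)),
    controls = tibble::tibble(member_id = sprintf("c%02d", 1:nc),
                              score = round(runif(nc, 0.05, 0.95), 3))
  )
}
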