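#' Apply study eligibility rules
#'
#' Keeps members who are adults (age >= 18) and continuously eligible over
#' the whole study evaluation period, and whose anchor leaves a full
#' 12-month pre window and at least 7 observable post months: enrolled
#' members must satisfy `enroll_month - 12 >= eligibility_start` and
#' `eligibility_end - enroll_month >= 7`; comparison-pool members must admit
#' at least one such anchor month. All bounds are inclusive. Exclusion
#' reasons are returned in the `exclusions` attribute and summarized in a
#' message. Idempotent.
#'
#' @param members Member roster tibble.
#' @param claims Unused; accepted so the filter can sit in a pipeline that
#'   carries both tables (eligibility here is span-based).
#' @param study_start,study_end Inclusive month-index bounds of the study
#'   evaluation period. Default to the widest span present in `members`.
#' @return Filtered tibble with an `exclusions` attribute
#'   (`member_id`, `reason`).
#' @export
filter_eligible <- function(members, claims = NULL, study_start = NULL, study_end = NULL) {
  if (nrow(members) == 0) {
    rlang::warn("filter_eligible(): empty member table")
    return(members)
  }
  if (is.null(study_start)) study_start <- min(members$eligibility_start)
  if (is.null(study_end)) study_end <- max(members$eligibility_end)

  reason <- rep(NA_character_, nrow(members))
  mark <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- mark(members$age < 18, "age < 18")
  reason <- mark(
    members$eligibility_start > study_start | members$eligibility_end < study_end,
    "not continuously eligible over study period"
  )
  enr <- members$enrolled
  reason <- mark(enr & (members$enroll_month - 12 < members$eligibility_start),
                 "fewer than 12 observable pre-enlistment months")
  reason <- mark(enr & (members$eligibility_end - members$enroll_month < 7),
                 "fewer than 7 observable post-enlistment months")
  reason <- mark(!enr & (members$eligibility_end - members$eligibility_start < 19),
                 "no anchor month admits 12 pre and 7 post months")

  keep <- is.na(reason)
  excl <- tibble::tibble(member_id = members$member_id[!keep], reason = reason[!keep])
  if (nrow(excl) > 0) {
    counts <- dplyr::count(excl, .data$reason)
    message("filter_eligible(): excluded ", nrow(excl), " of ", nrow(members), " members (",
            paste(paste0(counts$reason, ": ", counts$n), collapse = "; "), ")")
  }
  out <- members[keep, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

# ---- windowed claim-feature machinery -------------------------------------
#
# Claims are accumulated once into member x month matrices (medical spend,
# pharmacy spend, ED visits, inpatient visits, per-category presence) with
# column-wise cumulative sums, so the 12-month window aggregate at any
# anchor is a single column difference. Distinct ED diagnosis codes are the
# only aggregate that cannot be composed from monthly sums; they are
# computed from the (small) ED claim subset per anchor.

feature_cache <- function(members, claims) {
  n <- nrow(members)
  m <- max(members$eligibility_end) + 1L
  i <- match(claims$member_id, members$member_id)
  keep <- !is.na(i)
  cl <- claims[keep, , drop = FALSE]
  i <- i[keep]
  j <- cl$month + 1L

  build <- function(rows, x) {
    as.matrix(Matrix::sparseMatrix(i = i[rows], j = j[rows], x = x,
                                   dims = c(n, m)))
  }
  is_rx <- cl$category %in% pharmacy_categories()
  cache <- list(
    member_id = members$member_id, n = n, m = m,
    medical = col_cumsum(build(which(!is_rx), cl$amount_cents[!is_rx] / 100)),
    pharmacy = col_cumsum(build(which(is_rx), cl$amount_cents[is_rx] / 100)),
    ed = col_cumsum(build(which(cl$category == "ED"), 1)),
    inpatient = col_cumsum(build(which(cl$category == "inpatient"), 1)),
    presence = lapply(spend_categories(), function(cc) {
      col_cumsum(build(which(cl$category == cc), 1))
    }),
    ed_codes = local({
      ed <- cl$category == "ED"
      code_id <- match(cl$ed_diag_code[ed], unique(cl$ed_diag_code[ed]))
      list(row = i[ed], month = cl$month[ed], code_id = code_id,
           n_codes = max(code_id, 0L))
    })
  )
  cache
}

# 12-month window sum ending the month before `anchor`, from a cumsum matrix.
window_sum <- function(cs, anchor) {
  out <- cs[, anchor]
  if (anchor > 12) out <- out - cs[, anchor - 12]
  out
}

features_from_cache <- function(cache, members, anchor_month) {
  rows <- match(members$member_id, cache$member_id)
  a <- anchor_month
  check_that(a >= 12 && a <= cache$m - 1,
             paste0("anchor month ", a, " outside usable calendar"))
  distinct_cats <- Reduce(`+`, lapply(cache$presence, function(cs) {
    as.integer(window_sum(cs, a)[rows] > 0)
  }))
  ec <- cache$ed_codes
  in_w <- ec$month >= a - 12 & ec$month <= a - 1
  key <- as.double(ec$row[in_w]) * (ec$n_codes + 1) + ec$code_id[in_w]
  first <- !duplicated(key)
  counts_all <- tabulate(ec$row[in_w][first], nbins = cache$n)
  diag_counts <- counts_all[rows]

  tibble::tibble(
    member_id = members$member_id,
    anchor_month = as.integer(a),
    age = members$age,
    sex = members$sex,
    location = members$location,
    plan_type = members$plan_type,
    pharmacy_data_available = members$pharmacy_data_available,
    comm_receptivity = members$comm_receptivity,
    care_management = members$care_management,
    member_advocacy = members$member_advocacy,
    chronic_count = members$chronic_count,
    risk_score = members$risk_score,
    inpatient_visits_12m = window_sum(cache$inpatient, a)[rows],
    ed_visits_12m = window_sum(cache$ed, a)[rows],
    diag_code_count_12m = as.integer(diag_counts),
    procedure_count_12m = as.integer(distinct_cats),
    pre_medical_pupm = window_sum(cache$medical, a)[rows] / 12,
    pre_pharmacy_pupm = ifelse(members$pharmacy_data_available,
                               window_sum(cache$pharmacy, a)[rows] / 12, NA_real_)
  )
}

#' Build 12-month anchored feature vectors
#'
#' Computes, for each member, covariates summarizing the 12 whole months
#' strictly before `anchor_month` (months `anchor_month - 12` through
#' `anchor_month - 1`; the anchor month itself belongs to neither window):
#' visit counts, distinct ED diagnosis codes, distinct cost categories used,
#' and pre-period medical/pharmacy PUPM (window total divided by 12; months
#' without claims count in the denominator). Pharmacy PUPM is `NA` exactly
#' when the member has no pharmacy data-sharing agreement.
#'
#' @param members Roster rows to featurize.
#' @param claims Claim-line tibble.
#' @param anchor_month Anchor (enlistment or candidate) month index.
#' @return A feature tibble, one row per member, row order preserved.
#' @export
build_features <- function(members, claims, anchor_month) {
  short <- members$eligibility_start > anchor_month - 12
  if (any(short)) {
    rlang::abort(paste0(
      "members lack a 12-month pre window at anchor ", anchor_month, ": ",
      paste(utils::head(members$member_id[short], 5), collapse = ", ")
    ), class = "pupmatch_precondition_error")
  }
  features_from_cache(feature_cache(members, claims), members, anchor_month)
}

#' Feature vectors for the still-unmatched comparison pool at one month
#'
#' Emits one anchored feature vector per comparison-pool member who is not
#' yet matched and whose eligibility span admits `month` as an anchor (12
#' observable pre months and >= 7 post months, since a matched comparison
#' inherits its partner's anchor).
#'
#' @param pool Comparison-pool roster (non-enrolled members).
#' @param claims Claim-line tibble.
#' @param month Candidate anchor month.
#' @param matched_ids Member ids already consumed by earlier months.
#' @return Feature tibble (possibly zero rows).
#' @export
monthly_comparison_features <- function(pool, claims, month, matched_ids = character()) {
  ok <- !(pool$member_id %in% matched_ids) &
    pool$eligibility_start <= month - 12 &
    pool$eligibility_end >= month + 7
  build_features(pool[ok, , drop = FALSE], claims, month)
}
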