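effect_row <- function(label, estimate, ci_low, ci_high, t_stat, p_value,
                       n_treated, n_comparison, alpha = 0.05) {
  out <- tibble::tibble(
    label = label, estimate = estimate, ci_low = ci_low, ci_high = ci_high,
    t_stat = t_stat, p_value = p_value,
    n_treated = as.integer(n_treated), n_comparison = as.integer(n_comparison),
    alpha = alpha
  )
  class(out) <- c("pupm_effect", class(out))
  out
}

# Welch two-sample comparison returning estimate = mean(x) - mean(y), robust
# to degenerate (constant) inputs: equal constants -> estimate 0, p = 1.
welch_row <- function(label, x, y, alpha = 0.05) {
  est <- mean(x) - mean(y)
  tt <- tryCatch(stats::t.test(x, y, conf.level = 1 - alpha),
                 error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$p.value)) { # constant inputs: no sampling error
    p <- if (isTRUE(all.equal(est, 0))) 1 else 0
    return(effect_row(label, est, est, est, 0, p, length(y), length(x), alpha))
  }
  effect_row(label, est, tt$conf.int[1], tt$conf.int[2],
             unname(tt$statistic), tt$p.value, length(y), length(x), alpha)
}

#' Within-group pre/post change in PUPM spending
#'
#' Two-tailed paired t test of post- vs pre-enlistment PUPM within one
#' group, i.e. a one-sample test on the member-level change scores
#' `post_pupm - pre_pupm`. The estimate is the mean change (negative means
#' spending decreased). If every change is zero the estimate is 0 and p = 1
#' by convention.
#'
#' @param summaries `pupm_spend` rows for one group (>= 2 members).
#' @param label Row label.
#' @param alpha Significance level (CI level is `1 - alpha`).
#' @return A one-row `pupm_effect` tibble.
#' @export
within_group_change <- function(summaries, label = "within-group change", alpha = 0.05) {
  ch <- summaries$change
  check_that(length(ch) >= 2, "within_group_change() needs >= 2 members")
  n_t <- sum(summaries$group == "treated")
  n_c <- sum(summaries$group == "comparison")
  if (all(ch == 0)) {
    return(effect_row(label, 0, 0, 0, 0, 1, n_t, n_c, alpha))
  }
  tt <- tryCatch(stats::t.test(ch, conf.level = 1 - alpha), error = function(e) NULL)
  if (is.null(tt)) { # non-zero constant changes: mean exact, no sampling error
    m <- mean(ch)
    return(effect_row(label, m, m, m, Inf * sign(m), 0, n_t, n_c, alpha))
  }
  effect_row(label, mean(ch), tt$conf.int[1], tt$conf.int[2],
             unname(tt$statistic), tt$p.value, n_t, n_c, alpha)
}

#' Difference-in-differences savings estimate
#'
#' Savings = mean change (post minus pre PUPM) in the comparison group minus
#' mean change in the treated group, so a spending *reduction* among treated
#' members is a *positive* savings. Inference is a two-tailed unpaired
#' unequal-variance (Welch) t test on the member-level change scores, with
#' the 95% CI reported on the savings scale.
#'
#' @param treated_summaries,comparison_summaries `pupm_spend` rows per
#'   group (each >= 2 members).
#' @param label Row label.
#' @param alpha Significance level.
#' @return A one-row `pupm_effect` tibble.
#' @export
difference_in_differences <- function(treated_summaries, comparison_summaries,
                                      label = "difference-in-differences", alpha = 0.05) {
  check_that(nrow(treated_summaries) >= 2 && nrow(comparison_summaries) >= 2,
             "difference_in_differences() needs >= 2 members per group")
  welch_row(label, comparison_summaries$change, treated_summaries$change, alpha)
}

#' Cost-category decomposition of the savings estimate
#'
#' One difference-in-differences row per cost category (change scores built
#' from the per-category PUPM columns) plus an overall row computed on total
#' PUPM. Without capping, category savings sum exactly to the overall
#' savings; proportional capping preserves the identity at the PUPM-sum
#' level per member.
#'
#' @param treated_summaries,comparison_summaries `pupm_spend` rows.
#' @param categories Categories to report; defaults to all known. Unknown
#'   names error.
#' @param alpha Significance level.
#' @return A `pupm_effect` tibble, one row per category plus `"overall"`.
#' @export
category_breakdown <- function(treated_summaries, comparison_summaries,
                               categories = NULL, alpha = 0.05) {
  if (is.null(categories)) categories <- spend_categories()
  unknown <- setdiff(categories, spend_categories())
  check_that(length(unknown) == 0,
             paste0("unknown cost categories: ", paste(unknown, collapse = ", ")))
  cat_change <- function(s, cc) s[[paste0("post_cat_", cc)]] - s[[paste0("pre_cat_", cc)]]
  rows <- purrr::map_dfr(categories, function(cc) {
    welch_row(cc, cat_change(comparison_summaries, cc),
              cat_change(treated_summaries, cc), alpha)
  })
  overall <- difference_in_differences(treated_summaries, comparison_summaries,
                                       label = "overall", alpha = alpha)
  out <- dplyr::bind_rows(rows, overall)
  class(out) <- c("pupm_effect", class(out))
  out
}

#' Probabilistic emergent/non-emergent split of ED spending
#'
#' Each ED claim's cost is split fractionally by its diagnosis code's
#' probability row: `p_emergent` of the amount is emergent, `p_nonemergent`
#' non-emergent, and the remainder "other", then aggregated per member (and
#' per period when a `period` column is present). Codes absent from the
#' table follow `unknown`: `"other"` (default) assigns their full cost to
#' the other bucket with a warning; `"error"` aborts.
#'
#' @param ed_claims ED claim lines (`member_id`, `amount_cents`,
#'   `ed_diag_code`, optional `period`).
#' @param table An [ed_probability_table()].
#' @param unknown Policy for unknown diagnosis codes.
#' @return Tibble with `member_id` (and `period` if supplied) and USD
#'   columns `emergent`, `nonemergent`, `other`.
#' @export
classify_ed <- function(ed_claims, table = ed_probability_table(),
                        unknown = c("other", "error")) {
  unknown <- match.arg(unknown)
  idx <- match(ed_claims$ed_diag_code, table$diag_code)
  if (anyNA(idx)) {
    bad <- unique(ed_claims$ed_diag_code[is.na(idx)])
    if (unknown == "error") {
      rlang::abort(paste0("unknown ED diagnosis codes: ", paste(bad, collapse = ", ")))
    }
    rlang::warn(paste0("assigning ", sum(is.na(idx)),
                       " ED claims with unknown diagnosis codes to \"other\""))
  }
  usd <- ed_claims$amount_cents / 100
  p_em <- ifelse(is.na(idx), 0, table$p_emergent[idx])
  p_ne <- ifelse(is.na(idx), 0, table$p_nonemergent[idx])
  df <- tibble::tibble(
    member_id = ed_claims$member_id,
    emergent = usd * p_em,
    nonemergent = usd * p_ne,
    other = usd * (1 - p_em - p_ne)
  )
  keys <- "member_id"
  if ("period" %in% names(ed_claims)) {
    df$period <- ed_claims$period
    keys <- c("member_id", "period")
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(c("emergent", "nonemergent", "other"), sum),
                     .groups = "drop")
}

#' Annualized savings
#'
#' `savings_pupm * n_users * months`: e.g. $10 PUPM across 56,816 users over
#' 12 months is about $6.8 million; for a single user it is $120 per year.
#'
#' @param savings_pupm Savings in USD per user per month (>= 0).
#' @param n_users Number of users (>= 0).
#' @param months Months to annualize over (default 12).
#' @return Total USD.
#' @export
annualize <- function(savings_pupm, n_users, months = 12) {
  check_that(all(c(savings_pupm, n_users, months) >= 0),
             "annualize() inputs must be non-negative")
  savings_pupm * n_users * months
}

#' Subgroup difference-in-differences
#'
#' Restricts the matched-pair set to treated members satisfying a predicate
#' on member attributes (their matched partners follow), then re-estimates
#' the difference-in-differences on the restricted set.
#'
#' @param pairs A `pupm_match` or pairs tibble.
#' @param summaries Full `pupm_spend` table.
#' @param members Member roster (the predicate's data mask).
#' @param predicate Bare expression on member columns, e.g.
#'   `chronic_count >= 2`.
#' @param alpha Significance level.
#' @return A one-row `pupm_effect` tibble.
#' @export
subgroup_effect <- function(pairs, summaries, members, predicate, alpha = 0.05) {
  pairs <- as_pairs(pairs)
  sel <- rlang::eval_tidy(rlang::enquo(predicate), data = members)
  keep_ids <- members$member_id[sel]
  sub <- pairs[pairs$treated_id %in% keep_ids, , drop = FALSE]
  check_that(nrow(sub) >= 2, "subgroup predicate selects fewer than 2 treated members")
  difference_in_differences(
    summaries[summaries$member_id %in% sub$treated_id, , drop = FALSE],
    summaries[summaries$member_id %in% sub$control_id, , drop = FALSE],
    label = "subgroup difference-in-differences", alpha = alpha
  )
}

#' Naive unmatched post-period contrast
#'
#' The contrast a cost evaluation would report with no matching and no
#' pre-period: mean post-enlistment PUPM of all eligible non-enrolled
#' members minus that of enrolled members (savings sign convention).
#' Non-enrolled members, having no anchor, are evaluated over a reference
#' window anchored at the median treated enlistment month. Under
#' covariate-driven self-selection this estimator absorbs baseline spending
#' differences between the groups; it is exposed so the contrast with the
#' matched difference-in-differences is testable.
#'
#' @param members Eligible roster.
#' @param claims Claim-line tibble (flags filtered internally).
#' @param alpha Significance level.
#' @return A one-row `pupm_effect` tibble.
#' @export
naive_post_difference <- function(members, claims, alpha = 0.05) {
  treated <- members[members$enrolled, , drop = FALSE]
  pool <- members[!members$enrolled, , drop = FALSE]
  check_that(nrow(treated) >= 2 && nrow(pool) >= 2,
             "naive_post_difference() needs >= 2 members per group")
  claims <- suppressMessages(filter_claims(claims))
  ref <- as.integer(round(stats::median(treated$enroll_month)))
  anchors <- ifelse(members$enrolled, members$enroll_month, ref)
  post_m <- pmin(12L, members$eligibility_end - anchors)
  i <- match(claims$member_id, members$member_id)
  rel <- claims$month - anchors[i]
  keep <- !is.na(i) & rel >= 1 & rel <= post_m[i]
  sums <- rowsum(claims$amount_cents[keep] / 100, i[keep])
  tot <- numeric(nrow(members))
  tot[as.integer(rownames(sums))] <- sums[, 1]
  pupm <- tot / post_m
  welch_row("naive unmatched post-period difference",
            pupm[!members$enrolled], pupm[members$enrolled], alpha)
}

#' @method print pupm_effect
#' @export
print.pupm_effect <- function(x, ...) {
  cat("<pupm_effect> USD per user per month\n")
  NextMethod()
}

#' Tidy an effect table
#' @param x A `pupm_effect`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.pupm_effect <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pupm_effect")
  out
}
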