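#' Exact-matching segment key
#'
#' Matching is performed within segments defined by self-reported sex,
#' pharmacy data availability, and health plan type.
#'
#' @param df Tibble with columns `sex`, `pharmacy_data_available`,
#'   `plan_type`.
#' @return Character vector of segment keys.
#' @export
segment_key <- function(df) {
  paste(df$sex, df$pharmacy_data_available, df$plan_type, sep = "|")
}

#' Greedy 1:1 nearest-neighbor matching within one segment
#'
#' Treated members are processed in descending propensity-score order (the
#' hardest-to-match, extreme-score members pick first; ties broken by
#' ascending `member_id`); each takes the remaining control nearest in
#' absolute logit-score distance, without replacement. Equal-distance ties
#' go to the lower-score control, then lower `member_id`; the result is a
#' function of the score multisets only, so input row order is irrelevant.
#'
#' @param treated,controls Tibbles with columns `member_id` and `score`
#'   (probabilities in (0,1)).
#' @param caliper Optional maximum allowed logit distance; pairs further
#'   apart are not formed.
#' @return Tibble of pairs: `treated_id`, `control_id`, `distance`
#'   (absolute logit difference).
#' @export
greedy_match_segment <- function(treated, controls, caliper = NULL) {
  if (nrow(treated) == 0 || nrow(controls) == 0) {
    return(tibble::tibble(treated_id = character(), control_id = character(),
                          distance = numeric()))
  }
  t_ord <- order(-treated$score, treated$member_id)
  t_id <- treated$member_id[t_ord]
  t_logit <- logit(treated$score[t_ord])
  c_ord <- order(controls$score, controls$member_id)
  c_id <- controls$member_id[c_ord]
  c_logit <- logit(controls$score[c_ord])
  nc <- length(c_id)
  free <- rep(TRUE, nc)
  n_free <- nc
  res_t <- character(0); res_c <- character(0); res_d <- numeric(0)

  for (ti in seq_along(t_id)) {
    if (n_free == 0) break
    lt <- t_logit[ti]
    pos <- findInterval(lt, c_logit) # last index with c_logit <= lt
    left <- pos
    while (left >= 1 && !free[left]) left <- left - 1
    right <- pos + 1
    while (right <= nc && !free[right]) right <- right + 1
    dl <- if (left >= 1) lt - c_logit[left] else Inf
    dr <- if (right <= nc) c_logit[right] - lt else Inf
    pick <- if (dl <= dr) left else right # tie -> lower-score control
    d <- min(dl, dr)
    if (!is.finite(d)) next
    if (!is.null(caliper) && d > caliper) next
    if (pick == left) {
      # among equal-logit candidates take the smallest member id; controls
      # are sorted by (logit, id), so walk to the leftmost free one in the
      # tied run (anything between is already matched)
      j <- left - 1
      while (j >= 1 && c_logit[j] == c_logit[left]) {
        if (free[j]) pick <- j
        j <- j - 1
      }
    }
    free[pick] <- FALSE
    n_free <- n_free - 1
    res_t <- c(res_t, t_id[ti]); res_c <- c(res_c, c_id[pick]); res_d <- c(res_d, d)
  }
  tibble::tibble(treated_id = res_t, control_id = res_c, distance = res_d)
}

#' Iterative month-by-month segment-stratified matching
#'
#' Implements rolling-enrollment matching: enlistment months are processed
#' in ascending order; at each month, feature vectors are (re)built for the
#' still-unmatched comparison pool anchored at that month, everyone is
#' scored with the propensity model, and greedy 1:1 nearest-neighbor
#' matching on absolute logit-score distance runs within each (sex,
#' pharmacy-availability, plan-type) segment. Matched controls are removed
#' from the pool permanently (no replacement across months). Treated members
#' with no available control in their segment are reported unmatched, never
#' silently dropped.
#'
#' @param members Eligible roster (treated = `enrolled`); see
#'   [filter_eligible()].
#' @param claims Claim-line tibble.
#' @param model Fitted [fit_propensity()] model, or a function mapping a
#'   feature tibble to scores in (0,1) (useful for controlled experiments).
#' @param caliper Optional logit-distance caliper (none by default).
#' @param cache Optional prebuilt internal feature cache for `members` and
#'   `claims` (reused by [run_pipeline()] to avoid rebuilding).
#' @param verbose Emit per-month progress messages.
#' @return A list of class `pupm_match`: `pairs` (tibble with `treated_id`,
#'   `control_id`, `anchor_month`, `sex`, `pharmacy_data_available`,
#'   `plan_type`, `distance`) and `unmatched_treated`.
#' @export
iterative_match <- function(members, claims, model, caliper = NULL,
                            cache = NULL, verbose = FALSE) {
  check_that(!anyDuplicated(members$member_id), "duplicate member_id in roster",
             class = "pupmatch_input_error")
  treated <- members[members$enrolled, , drop = FALSE]
  pool <- members[!members$enrolled, , drop = FALSE]
  check_that(nrow(treated) > 0, "no enrolled members to match",
             class = "pupmatch_input_error")
  check_that(length(intersect(treated$member_id, pool$member_id)) == 0,
             "treated and comparison sets overlap", class = "pupmatch_input_error")

  if (is.null(cache)) cache <- feature_cache(members, claims)
  months <- sort(unique(treated$enroll_month))
  matched_controls <- character(0)
  pairs <- vector("list", length(months))
  unmatched <- vector("list", length(months))

  for (mi in seq_along(months)) {
    mo <- months[mi]
    t_sub <- treated[treated$enroll_month == mo, , drop = FALSE]
    p_ok <- !(pool$member_id %in% matched_controls) &
      pool$eligibility_start <= mo - 12 & pool$eligibility_end >= mo + 7
    p_sub <- pool[p_ok, , drop = FALSE]
    tf <- features_from_cache(cache, t_sub, mo)
    cf <- features_from_cache(cache, p_sub, mo)
    score_fun <- if (is.function(model)) model else function(f) score_propensity(model, f)
    tf$score <- score_fun(tf)
    cf$score <- if (nrow(cf) > 0) score_fun(cf) else numeric(0)
    tf$segment <- segment_key(tf)
    cf$segment <- segment_key(cf)

    month_pairs <- purrr::map_dfr(sort(unique(tf$segment)), function(seg) {
      greedy_match_segment(tf[tf$segment == seg, c("member_id", "score")],
                           cf[cf$segment == seg, c("member_id", "score")],
                           caliper = caliper)
    })
    if (nrow(month_pairs) > 0) {
      month_pairs$anchor_month <- as.integer(mo)
      seg_cols <- tf[match(month_pairs$treated_id, tf$member_id),
                     c("sex", "pharmacy_data_available", "plan_type")]
      pairs[[mi]] <- dplyr::bind_cols(month_pairs, seg_cols)
      matched_controls <- c(matched_controls, month_pairs$control_id)
    }
    un <- setdiff(t_sub$member_id, month_pairs$treated_id)
    if (length(un) > 0) {
      unmatched[[mi]] <- tibble::tibble(
        member_id = un, anchor_month = as.integer(mo),
        reason = "no control available in segment"
      )
    }
    if (verbose) {
      message("month ", mo, ": ", nrow(t_sub), " treated, ",
              nrow(month_pairs), " matched, pool ", nrow(p_sub))
    }
  }
  pairs_df <- dplyr::bind_rows(pairs)
  if (nrow(pairs_df) == 0) {
    pairs_df <- tibble::tibble(
      treated_id = character(), control_id = character(),
      anchor_month = integer(), sex = character(),
      pharmacy_data_available = logical(), plan_type = character(),
      distance = numeric()
    )
  }
  out <- list(
    pairs = pairs_df[, c("treated_id", "control_id", "anchor_month",
                         "sex", "pharmacy_data_available",
                         "plan_type", "distance")],
    unmatched_treated = dplyr::bind_rows(unmatched)
  )
  if (nrow(out$unmatched_treated) == 0) {
    out$unmatched_treated <- tibble::tibble(member_id = character(),
                                            anchor_month = integer(),
                                            reason = character())
  }
  class(out) <- "pupm_match"
  out
}

#' @method print pupm_match
#' @export
print.pupm_match <- function(x, ...) {
  cat("<pupm_match>", nrow(x$pairs), "matched pairs;",
      nrow(x$unmatched_treated), "unmatched treated\n")
  invisible(x)
}

as_pairs <- function(x) {
  if (inherits(x, "pupm_match")) x$pairs else x
}

#' Covariate balance diagnostics for a matched cohort
#'
#' For every feature, computes treated and comparison means, the
#' standardized mean difference SMD = (mean_t - mean_c) / pooled SD (binary
#' features use the proportion difference over the pooled binary SD
#' `sqrt((p_t(1-p_t) + p_c(1-p_c))/2)`; categorical features are expanded to
#' one indicator per level), and a two-tailed unpaired (Welch) test p-value.
#' Features with |SMD| > 0.1 or p < `alpha` are flagged; the conventional
#' overall pass rule is all |SMD| <= 0.1.
#'
#' If both group means are equal with zero pooled SD the SMD is 0; unequal
#' means with zero pooled SD are flagged degenerate (infinite SMD).
#'
#' @param pairs A `pupm_match` or its `pairs` tibble.
#' @param features Feature tibble covering all matched members
#'   (`member_id` plus feature columns; one row per matched member at the
#'   pair's anchor).
#' @param alpha Significance level for the per-feature tests.
#' @return A tibble of class `pupm_balance` with attribute `pass`.
#' @export
compute_balance <- function(pairs, features, alpha = 0.05) {
  pairs <- as_pairs(pairs)
  check_that(nrow(pairs) >= 2, "balance needs at least 2 matched pairs")
  ft <- features[match(pairs$treated_id, features$member_id), , drop = FALSE]
  fc <- features[match(pairs$control_id, features$member_id), , drop = FALSE]
  check_that(!anyNA(ft$member_id) && !anyNA(fc$member_id),
             "features must cover every matched member")

  expand <- function(df) {
    keep <- setdiff(names(df), c("member_id", "anchor_month", "score", "segment"))
    cols <- list()
    for (nm in keep) {
      v <- df[[nm]]
      if (is.numeric(v)) {
        cols[[nm]] <- as.numeric(v)
      } else if (is.logical(v)) {
        cols[[paste0(nm)]] <- as.numeric(v)
      } else {
        for (lv in sort(unique(as.character(v)))) {
          cols[[paste0(nm, "=", lv)]] <- as.numeric(v == lv)
        }
      }
    }
    cols
  }
  xt <- expand(ft)
  xc <- expand(fc)
  feats <- union(names(xt), names(xc))

  rows <- purrr::map_dfr(feats, function(nm) {
    a <- xt[[nm]] %||% rep(0, nrow(ft))
    b <- xc[[nm]] %||% rep(0, nrow(fc))
    binary <- all(stats::na.omit(c(a, b)) %in% c(0, 1))
    ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
    sd_pool <- if (binary) {
      sqrt((ma * (1 - ma) + mb * (1 - mb)) / 2)
    } else {
      sqrt((stats::var(a, na.rm = TRUE) + stats::var(b, na.rm = TRUE)) / 2)
    }
    smd <- if (sd_pool > 0) (ma - mb) / sd_pool else if (isTRUE(all.equal(ma, mb))) 0 else Inf
    p <- tryCatch(stats::t.test(a, b)$p.value,
                  error = function(e) if (isTRUE(all.equal(ma, mb))) 1 else 0)
    tibble::tibble(feature = nm, treated_mean = ma, comparison_mean = mb,
                   smd = smd, p_value = p,
                   smd_flag = abs(smd) > 0.1, p_flag = p < alpha,
                   degenerate = !is.finite(smd))
  })
  attr(rows, "pass") <- all(abs(rows$smd) <= 0.1)
  attr(rows, "alpha") <- alpha
  class(rows) <- c("pupm_balance", class(rows))
  rows
}

#' Glance at a balance report
#' @param x A `pupm_balance`.
#' @param ... Unused.
#' @return One-row tibble: feature count, max |SMD|, flag counts, pass.
#' @export
glance.pupm_balance <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    max_abs_smd = max(abs(x$smd)),
    n_smd_flagged = sum(x$smd_flag),
    n_p_flagged = sum(x$p_flag),
    pass = attr(x, "pass")
  )
}
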