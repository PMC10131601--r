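#' Remove excluded health-care spending
#'
#' Drops claim lines flagged non-impactable or pregnancy-related (a line
#' carrying both flags is removed, and counted, once). The number of removed
#' rows is messaged and returned in attributes `n_removed`,
#' `n_nonimpactable`, `n_pregnancy_related`.
#'
#' @param claims Claim-line tibble with logical `nonimpactable` and
#'   `pregnancy_related` columns.
#' @return The filtered tibble.
#' @export
filter_claims <- function(claims) {
  drop <- claims$nonimpactable | claims$pregnancy_related
  out <- claims[!drop, , drop = FALSE]
  message("filter_claims(): removed ", sum(drop), " of ", nrow(claims),
          " claim lines (", sum(claims$nonimpactable), " nonimpactable, ",
          sum(claims$pregnancy_related), " pregnancy related)")
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_nonimpactable") <- sum(claims$nonimpactable)
  attr(out, "n_pregnancy_related") <- sum(claims$pregnancy_related)
  out
}

#' Cap period spend totals at a nearest-rank percentile
#'
#' The cap is the nearest-rank percentile — the `ceiling(p/100 * n)`-th
#' order statistic — of the pooled period totals (treated and comparison
#' together, so both groups face one cap); totals above it are set to it.
#' Applied separately to pre-period and post-period totals by the caller.
#' Idempotent, and alters at most `ceiling((1 - p/100) * n)` members.
#'
#' @param totals Numeric vector of per-member period totals (USD).
#' @param percentile Percentile in (0, 100]; 99 caps at the 99th.
#' @return A list: `capped` (vector, same order), `cap` (the cap value),
#'   `n_capped` (members altered).
#' @export
cap_spending <- function(totals, percentile = 99) {
  check_that(length(totals) >= 1, "cap_spending() needs at least one member")
  cap <- nearest_rank(totals, percentile)
  capped <- pmin(totals, cap)
  list(capped = capped, cap = cap, n_capped = sum(totals > cap))
}

#' Per-user-per-month spend over a month window
#'
#' Sums claim amounts falling in `window_months` and divides by the number
#' of window months; months with zero spend count in the denominator.
#' Members in `member_ids` with no claims get PUPM 0.
#'
#' @param claims Claim-line tibble (already filtered).
#' @param window_months Integer vector of month indices (non-empty).
#' @param member_ids Members to report; defaults to those present in
#'   `claims`.
#' @return Tibble with `member_id` and `pupm` (USD/month).
#' @export
compute_pupm <- function(claims, window_months, member_ids = NULL) {
  check_that(length(window_months) >= 1, "empty PUPM window",
             class = "pupmatch_precondition_error")
  if (is.null(member_ids)) member_ids <- sort(unique(claims$member_id))
  sub <- claims[claims$month %in% window_months, , drop = FALSE]
  tot <- dplyr::summarise(dplyr::group_by(sub, .data$member_id),
                          total = sum(.data$amount_cents) / 100, .groups = "drop")
  pupm <- tot$total[match(member_ids, tot$member_id)]
  pupm[is.na(pupm)] <- 0
  tibble::tibble(member_id = member_ids, pupm = pupm / length(window_months))
}

#' Pre/post PUPM spend summaries for a matched cohort
#'
#' For every matched member, computes capped, filtered pre- and
#' post-enlistment PUPM spend. Windows come from the pair's anchor month
#' (the treated member's enlistment month; the matched comparison member
#' inherits it): pre = the 12 months strictly before the anchor, post = the
#' fully observed months strictly after it, truncated at 12 (>= 7 by
#' eligibility). The anchor month itself belongs to neither period. Flagged
#' claims are removed, per-member period totals are capped at the pooled
#' nearest-rank percentile separately per period, and capping is spread
#' proportionally across categories so category PUPMs still sum to the
#' total.
#'
#' @param members Roster (for eligibility spans).
#' @param claims Claim-line tibble (raw; flags filtered internally unless
#'   `filter_flags = FALSE`).
#' @param pairs A `pupm_match` or pairs tibble.
#' @param cap_percentile Percentile for [cap_spending()]; `NULL` disables
#'   capping.
#' @param filter_flags Apply [filter_claims()] first.
#' @return A tibble of class `pupm_spend`: `member_id`, `group`
#'   (`"treated"`/`"comparison"`), `anchor_month`, `pre_months` (12),
#'   `post_months` (7-12), `pre_pupm`, `post_pupm`,
#'   `change = post_pupm - pre_pupm`, and per-category PUPM columns
#'   `pre_cat_*` / `post_cat_*`. Attributes `cap_pre`, `cap_post`,
#'   `n_capped_pre`, `n_capped_post`.
#' @export
summarize_spend <- function(members, claims, pairs, cap_percentile = 99,
                            filter_flags = TRUE) {
  pairs <- as_pairs(pairs)
  check_that(nrow(pairs) >= 1, "no matched pairs")
  if (filter_flags) claims <- filter_claims(claims)

  roster <- tibble::tibble(
    member_id = c(pairs$treated_id, pairs$control_id),
    group = rep(c("treated", "comparison"), each = nrow(pairs)),
    anchor_month = rep(pairs$anchor_month, 2)
  )
  check_that(!anyDuplicated(roster$member_id),
             "a member appears in more than one pair")
  elig_end <- members$eligibility_end[match(roster$member_id, members$member_id)]
  check_that(!anyNA(elig_end), "matched member missing from roster")
  roster$pre_months <- 12L
  # identical windows within a pair: the post window is truncated at 12 and
  # at the earlier of the two members' eligibility ends
  end_t <- elig_end[seq_len(nrow(pairs))]
  end_c <- elig_end[nrow(pairs) + seq_len(nrow(pairs))]
  pair_post <- pmin(12L, pmin(end_t, end_c) - pairs$anchor_month)
  roster$post_months <- rep(pair_post, 2)
  check_that(all(roster$post_months >= 7), "matched member with < 7 post months")

  cats <- spend_categories()
  ncat <- length(cats)
  nr <- nrow(roster)
  cl <- claims[claims$member_id %in% roster$member_id, , drop = FALSE]
  ri <- match(cl$member_id, roster$member_id)
  rel <- cl$month - roster$anchor_month[ri]
  is_pre <- rel >= -12 & rel <= -1
  is_post <- rel >= 1 & rel <= roster$post_months[ri]
  keep <- is_pre | is_post
  ri <- ri[keep]
  per <- ifelse(is_pre[keep], 0L, 1L) # 0 = pre, 1 = post
  cat_i <- match(cl$category[keep], cats)
  check_that(!anyNA(cat_i), "claim with unknown cost category")
  usd <- cl$amount_cents[keep] / 100

  # member x period x category totals via one rowsum pass
  key <- ((ri - 1L) * 2L + per) * ncat + (cat_i - 1L)
  sums <- rowsum(usd, key)
  k <- as.integer(rownames(sums))
  cat_mat <- matrix(0, nr, 2L * ncat) # cols: (pre cats 1..ncat, post cats 1..ncat)
  c0 <- k %% ncat
  rest <- k %/% ncat
  cat_mat[cbind(rest %/% 2L + 1L, (rest %% 2L) * ncat + c0 + 1L)] <- sums[, 1]
  pre_tot <- rowSums(cat_mat[, 1:ncat, drop = FALSE])
  post_tot <- rowSums(cat_mat[, ncat + 1:ncat, drop = FALSE])

  # pooled nearest-rank capping per period; capping spread proportionally
  # across categories so category PUPMs still sum to the total
  caps <- list(pre = NA_real_, post = NA_real_)
  n_capped <- list(pre = 0L, post = 0L)
  factor_pre <- rep(1, nr)
  factor_post <- rep(1, nr)
  if (!is.null(cap_percentile)) {
    res_pre <- cap_spending(pre_tot, cap_percentile)
    res_post <- cap_spending(post_tot, cap_percentile)
    factor_pre <- ifelse(pre_tot > 0, res_pre$capped / pre_tot, 1)
    factor_post <- ifelse(post_tot > 0, res_post$capped / post_tot, 1)
    caps <- list(pre = res_pre$cap, post = res_post$cap)
    n_capped <- list(pre = res_pre$n_capped, post = res_post$n_capped)
    pre_tot <- res_pre$capped
    post_tot <- res_post$capped
  }
  cat_mat[, 1:ncat] <- cat_mat[, 1:ncat, drop = FALSE] * factor_pre
  cat_mat[, ncat + 1:ncat] <- cat_mat[, ncat + 1:ncat, drop = FALSE] * factor_post

  out <- roster
  out$pre_pupm <- pre_tot / roster$pre_months
  out$post_pupm <- post_tot / roster$post_months
  out$change <- out$post_pupm - out$pre_pupm
  cat_pupm <- cbind(cat_mat[, 1:ncat, drop = FALSE] / roster$pre_months,
                    cat_mat[, ncat + 1:ncat, drop = FALSE] / roster$post_months)
  colnames(cat_pupm) <- c(paste0("pre_cat_", cats), paste0("post_cat_", cats))
  out <- dplyr::bind_cols(out, tibble::as_tibble(cat_pupm))
  attr(out, "cap_pre") <- caps$pre
  attr(out, "cap_post") <- caps$post
  attr(out, "n_capped_pre") <- n_capped$pre
  attr(out, "n_capped_post") <- n_capped$post
  class(out) <- c("pupm_spend", class(out))
  out
}

#' Spend summary for a single matched member
#'
#' @param member_id The member; must appear in a matched pair.
#' @param members,claims,pairs,... As in [summarize_spend()].
#' @return One-row `pupm_spend` tibble.
#' @export
summarize_member <- function(member_id, members, claims, pairs, ...) {
  pairs <- as_pairs(pairs)
  hit <- pairs$treated_id == member_id | pairs$control_id == member_id
  check_that(any(hit), paste0("member ", member_id, " is not in any matched pair"))
  s <- summarize_spend(members, claims, pairs[hit, , drop = FALSE], ...)
  s[s$member_id == member_id, , drop = FALSE]
}
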