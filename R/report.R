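#' Run the full matched pre/post cost evaluation
#'
#' End-to-end orchestration: eligibility filtering, anchored feature
#' construction, ensemble propensity fitting, rolling month-by-month
#' segment-stratified 1:1 matching, balance confirmation, capped/filtered
#' PUPM spend summarization, and effect estimation (within-group changes,
#' difference-in-differences savings, the naive unmatched contrast, the
#' cost-category decomposition, and the emergent/non-emergent ED split).
#' Fully deterministic given the seed(s).
#'
#' The propensity model is trained on the eligible population: treated
#' members are featurized at their enlistment month; comparison-pool members
#' at a pseudo-anchor drawn (seeded) from the empirical treated enlistment
#' month distribution, mirroring the rolling design.
#'
#' A balance failure (any |SMD| above `smd_threshold`) does not stop the
#' run; the manifest is flagged non-compliant.
#'
#' @param config A [sim_config()] used to simulate members and claims when
#'   they are not supplied.
#' @param members,claims Optional pre-loaded tables (see [read_members()]).
#' @param out_dir If non-NULL, write `pairs.csv`, `estimates.csv`,
#'   `balance.csv` and `manifest.json` there.
#' @param ed_table ED probability table; default the shipped synthetic one.
#' @param cap_percentile Spend-cap percentile (`NULL` disables capping).
#' @param smd_threshold Balance pass threshold on |SMD|.
#' @param alpha Significance level for all tests.
#' @param seed Seed for model fitting and pseudo-anchor draws; defaults to
#'   `config$seed` (or 1).
#' @param verbose Per-stage progress messages.
#' @return A list of class `pupm_manifest`: stage `counts`, `estimates`
#'   (a `pupm_effect` tibble), `balance`, `pairs`, `unmatched_treated`,
#'   `summaries`, `model`, `caps`, `compliant`, `config_hash`, `seed`,
#'   `version`.
#' @export
run_pipeline <- function(config = NULL, members = NULL, claims = NULL,
                         out_dir = NULL, ed_table = NULL,
                         cap_percentile = 99, smd_threshold = 0.1,
                         alpha = 0.05, seed = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pupmatch] ", ...)
  if (is.null(members)) {
    check_that(!is.null(config), "supply either a config or members + claims")
    say("simulating cohort (n = ", config$n_members, ")")
    sim <- simulate_cohort(config)
    members <- sim$members
    claims <- sim$claims
  }
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  if (is.null(ed_table)) ed_table <- ed_probability_table()

  counts <- list(n_members = nrow(members), n_claims = nrow(claims))
  eligible <- suppressMessages(filter_eligible(members, claims))
  counts$n_excluded <- nrow(members) - nrow(eligible)
  counts$n_eligible <- nrow(eligible)
  counts$n_treated <- sum(eligible$enrolled)
  counts$n_pool <- sum(!eligible$enrolled)
  say("eligible: ", counts$n_eligible, " (", counts$n_treated, " enrolled)")
  if (counts$n_treated == 0) {
    rlang::abort(paste0(
      "cannot match: no enrolled members remain after eligibility filtering (",
      counts$n_eligible, " eligible members, all comparison)"
    ), class = "pupmatch_input_error")
  }

  # --- propensity training set ---------------------------------------------
  cache <- feature_cache(eligible, claims)
  treated <- eligible[eligible$enrolled, , drop = FALSE]
  pool <- eligible[!eligible$enrolled, , drop = FALSE]
  set.seed(seed)
  pseudo <- sample(treated$enroll_month, nrow(pool), replace = TRUE)
  pseudo <- pmax(pool$eligibility_start + 12L, pmin(pool$eligibility_end - 7L, pseudo))
  t_feats <- purrr::map_dfr(sort(unique(treated$enroll_month)), function(a) {
    features_from_cache(cache, treated[treated$enroll_month == a, , drop = FALSE], a)
  })
  p_feats <- purrr::map_dfr(sort(unique(pseudo)), function(a) {
    features_from_cache(cache, pool[pseudo == a, , drop = FALSE], a)
  })
  train <- dplyr::bind_rows(t_feats, p_feats)
  labels <- c(rep(TRUE, nrow(t_feats)), rep(FALSE, nrow(p_feats)))
  say("fitting propensity ensemble on ", nrow(train), " members")
  model <- fit_propensity(train, labels, seed = seed)

  # --- rolling matching ----------------------------------------------------
  say("matching month by month")
  match_res <- iterative_match(eligible, claims, model, cache = cache, verbose = verbose)
  counts$n_matched_pairs <- nrow(match_res$pairs)
  counts$n_unmatched_treated <- nrow(match_res$unmatched_treated)

  # --- balance -------------------------------------------------------------
  pair_feats <- purrr::map_dfr(sort(unique(match_res$pairs$anchor_month)), function(a) {
    ids <- match_res$pairs[match_res$pairs$anchor_month == a, ]
    features_from_cache(cache,
      eligible[match(c(ids$treated_id, ids$control_id), eligible$member_id), , drop = FALSE], a)
  })
  balance <- compute_balance(match_res, pair_feats, alpha = alpha)
  compliant <- all(abs(balance$smd) <= smd_threshold)
  say("balance: max |SMD| = ", round(max(abs(balance$smd)), 3),
      if (compliant) " (pass)" else " (NON-COMPLIANT)")

  # --- spend + effects -----------------------------------------------------
  claims_f <- filter_claims(claims)
  counts$n_claims_removed_nonimpactable <- attr(claims_f, "n_nonimpactable")
  counts$n_claims_removed_pregnancy <- attr(claims_f, "n_pregnancy_related")
  counts$n_claims_removed <- attr(claims_f, "n_removed")
  summaries <- summarize_spend(eligible, claims_f, match_res,
                               cap_percentile = cap_percentile, filter_flags = FALSE)
  counts$n_members_capped_pre <- attr(summaries, "n_capped_pre")
  counts$n_members_capped_post <- attr(summaries, "n_capped_post")
  st <- summaries[summaries$group == "treated", , drop = FALSE]
  sc <- summaries[summaries$group == "comparison", , drop = FALSE]

  estimates <- dplyr::bind_rows(
    within_group_change(st, "treated pre/post change", alpha),
    within_group_change(sc, "comparison pre/post change", alpha),
    difference_in_differences(st, sc, alpha = alpha),
    naive_post_difference(eligible, claims, alpha),
    category_breakdown(st, sc, alpha = alpha),
    ed_split_effects(claims_f, summaries, ed_table, alpha)
  )
  class(estimates) <- c("pupm_effect", setdiff(class(estimates), "pupm_effect"))
  did <- estimates$estimate[estimates$label == "difference-in-differences"]
  annualized <- annualize(max(0, did), counts$n_matched_pairs, 12)
  say("difference-in-differences savings: ", round(did, 2), " USD PUPM (",
      round(annualized), " USD annualized)")

  manifest <- list(
    counts = counts,
    estimates = estimates,
    balance = balance,
    pairs = match_res$pairs,
    unmatched_treated = match_res$unmatched_treated,
    summaries = summaries,
    model = model,
    caps = list(pre = attr(summaries, "cap_pre"), post = attr(summaries, "cap_post")),
    did_savings_pupm = did,
    annualized_savings_usd = annualized,
    compliant = compliant,
    config_hash = rlang::hash(list(config, seed, cap_percentile, smd_threshold, alpha)),
    seed = seed,
    version = as.character(utils::packageVersion("pupmatch"))
  )
  class(manifest) <- "pupm_manifest"
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  manifest
}

# Emergent / non-emergent ED difference-in-differences rows: each matched
# member's windowed ED claims are split probabilistically by diagnosis code,
# converted to per-period PUPM, and the change scores compared across groups.
ed_split_effects <- function(claims_f, summaries, ed_table, alpha = 0.05) {
  ed <- claims_f[claims_f$category == "ED" &
                   claims_f$member_id %in% summaries$member_id, , drop = FALSE]
  zero_rows <- function() dplyr::bind_rows(
    effect_row("ED emergent", 0, 0, 0, 0, 1,
               sum(summaries$group == "treated"), sum(summaries$group == "comparison"), alpha),
    effect_row("ED nonemergent", 0, 0, 0, 0, 1,
               sum(summaries$group == "treated"), sum(summaries$group == "comparison"), alpha)
  )
  if (nrow(ed) == 0) return(zero_rows())
  i <- match(ed$member_id, summaries$member_id)
  rel <- ed$month - summaries$anchor_month[i]
  ed$period <- dplyr::case_when(
    rel >= -12 & rel <= -1 ~ "pre",
    rel >= 1 & rel <= summaries$post_months[i] ~ "post",
    TRUE ~ NA_character_
  )
  ed <- ed[!is.na(ed$period), , drop = FALSE]
  if (nrow(ed) == 0) return(zero_rows())
  split <- classify_ed(ed, ed_table)

  base <- tidyr::expand_grid(member_id = summaries$member_id, period = c("pre", "post")) |>
    dplyr::left_join(split, by = c("member_id", "period")) |>
    dplyr::mutate(dplyr::across(c("emergent", "nonemergent"), ~ dplyr::coalesce(.x, 0)))
  j <- match(base$member_id, summaries$member_id)
  base$months <- ifelse(base$period == "pre", 12L, summaries$post_months[j])
  base$group <- summaries$group[j]
  chg <- base |>
    dplyr::mutate(em = .data$emergent / .data$months,
                  ne = .data$nonemergent / .data$months) |>
    dplyr::select("member_id", "group", "period", "em", "ne") |>
    tidyr::pivot_wider(names_from = "period", values_from = c("em", "ne")) |>
    dplyr::mutate(ch_em = .data$em_post - .data$em_pre,
                  ch_ne = .data$ne_post - .data$ne_pre)
  dplyr::bind_rows(
    welch_row("ED emergent", chg$ch_em[chg$group == "comparison"],
              chg$ch_em[chg$group == "treated"], alpha),
    welch_row("ED nonemergent", chg$ch_ne[chg$group == "comparison"],
              chg$ch_ne[chg$group == "treated"], alpha)
  )
}

#' Write manifest artifacts to a directory
#'
#' Writes `pairs.csv`, `estimates.csv`, `balance.csv` (UTF-8, comma,
#' header) and `manifest.json` (counts, caps, headline estimates,
#' compliance, version).
#'
#' @param manifest A `pupm_manifest`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_manifest <- function(manifest, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(manifest$pairs, file.path(out_dir, "pairs.csv"), progress = FALSE)
  readr::write_csv(tidy(manifest$estimates), file.path(out_dir, "estimates.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(manifest$balance), file.path(out_dir, "balance.csv"),
                   progress = FALSE)
  json <- list(
    counts = manifest$counts,
    caps = manifest$caps,
    did_savings_pupm = manifest$did_savings_pupm,
    annualized_savings_usd = manifest$annualized_savings_usd,
    compliant = manifest$compliant,
    config_hash = manifest$config_hash,
    seed = manifest$seed,
    version = manifest$version
  )
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @method print pupm_manifest
#' @export
print.pupm_manifest <- function(x, ...) {
  c_ <- x$counts
  cat("<pupm_manifest> pupmatch", x$version, "\n")
  cat("  members ", c_$n_members, " -> eligible ", c_$n_eligible,
      " (treated ", c_$n_treated, ", pool ", c_$n_pool, ")\n", sep = "")
  cat("  matched pairs: ", c_$n_matched_pairs, "  unmatched treated: ",
      c_$n_unmatched_treated, "\n", sep = "")
  cat("  claims removed by flags: ", c_$n_claims_removed, "\n", sep = "")
  cat("  balance: ", if (x$compliant) "pass" else "NON-COMPLIANT",
      " (max |SMD| ", round(max(abs(x$balance$smd)), 3), ")\n", sep = "")
  cat("  DiD savings: ", round(x$did_savings_pupm, 2), " USD PUPM;  annualized ",
      format(round(x$annualized_savings_usd), big.mark = ","), " USD\n", sep = "")
  invisible(x)
}

#' Glance at a pipeline manifest
#' @param x A `pupm_manifest`.
#' @param ... Unused.
#' @return One-row tibble of stage counts and headline estimates.
#' @export
glance.pupm_manifest <- function(x, ...) {
  did_row <- x$estimates[x$estimates$label == "difference-in-differences", ]
  tibble::tibble(
    n_members = x$counts$n_members, n_eligible = x$counts$n_eligible,
    n_treated = x$counts$n_treated, n_matched_pairs = x$counts$n_matched_pairs,
    n_unmatched_treated = x$counts$n_unmatched_treated,
    did_savings_pupm = did_row$estimate,
    did_ci_low = did_row$ci_low, did_ci_high = did_row$ci_high,
    did_p_value = did_row$p_value,
    annualized_savings_usd = x$annualized_savings_usd,
    balance_pass = x$compliant
  )
}
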