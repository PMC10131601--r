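test_that("flagged spending is excluded exactly once", {
  claims <- dplyr::bind_rows(
    purrr::map(1:6, ~ make_claim("A", .x)),
    make_claim("A", 7, nonimpactable = TRUE),
    make_claim("A", 8, nonimpactable = TRUE),
    make_claim("A", 9, nonimpactable = TRUE),
    make_claim("A", 10, pregnancy_related = TRUE)
  )
  out <- quiet(filter_claims(claims))
  expect_equal(nrow(out), 6)
  expect_equal(attr(out, "n_removed"), 4)

  both <- make_claim("A", 1, nonimpactable = TRUE, pregnancy_related = TRUE)
  out2 <- quiet(filter_claims(dplyr::bind_rows(make_claim("A", 2), both)))
  expect_equal(nrow(out2), 1)
  expect_equal(attr(out2, "n_removed"), 1) # counted once

  clean <- dplyr::bind_rows(make_claim("A", 1), make_claim("A", 2))
  expect_equal(tibble::as_tibble(quiet(filter_claims(clean))),
               tibble::as_tibble(clean), ignore_attr = TRUE)
})

test_that("nearest-rank 99th-percentile capping behaves as defined", {
  res <- cap_spending(1:100, 99)
  expect_equal(res$cap, 99) # ceiling(0.99 * 100) = 99th order statistic
  expect_equal(res$n_capped, 1)
  expect_equal(sort(unique(res$capped)), 1:99)
  expect_equal(max(res$capped), 99)

  # idempotent fixed point
  res2 <- cap_spending(res$capped, 99)
  expect_equal(res2$capped, res$capped)
  expect_equal(res2$n_capped, 0)

  # all-equal totals unchanged
  res3 <- cap_spending(rep(5, 10), 99)
  expect_equal(res3$capped, rep(5, 10))

  # never increases, alters at most ceiling(0.01 n)
  set.seed(2)
  for (n in c(17, 250, 1000)) {
    x <- rlnorm(n, 5, 1.5)
    r <- cap_spending(x, 99)
    expect_true(all(r$capped <= x))
    expect_lte(r$n_capped, ceiling(0.01 * n))
  }
})

test_that("PUPM divides window totals by window length", {
  claims <- make_claim("A", 16, amount_usd = 700)
  expect_equal(compute_pupm(claims, 16:22)$pupm, 100)
  expect_equal(compute_pupm(make_claim("A", 5, amount_usd = 1200), 3:14)$pupm, 100)
  expect_equal(compute_pupm(empty_claims(), 1:6, member_ids = "A")$pupm, 0)
  expect_error(compute_pupm(claims, integer()), class = "pupmatch_precondition_error")
})

test_that("spend summaries use anchored windows inherited by the control", {
  members <- dplyr::bind_rows(
    make_member("T", enrolled = TRUE, enroll_month = 15L, eligibility_end = 22L),
    make_member("C", eligibility_end = 29L)
  )
  pairs <- tibble::tibble(treated_id = "T", control_id = "C", anchor_month = 15L)
  claims <- dplyr::bind_rows(
    purrr::map(3:14, ~ make_claim("T", .x, amount_usd = 200)),  # pre: $2,400
    make_claim("T", 15, amount_usd = 1e6),                      # anchor month: excluded
    make_claim("T", 16, amount_usd = 700),                      # post window 16..22
    make_claim("C", 14, amount_usd = 1200),
    make_claim("C", 16, amount_usd = 70), make_claim("C", 22, amount_usd = 70),
    make_claim("C", 23, amount_usd = 1e6)                       # beyond T's post window
  )
  s <- quiet(summarize_spend(members, claims, pairs, cap_percentile = NULL))
  st <- s[s$member_id == "T", ]
  sc <- s[s$member_id == "C", ]
  expect_equal(st$group, "treated")
  expect_equal(sc$group, "comparison")
  # treated: post truncated at eligibility_end 22 -> 7 months
  expect_equal(st$post_months, 7L)
  expect_equal(st$pre_pupm, 200)
  expect_equal(st$post_pupm, 100)
  expect_equal(st$change, -100)
  # control inherits the anchor and window length despite longer eligibility
  expect_equal(sc$post_months, 7L)
  expect_equal(sc$pre_pupm, 100)
  expect_equal(sc$post_pupm, 20)
})

test_that("category PUPMs sum to the total, capped or not", {
  cfg <- sim_config(n_members = 1500, seed = 41)
  sim <- simulate_cohort(cfg)
  man <- quiet(run_pipeline(members = sim$members, claims = sim$claims, config = cfg))
  s <- man$summaries
  cats <- spend_categories()
  pre_sum <- rowSums(as.matrix(s[, paste0("pre_cat_", cats)]))
  post_sum <- rowSums(as.matrix(s[, paste0("post_cat_", cats)]))
  expect_equal(pre_sum, s$pre_pupm, tolerance = 1e-8)
  expect_equal(post_sum, s$post_pupm, tolerance = 1e-8)
  expect_lte(attr(s, "n_capped_pre"), ceiling(0.01 * nrow(s)))
  expect_lte(attr(s, "n_capped_post"), ceiling(0.01 * nrow(s)))
  expect_true(all(s$post_months >= 7 & s$post_months <= 12))
  expect_equal(s$change, s$post_pupm - s$pre_pupm)
})

test_that("summarize_member requires membership in a pair", {
  members <- dplyr::bind_rows(
    make_member("T", enrolled = TRUE, enroll_month = 15L), make_member("C"),
    make_member("X")
  )
  pairs <- tibble::tibble(treated_id = "T", control_id = "C", anchor_month = 15L)
  claims <- make_claim("T", 10, amount_usd = 120)
  one <- quiet(summarize_member("T", members, claims, pairs))
  expect_equal(one$pre_pupm, 10)
  expect_error(quiet(summarize_member("X", members, claims, pairs)), "not in any")
})
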