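test_that("within-group change is a paired test on change scores", {
  s <- make_summaries(c(-5, -10, -15), "treated")
  est <- within_group_change(s)
  expect_equal(est$estimate, -10)
  expect_lt(est$t_stat, 0)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)

  s0 <- make_summaries(rep(0, 4), "treated")
  est0 <- within_group_change(s0)
  expect_equal(est0$estimate, 0)
  expect_equal(est0$p_value, 1)
  expect_error(within_group_change(make_summaries(1, "treated")))
})

test_that("the paired test holds its nominal type-I error", {
  set.seed(61)
  hits <- vapply(1:1000, function(i) {
    within_group_change(make_summaries(rnorm(30, 0, 40), "treated"))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("difference-in-differences follows the savings sign convention", {
  # comparison mean change +2, treated mean change -8 -> savings 10
  sc <- make_summaries(c(1, 3), "comparison")
  st <- make_summaries(c(-7, -9), "treated")
  est <- difference_in_differences(st, sc)
  expect_equal(est$estimate, 10)
  expect_true(est$ci_low <= 10 && 10 <= est$ci_high)

  # identical groups: savings 0, p = 1
  same <- make_summaries(c(-3, 1, 5), "treated")
  same_c <- make_summaries(c(-3, 1, 5), "comparison")
  est0 <- difference_in_differences(same, same_c)
  expect_equal(est0$estimate, 0)
  expect_equal(est0$p_value, 1)

  # swapping group labels negates the estimate exactly
  est_swap <- difference_in_differences(sc, st)
  expect_equal(est_swap$estimate, -est$estimate)
  expect_error(difference_in_differences(make_summaries(1, "treated"), sc))
})

test_that("p < alpha exactly when the CI excludes zero", {
  set.seed(62)
  for (i in 1:25) {
    st <- make_summaries(rnorm(20, -4, 10), "treated")
    sc <- make_summaries(rnorm(20, 0, 10), "comparison")
    est <- difference_in_differences(st, sc)
    expect_equal(est$p_value < est$alpha,
                 est$ci_low > 0 || est$ci_high < 0)
  }
})

test_that("category savings sum to the overall savings when uncapped", {
  cfg <- sim_config(n_members = 1500, seed = 42)
  sim <- simulate_cohort(cfg)
  man <- quiet(run_pipeline(members = sim$members, claims = sim$claims,
                            config = cfg, cap_percentile = NULL))
  st <- man$summaries[man$summaries$group == "treated", ]
  sc <- man$summaries[man$summaries$group == "comparison", ]
  tab <- category_breakdown(st, sc)
  cat_sum <- sum(tab$estimate[tab$label != "overall"])
  overall <- tab$estimate[tab$label == "overall"]
  expect_equal(cat_sum, overall, tolerance = 1e-6)
  expect_equal(overall, difference_in_differences(st, sc)$estimate)
  expect_error(category_breakdown(st, sc, categories = "spa_visits"), "unknown")
})

test_that("all-zero categories give zero estimates", {
  st <- make_summaries(c(-1, 2), "treated")
  sc <- make_summaries(c(0, 1), "comparison")
  for (cc in spend_categories()) {
    st[[paste0("pre_cat_", cc)]] <- 0; st[[paste0("post_cat_", cc)]] <- 0
    sc[[paste0("pre_cat_", cc)]] <- 0; sc[[paste0("post_cat_", cc)]] <- 0
  }
  tab <- category_breakdown(st, sc)
  expect_true(all(tab$estimate[tab$label != "overall"] == 0))
  expect_true(all(tab$p_value[tab$label != "overall"] == 1))
})

test_that("ED costs split fractionally by diagnosis probabilities", {
  tab <- tibble::tibble(
    diag_code = c("X1", "X2", "X3"),
    p_emergent = c(0.3, 1, 0.2), p_nonemergent = c(0.7, 0, 0.8),
    p_other = c(0, 0, 0)
  )
  one <- classify_ed(make_claim("A", 5, "ED", 100, ed_diag_code = "X1"), tab)
  expect_equal(one$emergent, 30)
  expect_equal(one$nonemergent, 70)

  full <- classify_ed(make_claim("A", 5, "ED", 80, ed_diag_code = "X2"), tab)
  expect_equal(full$emergent, 80)
  expect_equal(full$nonemergent, 0)

  two <- classify_ed(dplyr::bind_rows(
    make_claim("A", 5, "ED", 50, ed_diag_code = "X3"),
    make_claim("A", 6, "ED", 50, ed_diag_code = "X2")
  ), tab)
  # 50*(.2,.8) + 50*(1,0) = (60, 40)... aggregated per member
  expect_equal(two$emergent, 60)
  expect_equal(two$nonemergent, 40)

  unknown <- make_claim("A", 5, "ED", 40, ed_diag_code = "ZZZ")
  expect_warning(res <- classify_ed(unknown, tab), "unknown")
  expect_equal(res$other, 40)
  expect_error(classify_ed(unknown, tab, unknown = "error"), "ZZZ")
})

test_that("the shipped ED table is valid and rows sum to one", {
  tab <- ed_probability_table()
  expect_true(all(abs(tab$p_emergent + tab$p_nonemergent + tab$p_other - 1) < 1e-9))
  expect_gt(nrow(tab), 10)
})

test_that("annualization is a plain product", {
  expect_equal(annualize(10, 56816, 12), 6817920)
  expect_equal(annualize(10, 1, 12), 120)
  expect_equal(annualize(0, 56816, 12), 0)
  expect_error(annualize(-1, 10), "non-negative")
})

test_that("subgroup effects restrict to matched pairs of selected treated", {
  members <- dplyr::bind_rows(
    make_member("T1", chronic_count = 2L, enrolled = TRUE, enroll_month = 13L),
    make_member("T2", chronic_count = 2L, enrolled = TRUE, enroll_month = 13L),
    make_member("T3", chronic_count = 0L, enrolled = TRUE, enroll_month = 13L),
    make_member("C1"), make_member("C2"), make_member("C3")
  )
  pairs <- tibble::tibble(treated_id = c("T1", "T2", "T3"),
                          control_id = c("C1", "C2", "C3"),
                          anchor_month = 13L)
  summaries <- dplyr::bind_rows(
    make_summaries(c(-10, -20, -30), "treated"),
    make_summaries(c(1, 2, 3), "comparison")
  )
  summaries$member_id <- c("T1", "T2", "T3", "C1", "C2", "C3")

  all_in <- subgroup_effect(pairs, summaries, members, age >= 18)
  overall <- difference_in_differences(summaries[summaries$group == "treated", ],
                                       summaries[summaries$group == "comparison", ])
  expect_equal(all_in$estimate, overall$estimate)

  sub <- subgroup_effect(pairs, summaries, members, chronic_count >= 2)
  expect_equal(sub$estimate, mean(c(1, 2)) - mean(c(-10, -20)))
  expect_error(subgroup_effect(pairs, summaries, members, age > 99),
               "fewer than 2")
})

test_that("two-stratum effects are both recovered", {
  # one subgroup receives a -39 PUPM effect, the rest -10; the generic
  # subgroup estimator should recover both against their matched partners
  cfg <- sim_config(n_members = 12000, seed = 43, treatment_effect_pupm = -10)
  sim <- simulate_cohort(cfg)
  members <- sim$members
  flagged <- members$enrolled & members$comm_receptivity
  e_imp <- expected_monthly_spend(members, cfg)
  extra <- 29 / e_imp # shift flagged members' post impactable spend by -29 more
  cl <- sim$claims
  i <- match(cl$member_id, members$member_id)
  post <- !is.na(members$enroll_month[i]) & cl$month > members$enroll_month[i]
  scale_row <- ifelse(flagged[i] & post & !cl$nonimpactable & !cl$pregnancy_related,
                      pmax(0, 1 - extra[i]), 1)
  cl$amount_cents <- cl$amount_cents * scale_row
  man <- quiet(run_pipeline(members = members, claims = cl, config = cfg))
  sub39 <- subgroup_effect(man$pairs, man$summaries, members, comm_receptivity)
  sub10 <- subgroup_effect(man$pairs, man$summaries, members, !comm_receptivity)
  expect_true(sub39$ci_low <= 39 && 39 <= sub39$ci_high)
  expect_true(sub10$ci_low <= 10 && 10 <= sub10$ci_high)
})
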