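test_that("nearest neighbor works on the logit scale", {
  treated <- tibble::tibble(member_id = "t1", score = 0.5)
  controls <- tibble::tibble(member_id = c("c1", "c2"), score = c(0.4, 0.55))
  pairs <- greedy_match_segment(treated, controls)
  # |logit(.5)-logit(.4)| = 0.405 > |logit(.5)-logit(.55)| = 0.201
  expect_equal(pairs$control_id, "c2")
  expect_equal(pairs$distance, abs(log(0.55 / 0.45)), tolerance = 1e-12)
})

test_that("greedy order is descending treated score", {
  treated <- tibble::tibble(member_id = c("A", "B"), score = c(0.9, 0.8))
  controls <- tibble::tibble(member_id = c("x", "y"), score = c(0.85, 0.79))
  pairs <- greedy_match_segment(treated, controls)
  expect_equal(pairs$control_id[match(c("A", "B"), pairs$treated_id)], c("x", "y"))
})

test_that("greedy matching is 1:1, exhaustive, and order-invariant", {
  # identical score multisets: all matched at total distance 0
  t1 <- tibble::tibble(member_id = paste0("t", 1:5), score = c(.2, .3, .5, .7, .9))
  c1 <- tibble::tibble(member_id = paste0("c", 1:5), score = c(.9, .2, .7, .3, .5))
  p <- greedy_match_segment(t1, c1)
  expect_equal(nrow(p), 5)
  expect_equal(sum(p$distance), 0)
  # pigeonhole: more treated than controls
  p2 <- greedy_match_segment(t1, c1[1:3, ])
  expect_equal(nrow(p2), 3)
  expect_equal(anyDuplicated(p2$control_id), 0)
  # row order of inputs is irrelevant
  set.seed(1)
  p3 <- greedy_match_segment(t1[sample(5), ], c1[sample(5), ])
  expect_equal(dplyr::arrange(p, treated_id), dplyr::arrange(p3, treated_id))
})

test_that("greedy matching equals the brute-force oracle on small instances", {
  for (seed in 1:200) {
    inst <- random_match_instance(seed)
    got <- greedy_match_segment(inst$treated, inst$controls)
    want <- brute_force_greedy(inst$treated, inst$controls)
    expect_equal(dplyr::arrange(got, treated_id), dplyr::arrange(want, treated_id),
                 info = paste("seed", seed))
  }
})

# Roster where score := clip_prob(risk_score) lets tests pin scores exactly.
score_by_risk <- function(f) clip_prob(f$risk_score)

test_that("controls are consumed across months without replacement", {
  members <- dplyr::bind_rows(
    make_member("t1", enrolled = TRUE, enroll_month = 13L, risk_score = 0.50),
    make_member("t2", enrolled = TRUE, enroll_month = 14L, risk_score = 0.50),
    make_member("c_near", risk_score = 0.50),
    make_member("c_far", risk_score = 0.90)
  )
  res <- iterative_match(members, empty_claims(), score_by_risk)
  expect_equal(nrow(res$pairs), 2)
  m13 <- res$pairs[res$pairs$anchor_month == 13, ]
  m14 <- res$pairs[res$pairs$anchor_month == 14, ]
  expect_equal(m13$control_id, "c_near") # month 13 takes the nearest
  expect_equal(m14$control_id, "c_far")  # already consumed for month 14
  expect_equal(anyDuplicated(res$pairs$control_id), 0)
})

test_that("matching stays within segments and reports unmatched treated", {
  members <- dplyr::bind_rows(
    make_member("t_f", sex = "female", enrolled = TRUE, enroll_month = 13L),
    make_member("t_m", sex = "male", enrolled = TRUE, enroll_month = 13L),
    make_member("c_f", sex = "female", risk_score = 0.9) # no male control
  )
  res <- iterative_match(members, empty_claims(), score_by_risk)
  expect_equal(res$pairs$treated_id, "t_f")
  expect_equal(res$pairs$control_id, "c_f")
  expect_equal(res$pairs$sex, "female")
  expect_equal(res$unmatched_treated$member_id, "t_m")
  expect_match(res$unmatched_treated$reason, "segment")
})

test_that("duplicate member ids are rejected", {
  members <- dplyr::bind_rows(
    make_member("dup", enrolled = TRUE, enroll_month = 13L),
    make_member("dup"), make_member("c1")
  )
  expect_error(iterative_match(members, empty_claims(), score_by_risk),
               class = "pupmatch_input_error")
})

test_that("a caliper leaves distant treated unmatched", {
  members <- dplyr::bind_rows(
    make_member("t1", enrolled = TRUE, enroll_month = 13L, risk_score = 0.9),
    make_member("c1", risk_score = 0.1)
  )
  res <- iterative_match(members, empty_claims(), score_by_risk, caliper = 0.5)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$unmatched_treated$member_id, "t1")
})

test_that("SMD follows its definition, with binary and degenerate handling", {
  pairs <- tibble::tibble(
    treated_id = c("t1", "t2", "t3"), control_id = c("c1", "c2", "c3"),
    anchor_month = 15L
  )
  # continuous: means 1 vs 0, both group variances 4 -> pooled SD 2, SMD 0.5
  features <- tibble::tibble(
    member_id = c("t1", "t2", "t3", "c1", "c2", "c3"),
    x = c(-1, 1, 3, -2, 0, 2),
    flag = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), # identical proportions
    const = 1
  )
  b <- compute_balance(pairs, features)
  expect_equal(b$smd[b$feature == "x"], 0.5)
  expect_equal(b$smd[b$feature == "flag"], 0)
  expect_equal(b$smd[b$feature == "const"], 0) # zero SD, equal means
  expect_false(any(b$degenerate))

  # identical tables balance exactly and pass
  feat2 <- tibble::tibble(member_id = features$member_id,
                          y = rep(c(5, 7, 9), 2))
  b2 <- compute_balance(pairs, feat2)
  expect_true(all(b2$smd == 0))
  expect_true(attr(b2, "pass"))

  # degenerate: zero pooled SD with unequal means is flagged
  feat3 <- tibble::tibble(member_id = features$member_id,
                          z = c(1, 1, 1, 2, 2, 2))
  b3 <- compute_balance(pairs, feat3)
  expect_true(b3$degenerate[b3$feature == "z"])
})

test_that("matching shrinks imbalance on the selection-driving features", {
  cfg <- sim_config(n_members = 8000, seed = 31)
  sim <- simulate_cohort(cfg)
  eligible <- quiet(filter_eligible(sim$members, sim$claims))
  treated <- eligible[eligible$enrolled, ]
  pool <- eligible[!eligible$enrolled, ]
  feats <- build_features(eligible, sim$claims, anchor_month = 17)

  pre_pairs <- tibble::tibble( # naive "pairing": first pool members, unmatched
    treated_id = treated$member_id,
    control_id = pool$member_id[seq_len(nrow(treated))],
    anchor_month = 17L
  )
  pre_bal <- compute_balance(pre_pairs, feats)

  model <- fit_propensity(
    dplyr::bind_rows(feats[match(treated$member_id, feats$member_id), ],
                     feats[match(pool$member_id, feats$member_id), ]),
    c(rep(TRUE, nrow(treated)), rep(FALSE, nrow(pool))), seed = 31
  )
  res <- iterative_match(eligible, sim$claims, model)
  post_feats <- build_features(eligible, sim$claims, anchor_month = 17)
  post_bal <- compute_balance(res$pairs, post_feats)

  for (f in c("chronic_count", "risk_score", "pre_medical_pupm")) {
    expect_lt(abs(post_bal$smd[post_bal$feature == f]),
              abs(pre_bal$smd[pre_bal$feature == f]))
  }
  # full-run matching invariants: 1:1, no replacement
  expect_equal(anyDuplicated(res$pairs$treated_id), 0)
  expect_equal(anyDuplicated(res$pairs$control_id), 0)
  expect_equal(nrow(res$pairs) + nrow(res$unmatched_treated), nrow(treated))
})
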