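test_that("heart-rate categories follow the published cutoffs", {
  expect_equal(categorize_hr(65), "slow")
  expect_equal(categorize_hr(80), "mid")
  expect_equal(categorize_hr(100), "fast")
  expect_equal(categorize_hr(69.75), "mid")
  expect_equal(categorize_hr(94.25), "mid")
  expect_error(categorize_hr(0), "positive")
})

test_that("detection accuracy scores matched taps by the printed formula", {
  beats <- seq(0, 79)  # 80 beats at 60 bpm -> slow category
  full <- detection_accuracy(list(make_tap_trial(beats)))
  expect_equal(full$acc_d, 1)

  part <- detection_accuracy(list(make_tap_trial(beats, tapped = 1:60)))
  expect_equal(part$acc_d, 0.75)
  expect_equal(part$recorded, 80L)

  none <- detection_accuracy(list(list(tap_times = numeric(0),
                                       r_peak_times = seq(0, 69),
                                       trial_duration = 70)))
  expect_equal(none$acc_d, 0)
})

test_that("detection accuracy is invariant to trial order and matches 1:1", {
  t1 <- make_tap_trial(seq(0, 29), tapped = 1:20)
  t2 <- make_tap_trial(seq(0, 39), tapped = 1:35)
  expect_equal(detection_accuracy(list(t1, t2))$acc_d,
               detection_accuracy(list(t2, t1))$acc_d)

  # two taps near one beat: only one may count
  tr <- list(tap_times = c(0.30, 0.32), r_peak_times = c(0, 10),
             trial_duration = 11)
  expect_equal(detection_accuracy(list(tr))$corr_69 +
                 detection_accuracy(list(tr))$corr_betw +
                 detection_accuracy(list(tr))$corr_94, 1L)
})

test_that("counting accuracy reproduces the worked example and identities", {
  expect_equal(counting_accuracy(rep(80, 4), c(60, 70, 80, 90)), 0.875)
  expect_equal(counting_accuracy(rep(50, 4), rep(50, 4)), 1)
  expect_equal(counting_accuracy(rep(70, 4), rep(0, 4)), 0)
  # equals 1 iff counted = recorded everywhere
  expect_lt(counting_accuracy(rep(70, 4), c(70, 70, 70, 69)), 1)
  # unclipped below zero when counting wildly over
  expect_lt(counting_accuracy(rep(10, 4), rep(40, 4)), 0)
  expect_error(counting_accuracy(rep(80, 3), rep(80, 3)), "4 trials")
  expect_error(counting_accuracy(rep(0, 4), rep(1, 4)), ">= 1")
  # order invariance
  expect_equal(counting_accuracy(rep(80, 4), c(90, 80, 70, 60)), 0.875)
})

test_that("confidence ratings average and validate", {
  expect_equal(mean_confidence(c(5, 7)), 6)
  expect_equal(mean_confidence(c(9, 9, 9, 9)), 9)
  expect_equal(mean_confidence(c(1, 2, 3, 4)), 2.5)
  expect_error(mean_confidence(c(5, 10)), "1..9")
  expect_error(mean_confidence(c(5, 6.5)), "1..9")
})

test_that("awareness discrepancy normalizes within the cohort", {
  expect_equal(awareness_discrepancy(c(0, 0.5, 1), c(1, 5, 9)), c(0, 0, 0))
  aw <- awareness_discrepancy(c(1, 0.2, 0), c(1, 5, 9))
  expect_equal(aw[1], 1)  # cohort max accuracy, min confidence
  expect_error(awareness_discrepancy(c(0, 1), c(5, 5)), "confidence")
})

test_that("awareness is bounded and affine-invariant", {
  set.seed(31)
  for (i in 1:20) {
    acc <- rnorm(15); conf <- sample(1:9, 15, replace = TRUE) + rnorm(15, 0, .1)
    aw <- awareness_discrepancy(acc, conf)
    expect_true(all(aw >= 0 & aw <= 1))
    expect_equal(awareness_discrepancy(3 * acc - 7, 0.5 * conf + 2), aw)
  }
})

test_that("questionnaire scoring: aggregation, reverse coding, missing", {
  m <- maia_map()
  items <- unlist(m$subscales, use.names = FALSE)

  mid <- setNames(rep(2.5, 32), items)
  expect_true(all(score_questionnaire(mid, m) == 2.5))

  # reverse-coded item at scale max contributes 0 after the flip
  r <- setNames(rep(0, 32), items)
  r["item05"] <- 5
  sc <- score_questionnaire(r, m)
  expect_equal(unname(sc["M2"]), (0 + 5 + 5) / 3)  # item06/07 flip 0 -> 5

  # subscale isolation on a map without reverse-coded items
  plain <- m; plain$reverse <- character(0)
  iso <- setNames(rep(0, 32), items)
  iso[m$subscales$M6] <- 5
  sc2 <- score_questionnaire(iso, plain)
  expect_equal(unname(sc2["M6"]), 5)
  expect_true(all(sc2[setdiff(names(sc2), "M6")] == 0))

  expect_error(score_questionnaire(c(item99 = 3), m), "unknown item")
  expect_error(score_questionnaire(setNames(rep(9, 32), items), m), "range")

  # >20% missing in a subscale -> NA; <=20% -> aggregated from available
  miss <- mid[setdiff(items, m$subscales$M4[1:3])]   # 3/7 M4 items missing
  expect_true(is.na(score_questionnaire(miss, m)["M4"]))
  miss1 <- mid[setdiff(items, m$subscales$M4[1])]    # 1/7 missing
  expect_equal(unname(score_questionnaire(miss1, m)["M4"]), 2.5)
})

test_that("questionnaire scoring is idempotent and order-invariant", {
  b <- bpq_map()
  items <- unlist(b$subscales, use.names = FALSE)
  set.seed(12)
  resp <- setNames(sample(1:5, 22, replace = TRUE), items)
  s1 <- score_questionnaire(resp, b)
  expect_identical(s1, score_questionnaire(resp, b))
  expect_equal(score_questionnaire(resp[sample(names(resp))], b), s1)
  # sum aggregation spans the achievable range
  expect_equal(unname(score_questionnaire(setNames(rep(5, 22), items), b)),
               c(60, 30, 20))
})
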