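test_that("body-image discrepancy follows the BMI formulas", {
  b <- body_image_delta(70, 1.75, pfrs_bmi_values(), 5)
  expect_equal(b$bmi_r, 70 / 1.75^2)

  map <- c(25, 27)
  expect_equal(body_image_delta(24 * 1.75^2, 1.75, map, c(1, 2))$delta_ar,
               2, tolerance = 1e-12)
  same <- body_image_delta(22.5 * 1.6^2, 1.6, c(20, 22.5, 25), 2)
  expect_equal(same$delta_ar, 0, tolerance = 1e-12)
  expect_error(body_image_delta(70, 1.75, map, integer(0)), "no perceived")
})

test_that("percent correct", {
  expect_equal(percent_correct(18, 20), 90)
  expect_equal(percent_correct(0, 20), 0)
  expect_equal(percent_correct(20, 20), 100)
  expect_error(percent_correct(3, 0), "n_total")
  expect_error(percent_correct(21, 20), "n_correct")
})

test_that("race-model AUC on deterministic and race-consistent data", {
  # all-degenerate toy: full violation at every grid point
  toy <- structure(list(A = rep(300, 20), T = rep(300, 20), V = rep(300, 20),
                        AT = rep(200, 20), AV = rep(250, 20),
                        VT = rep(250, 20)),
                   class = "rt_condition_table")
  res <- race_model_auc(toy, "AT")
  expect_equal(res$violation, rep(1, 20))
  expect_equal(res$auc, 0.95)

  # actual CDF below the bound everywhere -> zero
  slow <- structure(list(A = rep(100, 20), T = rep(100, 20),
                         AT = rep(400, 20), V = rep(100, 20),
                         AV = rep(400, 20), VT = rep(400, 20)),
                    class = "rt_condition_table")
  expect_equal(race_model_auc(slow, "AT")$auc, 0)

  rt <- simulate_rt_conditions(n_trials = 5000, seed = 13)
  expect_lte(race_model_auc(rt, "AT")$auc, 0.01)

  expect_error(race_model_auc(list(A = 1:20, T = 1:20), "AT"), "missing")
  expect_error(race_model_auc(list(A = 1:20, T = 1:20, AT = 1:5), "AT"),
               "fewer than 10")
})

test_that("race-model AUC is invariant to a common time shift", {
  rt <- simulate_rt_conditions(coactivation_gain = 60, n_trials = 400,
                               seed = 17)
  shifted <- structure(lapply(unclass(rt), function(v) v + 250),
                       class = "rt_condition_table")
  for (pair in c("AT", "AV", "VT")) {
    expect_equal(race_model_auc(shifted, pair)$auc,
                 race_model_auc(rt, pair)$auc, tolerance = 1e-12)
  }
})

test_that("Gaussian-bump fitter recovers simultaneity-window parameters", {
  lv <- seq(-200, 200, by = 40)
  tab <- simulate_psychometric_trials(lv, pse = 0, sigma = 50, 200,
                                      form = "gaussian_bump", seed = 2)
  f <- fit_gaussian_bump(tab)
  expect_gte(f$jnd_sj, 42.5)
  expect_lte(f$jnd_sj, 57.5)

  tab20 <- simulate_psychometric_trials(lv, pse = 20, sigma = 60, 200,
                                        form = "gaussian_bump", seed = 3)
  expect_lt(abs(fit_gaussian_bump(tab20)$fit$mu - 20), 10)

  zero <- tab; zero$n_positive <- 0L
  expect_error(fit_gaussian_bump(zero), "zero")
})

test_that("Spearman-Karber midpoint estimator", {
  tab <- data.frame(stimulus_level = 1:5, n_presented = 10,
                    n_positive = c(0, 0, 5, 10, 10))
  expect_equal(spearman_karber_pse(tab), 3.0)

  step <- data.frame(stimulus_level = 1:5, n_presented = 10,
                     n_positive = c(0, 0, 10, 10, 10))
  expect_equal(spearman_karber_pse(step), 2.5)

  sim <- simulate_psychometric_trials(seq(1, 7, 0.5), pse = 4, sigma = 1,
                                      n_per_level = 500, seed = 6)
  expect_lt(abs(spearman_karber_pse(sim) - 4), 0.2)

  expect_error(spearman_karber_pse(tab[1:2, ]), "3 stimulus levels")
})

test_that("Spearman-Karber agrees with the fitted-Gaussian location", {
  for (s in 1:10) {
    tab <- simulate_psychometric_trials(seq(-90, 90, 15), pse = 10,
                                        sigma = 30, 200, seed = 100 + s)
    pse <- spearman_karber_pse(tab)
    fit <- fit_cumulative_gaussian(tab)$fit
    expect_lt(abs(pse - fit$mu), 0.05 * fit$sigma)
  }
})

test_that("cumulative-Gaussian fitter: recovery and the 75% JND convention", {
  lv <- seq(-120, 120, by = 30)
  tab <- simulate_psychometric_trials(lv, pse = 0, sigma = 40, 200, seed = 4)
  f <- fit_cumulative_gaussian(tab)
  expect_lt(abs(f$jnd - qnorm(0.75) * 40) / (qnorm(0.75) * 40), 0.15)

  # exact p = 0.25 / 0.75 at -27 / +27 pins the JND at 27
  sigma27 <- 27 / qnorm(0.75)
  exact <- exact_cg_table(c(-81, -27, 27, 81), mu = 0, sigma = sigma27)
  expect_lt(abs(fit_cumulative_gaussian(exact)$jnd - 27) / 27, 0.05)

  expect_error(fit_cumulative_gaussian(
    exact_cg_table(c(10, 20, 30, 40), mu = -200, sigma = 10)),
    "0.5")
})

test_that("TOJ JND is location- and mirror-invariant", {
  lv <- seq(-120, 120, by = 30)
  tab <- simulate_psychometric_trials(lv, pse = 0, sigma = 40, 300, seed = 8)
  base <- fit_cumulative_gaussian(tab)$jnd

  shift <- tab
  shift$stimulus_level <- shift$stimulus_level + 55
  expect_equal(fit_cumulative_gaussian(shift)$jnd, base, tolerance = 1e-6)

  flip <- tab[rev(seq_len(nrow(tab))), ]
  flip$stimulus_level <- -flip$stimulus_level
  flip$n_positive <- flip$n_presented - flip$n_positive
  expect_equal(fit_cumulative_gaussian(flip)$jnd, base, tolerance = 1e-6)
})

test_that("perfect separation falls back to ridge probit with a flag", {
  sep <- data.frame(stimulus_level = c(-40, -20, 20, 40), n_presented = 50,
                    n_positive = c(0L, 0L, 50L, 50L))
  f <- fit_cumulative_gaussian(sep)
  expect_true(f$fit$fallback)
  expect_gt(f$jnd, 0)
})

test_that("sum of confusion measures curve divergence on the grid", {
  lv <- seq(-200, 200, 40)
  tab <- simulate_psychometric_trials(lv, 0, 50, 400, seed = 9)
  f <- fit_cumulative_gaussian(tab)$fit
  expect_equal(sum_of_confusion(f, f), 0)

  # analytic oracle: two centred curves with different spreads
  grid <- seq(-400, 400, 10)
  f2 <- fit_cumulative_gaussian(exact_cg_table(lv, 0, 120))$fit
  expected <- sum(abs(pnorm((grid - f2$mu) / f2$sigma) -
                        pnorm((grid - f$mu) / f$sigma)))
  expect_equal(sum_of_confusion(f, f2, grid), expected, tolerance = 1e-8)

  # widening the crossed sigma strictly increases SC
  sc <- vapply(c(60, 90, 130, 200), function(s) {
    fc <- fit_cumulative_gaussian(exact_cg_table(lv, 0, s))$fit
    sum_of_confusion(f, fc, grid)
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
  expect_true(all(sc >= 0))
})

test_that("mental-rotation slope from per-angle medians", {
  tr <- data.frame(angle = rep(c(0, 45, 90, 135, 180), each = 3))
  tr$rt <- 500 + 2 * tr$angle
  tr$correct <- TRUE
  expect_equal(mental_rotation_slope(tr)$mre, 2)

  tr$rt <- 650
  expect_equal(mental_rotation_slope(tr)$mre, 0)

  set.seed(14)
  noisy <- data.frame(angle = rep(c(0, 45, 90, 135, 180), each = 20))
  noisy$rt <- 450 + 1.5 * noisy$angle + rnorm(nrow(noisy), sd = 30)
  noisy$correct <- TRUE
  expect_lt(abs(mental_rotation_slope(noisy)$mre - 1.5), 0.3)

  one <- data.frame(angle = 90, rt = 600, correct = TRUE)
  expect_error(mental_rotation_slope(one), "2 distinct angles")
})

test_that("RT-threshold adapter yields a monotone psychometric table", {
  set.seed(15)
  rts <- lapply(c(550, 520, 480, 440, 410), function(m) rnorm(80, m, 25))
  names(rts) <- c(10, 25, 40, 55, 70)
  tab <- pps_rt_adapter(rts)
  expect_s3_class(tab, "psychometric_table")
  prop <- tab$n_positive / tab$n_presented
  expect_true(all(diff(prop) >= 0))
  pse <- spearman_karber_pse(tab)
  expect_gt(pse, 10); expect_lt(pse, 70)
})
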