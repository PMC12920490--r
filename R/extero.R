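#' Body-image discrepancy from silhouette ratings
#'
#' Real BMI is weight / height^2; perceived-actual BMI is the mean of the
#' silhouette-scale BMI values the participant selected as their own
#' physique. The score is perceived minus real.
#'
#' @param weight kg (> 0); @param height m (> 0).
#' @param silhouette_bmi_values ordered numeric map, silhouette index -> BMI.
#' @param perceived_actual_ratings integer indices into the map (>= 1 rating).
#' @return List: `delta_ar`, `bmi_r`, `bmi_a`.
#' @export
body_image_delta <- function(weight, height, silhouette_bmi_values,
                             perceived_actual_ratings) {
  stopifnot(weight > 0, height > 0)
  if (length(perceived_actual_ratings) == 0) {
    stop("no perceived-actual silhouette ratings", call. = FALSE)
  }
  if (any(perceived_actual_ratings < 1 |
          perceived_actual_ratings > length(silhouette_bmi_values))) {
    stop("silhouette rating outside the map", call. = FALSE)
  }
  bmi_r <- weight / height^2
  bmi_a <- mean(silhouette_bmi_values[perceived_actual_ratings])
  list(delta_ar = bmi_a - bmi_r, bmi_r = bmi_r, bmi_a = bmi_a)
}

#' Default silhouette-to-BMI values for a 10-image figure rating scale
#'
#' Editable synthetic defaults spanning the emaciated-to-obese range; replace
#' with the calibration of the scale actually administered.
#' @export
pfrs_bmi_values <- function() {
  as.numeric(utils::read.csv(
    system.file("extdata", "pfrs_bmi_synthetic.csv", package = "bodysense",
                mustWork = TRUE))$bmi)
}

#' Percentage of correct trials
#' @param n_correct,n_total counts, `0 <= n_correct <= n_total`, `n_total >= 1`.
#' @return percentage in \[0, 100\].
#' @export
percent_correct <- function(n_correct, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1", call. = FALSE)
  if (any(n_correct < 0 | n_correct > n_total)) {
    stop("n_correct must lie in [0, n_total]", call. = FALSE)
  }
  100 * n_correct / n_total
}

#' Race-model violation area for one bimodal condition
#'
#' Empirical CDFs of the bimodal condition and its two unimodal parents are
#' evaluated at the bimodal condition's 5th-100th percentiles (steps of 5,
#' linear-interpolated quantiles). The race-model bound is
#' min(1, CDF_uni1 + CDF_uni2); positive excess of the actual CDF over the
#' bound is integrated over the percentile axis (as fractions) by the
#' trapezoidal rule.
#'
#' @param rts an `rt_condition_table` (named list of RT vectors).
#' @param pair `"AT"`, `"AV"` or `"VT"`.
#' @return List: `auc`, `percentiles`, `violation` (per grid point).
#' @export
race_model_auc <- function(rts, pair = c("AT", "AV", "VT")) {
  pair <- match.arg(pair)
  parents <- list(AT = c("A", "T"), AV = c("A", "V"), VT = c("V", "T"))[[pair]]
  need <- c(pair, parents)
  missing <- setdiff(need, names(rts))
  if (length(missing) > 0) {
    stop("missing condition(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  short <- need[vapply(rts[need], length, integer(1)) < 10]
  if (length(short) > 0) {
    stop("condition(s) with fewer than 10 RTs: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  p <- seq(0.05, 1, by = 0.05)
  q <- stats::quantile(rts[[pair]], probs = p, type = 7, names = FALSE)
  actual <- stats::ecdf(rts[[pair]])(q)
  predicted <- pmin(1, stats::ecdf(rts[[parents[1]]])(q) +
                       stats::ecdf(rts[[parents[2]]])(q))
  viol <- pmax(0, actual - predicted)
  auc <- sum(diff(p) * (viol[-1] + viol[-length(viol)]) / 2)
  list(auc = auc, percentiles = p, violation = viol)
}

# Binomial negative log-likelihood of a psychometric curve on a table.
psy_nll <- function(prob, tab) {
  eps <- 1e-9
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -sum(tab$n_positive * log(prob) +
         (tab$n_presented - tab$n_positive) * log(1 - prob))
}

new_gaussian_fit <- function(mu, sigma, amplitude, lapse, form, deviance,
                             converged, fallback = FALSE) {
  structure(list(mu = mu, sigma = sigma, amplitude = amplitude,
                 lapse = lapse, form = form, deviance = deviance,
                 converged = converged, fallback = fallback),
            class = "gaussian_fit")
}

#' Predict response probabilities from a fitted psychometric curve
#' @param fit a `gaussian_fit`; @param x stimulus levels.
#' @export
predict_psychometric <- function(fit, x) {
  core <- switch(fit$form,
    cumulative_gaussian = stats::pnorm((x - fit$mu) / fit$sigma),
    gaussian_bump = exp(-(x - fit$mu)^2 / (2 * fit$sigma^2))
  )
  fit$lapse / 2 + (1 - fit$lapse) * fit$amplitude * core
}

#' Fit a Gaussian-bump psychometric curve (simultaneity judgments)
#'
#' Maximum-likelihood (binomial) fit of
#' p(positive) = amplitude * exp(-(x - mu)^2 / (2 sigma^2)).
#' The just-noticeable difference of the simultaneity task is the fitted
#' sigma.
#'
#' @param table a `psychometric_table` with >= 5 levels.
#' @return List: `fit` (a `gaussian_fit`) and `jnd_sj` (= sigma).
#' @export
fit_gaussian_bump <- function(table) {
  stopifnot(nrow(table) >= 5)
  if (sum(table$n_positive) == 0) {
    stop("all responses zero: bump amplitude degenerate", call. = FALSE)
  }
  x <- table$stimulus_level
  p_obs <- table$n_positive / table$n_presented
  w <- pmax(p_obs, 1e-6)
  mu0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 4
  par0 <- c(stats::qlogis(min(max(max(p_obs), 0.05), 0.99)), mu0, log(s0))
  nll <- function(par) {
    amp <- stats::plogis(par[1])
    prob <- amp * exp(-(x - par[2])^2 / (2 * exp(2 * par[3])))
    psy_nll(prob, table)
  }
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 500))
  if (opt$convergence != 0) {
    stop("Gaussian-bump fit did not converge (code ", opt$convergence,
         "); levels = ", nrow(table), call. = FALSE)
  }
  # saturated-model deviance
  dev <- 2 * (opt$value - psy_nll(p_obs, table))
  fit <- new_gaussian_fit(mu = opt$par[2], sigma = exp(opt$par[3]),
                          amplitude = stats::plogis(opt$par[1]), lapse = 0,
                          form = "gaussian_bump", deviance = dev,
                          converged = TRUE)
  list(fit = fit, jnd_sj = fit$sigma)
}

#' Fit a cumulative-Gaussian psychometric curve (temporal-order judgments)
#'
#' Binomial maximum-likelihood fit of p(positive) = Phi((x - mu) / sigma).
#' The JND is the 75%-25% half-spread, `qnorm(0.75) * sigma`. On
#' non-convergence or perfect separation the fit falls back to a weakly
#' ridge-penalized probit regression and sets `fallback = TRUE`.
#'
#' @param table a `psychometric_table` with >= 4 levels whose observed
#'   proportions span both sides of 0.5.
#' @param ridge penalty used only by the fallback (default 1e-3).
#' @return List: `fit` (a `gaussian_fit`) and `jnd`.
#' @export
fit_cumulative_gaussian <- function(table, ridge = 1e-3) {
  stopifnot(nrow(table) >= 4)
  x <- table$stimulus_level
  p_obs <- table$n_positive / table$n_presented
  if (min(p_obs) > 0.5 || max(p_obs) < 0.5) {
    stop("responses do not span both sides of 0.5", call. = FALSE)
  }
  # probit GLM start values
  start_fit <- suppressWarnings(
    stats::glm(cbind(table$n_positive, table$n_presented - table$n_positive)
               ~ x, family = stats::binomial(link = "probit"))
  )
  b <- stats::coef(start_fit)
  mu0 <- if (is.finite(b[2]) && b[2] > 0) -b[1] / b[2] else stats::median(x)
  s0 <- if (is.finite(b[2]) && b[2] > 0) 1 / b[2] else diff(range(x)) / 4
  nll <- function(par) {
    prob <- stats::pnorm((x - par[1]) / exp(par[2]))
    psy_nll(prob, table)
  }
  separated <- all(p_obs %in% c(0, 1))
  opt <- if (separated) NULL else
    try(stats::optim(c(mu0, log(s0)), nll, method = "BFGS",
                     control = list(maxit = 500)), silent = TRUE)
  min_sigma <- min(diff(sort(unique(x)))) / 100
  ok <- !separated && !inherits(opt, "try-error") && opt$convergence == 0 &&
    exp(opt$par[2]) > min_sigma && is.finite(opt$value)
  if (ok) {
    dev <- 2 * (opt$value - psy_nll(p_obs, table))
    fit <- new_gaussian_fit(mu = opt$par[1], sigma = exp(opt$par[2]),
                            amplitude = 1, lapse = 0,
                            form = "cumulative_gaussian", deviance = dev,
                            converged = TRUE)
  } else {
    # ridge-penalized probit on (intercept, slope)
    xs <- scale(x)
    pen_nll <- function(ab) {
      prob <- stats::pnorm(ab[1] + ab[2] * as.numeric(xs))
      psy_nll(prob, table) + ridge * sum(ab^2)
    }
    opt2 <- stats::optim(c(0, 1), pen_nll, method = "BFGS",
                         control = list(maxit = 500))
    slope <- opt2$par[2] / attr(xs, "scaled:scale")
    inter <- opt2$par[1] - opt2$par[2] * attr(xs, "scaled:center") /
      attr(xs, "scaled:scale")
    fit <- new_gaussian_fit(mu = -inter / slope, sigma = 1 / slope,
                            amplitude = 1, lapse = 0,
                            form = "cumulative_gaussian",
                            deviance = NA_real_, converged = TRUE,
                            fallback = TRUE)
  }
  list(fit = fit, jnd = stats::qnorm(0.75) * fit$sigma)
}

# Weighted pool-adjacent-violators: smallest monotone non-decreasing fit.
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; cnt <- rep(1L, n)
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-12) {
      nw <- wt[i] + wt[i + 1]
      nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / nw
      val <- c(val[seq_len(i - 1)], nv, val[-seq_len(i + 1)])
      wt <- c(wt[seq_len(i - 1)], nw, wt[-seq_len(i + 1)])
      cnt <- c(cnt[seq_len(i - 1)], cnt[i] + cnt[i + 1], cnt[-seq_len(i + 1)])
      i <- max(1L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  rep(val, cnt)
}

#' Spearman-Karber estimate of the point of subjective equality
#'
#' Proportions are made monotone by weighted pool-adjacent-violators, then
#' extended to 0 and 1 at one level-spacing beyond each end, and the PSE is
#' the probability-weighted midpoint sum
#' `sum_i ((x_i + x_{i+1}) / 2) * (p_{i+1} - p_i)`.
#'
#' @param table a `psychometric_table` with >= 3 levels.
#' @return `pse_pps`, a single number in stimulus units.
#' @export
spearman_karber_pse <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 stimulus levels", call. = FALSE)
  ord <- order(table$stimulus_level)
  x <- table$stimulus_level[ord]
  p <- (table$n_positive / table$n_presented)[ord]
  p <- pava(p, table$n_presented[ord])
  p <- pmin(pmax(p, 0), 1)
  k <- length(x)
  x_ext <- c(x[1] - (x[2] - x[1]), x, x[k] + (x[k] - x[k - 1]))
  p_ext <- c(0, p, 1)
  mid <- (x_ext[-length(x_ext)] + x_ext[-1]) / 2
  sum(mid * diff(p_ext))
}

#' Sum of confusion between crossed- and uncrossed-hands TOJ curves
#'
#' Evaluates both fitted psychometric curves on a fixed symmetric SOA grid
#' and sums the absolute differences; zero iff the curves coincide on the
#' grid.
#'
#' @param fit_uncrossed,fit_crossed `gaussian_fit`s.
#' @param grid SOA grid in ms (default -400..400 step 10).
#' @return `sc`, a non-negative number.
#' @export
sum_of_confusion <- function(fit_uncrossed, fit_crossed,
                             grid = seq(-400, 400, by = 10)) {
  stopifnot(inherits(fit_uncrossed, "gaussian_fit"),
            inherits(fit_crossed, "gaussian_fit"),
            length(grid) >= 1)
  sum(abs(predict_psychometric(fit_crossed, grid) -
            predict_psychometric(fit_uncrossed, grid)))
}

#' Mental-rotation efficiency slope from laterality-judgment trials
#'
#' Per rotation angle, the median RT of correct trials is regressed on
#' angle by ordinary least squares; the slope (ms/degree) indexes mental
#' rotation cost (smaller = more efficient).
#'
#' @param trials data.frame with columns `angle` (degrees), `rt` (ms),
#'   `correct` (logical or 0/1).
#' @return List: `mre` (slope, ms/degree), `intercept`, `medians`
#'   (per-angle correct-trial median RTs).
#' @export
mental_rotation_slope <- function(trials) {
  stopifnot(all(c("angle", "rt", "correct") %in% names(trials)))
  ok <- trials[as.logical(trials$correct), , drop = FALSE]
  if (nrow(ok) == 0 || length(unique(ok$angle)) < 2) {
    stop("need correct trials at >= 2 distinct angles", call. = FALSE)
  }
  med <- stats::aggregate(rt ~ angle, data = ok, FUN = stats::median)
  fit <- stats::lm(rt ~ angle, data = med)
  list(mre = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       medians = med)
}

#' Threshold-based adapter from per-level RT lists to response proportions
#'
#' The peripersonal-space task records tactile RTs at graded stimulus
#' distances; the boundary estimator, however, operates on proportions. This
#' adapter declares a trial "positive" (facilitated) when its RT falls below
#' a threshold -- by default the grand median across levels -- and tabulates
#' positives per level. It is a documented stand-in for converting RT
#' facilitation into a psychometric table, not a canonical procedure.
#'
#' @param rt_by_level named list: stimulus level (coercible to numeric) ->
#'   RT vector.
#' @param threshold ms; default grand median over all trials.
#' @return A `psychometric_table`.
#' @export
pps_rt_adapter <- function(rt_by_level, threshold = NULL) {
  stopifnot(length(rt_by_level) >= 1)
  lv <- as.numeric(names(rt_by_level))
  if (any(is.na(lv))) stop("level names must be numeric", call. = FALSE)
  if (is.null(threshold)) threshold <- stats::median(unlist(rt_by_level))
  tab <- data.frame(
    stimulus_level = lv,
    n_presented = vapply(rt_by_level, length, integer(1)),
    n_positive = vapply(rt_by_level, function(r) sum(r < threshold),
                        integer(1))
  )
  tab <- tab[order(tab$stimulus_level), ]
  rownames(tab) <- NULL
  structure(tab, class = c("psychometric_table", "data.frame"))
}
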