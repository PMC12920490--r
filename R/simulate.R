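#' Simulate an R-peak train with planted oscillatory RR structure
#'
#' Beat times follow the instantaneous interval rule
#' RR(t) = 60/mean_hr + lf_amp*sin(2*pi*lf_freq*t) + hf_amp*sin(2*pi*hf_freq*t),
#' i.e. a constant-rate train modulated by one low-frequency and one
#' high-frequency sinusoid. With both amplitudes zero all intervals equal
#' 60/mean_hr exactly, which makes the downstream heart-rate and spectral
#' estimators testable against closed forms.
#'
#' @param duration recording length in seconds (> 0).
#' @param mean_hr mean heart rate in beats/min, in (30, 200).
#' @param lf_amp,hf_amp modulation amplitudes in seconds (>= 0).
#' @param lf_freq,hf_freq modulation frequencies in Hz.
#' @param start time of the first beat (s, default 1 so a synthesized trace
#'   has clean pre-beat baseline).
#' @return An object of class `r_peak_series`: list with `times` (s, strictly
#'   increasing) and the generating parameters.
#' @export
#' @examples
#' rr <- simulate_rr_series(duration = 60, mean_hr = 60)
#' diff(rr$times)[1:3]  # all exactly 1 s
simulate_rr_series <- function(duration, mean_hr,
                               lf_amp = 0, hf_amp = 0,
                               lf_freq = 0.1, hf_freq = 0.25, start = 1) {
  stopifnot(duration > 0, mean_hr > 30, mean_hr < 200,
            lf_amp >= 0, hf_amp >= 0, start >= 0)
  base <- 60 / mean_hr
  if (lf_amp + hf_amp >= base) {
    stop("modulation amplitudes too large: RR would become non-positive",
         call. = FALSE)
  }
  times <- numeric(0)
  t <- start
  while (t <= start + duration) {
    times <- c(times, t)
    rr <- base + lf_amp * sin(2 * pi * lf_freq * t) +
      hf_amp * sin(2 * pi * hf_freq * t)
    if (rr <= 0) {
      stop("instantaneous RR non-positive at t = ", signif(t, 4), call. = FALSE)
    }
    t <- t + rr
  }
  structure(
    list(times = times, mean_hr = mean_hr,
         lf_amp = lf_amp, hf_amp = hf_amp,
         lf_freq = lf_freq, hf_freq = hf_freq),
    class = "r_peak_series"
  )
}

# Mexican-hat (Ricker) QRS-like kernel, total width ~80 ms.
qrs_kernel <- function(sampling_rate, width = 0.08) {
  half <- width / 2
  t <- seq(-half, half, by = 1 / sampling_rate)
  s <- width / 6
  (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))
}

#' Synthesize an ECG-like trace from planted R-peak times
#'
#' Places a fixed Mexican-hat kernel (80 ms wide) at every planted beat and
#' optionally adds white Gaussian noise. The planted times are kept as
#' metadata so detector tests can compare recovered against true peaks.
#'
#' @param rr an `r_peak_series` (or numeric vector of beat times in s).
#' @param sampling_rate Hz, >= 250.
#' @param noise_sd Gaussian noise standard deviation in kernel-amplitude
#'   units (kernel peak is 1).
#' @param duration trace length in s; defaults to last beat + 1 s.
#' @param seed integer seed for the noise stream.
#' @return A `sampled_signal`: list with `samples`, `sampling_rate`,
#'   `start_time` and attribute-like field `planted_r_times`.
#' @export
simulate_ecg_trace <- function(rr, sampling_rate = 500, noise_sd = 0,
                               duration = NULL, seed = 1L) {
  times <- if (inherits(rr, "r_peak_series")) rr$times else as.numeric(rr)
  stopifnot(sampling_rate >= 250, noise_sd >= 0)
  if (is.null(duration)) {
    duration <- if (length(times) > 0) max(times) + 1 else 1
  }
  n <- ceiling(duration * sampling_rate)
  x <- numeric(n)
  if (length(times) > 0) {
    kern <- qrs_kernel(sampling_rate)
    halfk <- (length(kern) - 1L) %/% 2L
    centers <- round(times * sampling_rate) + 1L
    for (c0 in centers) {
      idx <- (c0 - halfk):(c0 + halfk)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + kern[ok]
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  structure(
    list(samples = x, sampling_rate = sampling_rate, start_time = 0,
         planted_r_times = times),
    class = "sampled_signal"
  )
}

#' Simulate a respiration-like trace
#'
#' Sinusoidal breathing at a given rate with optional cycle-amplitude
#' variability and additive noise; used to exercise breath counting.
#'
#' @param duration s; @param sampling_rate Hz; @param breaths_per_min rate;
#' @param amp_sd s.d. of per-cycle amplitude multipliers (lognormal);
#' @param noise_sd additive Gaussian noise s.d.; @param seed integer.
#' @return a `sampled_signal`.
#' @export
simulate_respiration_trace <- function(duration, sampling_rate = 50,
                                       breaths_per_min = 15,
                                       amp_sd = 0, noise_sd = 0, seed = 1L) {
  stopifnot(duration > 0, breaths_per_min > 0)
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = 1 / sampling_rate)
  f <- breaths_per_min / 60
  x <- sin(2 * pi * f * t)
  if (amp_sd > 0) {
    cycle <- floor(t * f)
    amps <- exp(stats::rnorm(max(cycle) + 1, sd = amp_sd))
    x <- x * amps[cycle + 1]
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), sd = noise_sd)
  structure(
    list(samples = x, sampling_rate = sampling_rate, start_time = 0),
    class = "sampled_signal"
  )
}

# Psychometric response probability for the two supported function forms.
psychometric_prob <- function(x, pse, sigma, form, lapse) {
  core <- switch(form,
    cumulative_gaussian = stats::pnorm((x - pse) / sigma),
    gaussian_bump = exp(-(x - pse)^2 / (2 * sigma^2)),
    stop("unknown function form: ", form, call. = FALSE)
  )
  lapse / 2 + (1 - lapse) * core
}

#' Simulate binomial psychometric-task trials
#'
#' Per stimulus level, the number of "positive" responses is drawn
#' Binomial(n_per_level, p(level)), with p either a cumulative Gaussian
#' (temporal-order / detection style) or a Gaussian bump (simultaneity
#' style), lapse-scaled as p = lapse/2 + (1 - lapse) * core.
#'
#' @param stimulus_levels strictly increasing numeric vector (ms or cm).
#' @param pse location parameter; @param sigma spread (> 0).
#' @param n_per_level trials per level (>= 1).
#' @param form `"cumulative_gaussian"` or `"gaussian_bump"`.
#' @param lapse lapse rate in \[0, 0.5).
#' @param seed integer.
#' @return A `psychometric_table` data.frame with columns
#'   `stimulus_level`, `n_presented`, `n_positive`.
#' @export
simulate_psychometric_trials <- function(stimulus_levels, pse, sigma,
                                         n_per_level,
                                         form = c("cumulative_gaussian",
                                                  "gaussian_bump"),
                                         lapse = 0, seed = 1L) {
  form <- match.arg(form)
  stopifnot(length(stimulus_levels) >= 1,
            all(diff(stimulus_levels) > 0),
            sigma > 0, n_per_level >= 1)
  if (lapse < 0 || lapse >= 0.5) {
    stop("lapse rate must lie in [0, 0.5)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- psychometric_prob(stimulus_levels, pse, sigma, form, lapse)
  k <- stats::rbinom(length(stimulus_levels), n_per_level, p)
  structure(
    data.frame(stimulus_level = stimulus_levels,
               n_presented = n_per_level,
               n_positive = k),
    class = c("psychometric_table", "data.frame")
  )
}

#' Simulate reaction times for the six multisensory conditions
#'
#' Unimodal RTs (A, T, V) are ex-Gaussian. With `coactivation_gain = 0` each
#' bimodal RT is the minimum of two fresh independent unimodal draws, so the
#' race-model inequality holds by construction; a positive gain is subtracted
#' from every bimodal RT, forcing a violation.
#'
#' @param unimodal_means named vector `c(A=, T=, V=)` of mean RTs (ms).
#' @param coactivation_gain ms subtracted from bimodal RTs (>= 0).
#' @param n_trials per condition (>= 1).
#' @param seed integer.
#' @param sigma,tau ex-Gaussian spread parameters (ms); the Gaussian mean is
#'   adjusted so that the ex-Gaussian mean equals the requested mean.
#' @return An `rt_condition_table`: named list of six RT vectors
#'   (A, T, V, AT, AV, VT), in ms.
#' @export
simulate_rt_conditions <- function(unimodal_means = c(A = 420, T = 400, V = 450),
                                   coactivation_gain = 0, n_trials = 100,
                                   seed = 1L, sigma = 50, tau = 80) {
  stopifnot(n_trials >= 1, coactivation_gain >= 0,
            all(c("A", "T", "V") %in% names(unimodal_means)))
  set.seed(as.integer(seed))
  draw_uni <- function(cond, n) {
    mu <- unimodal_means[[cond]] - tau
    stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
  }
  out <- list(
    A = draw_uni("A", n_trials),
    T = draw_uni("T", n_trials),
    V = draw_uni("V", n_trials)
  )
  pairs <- list(AT = c("A", "T"), AV = c("A", "V"), VT = c("V", "T"))
  for (nm in names(pairs)) {
    d1 <- draw_uni(pairs[[nm]][1], n_trials)
    d2 <- draw_uni(pairs[[nm]][2], n_trials)
    out[[nm]] <- pmax(pmin(d1, d2) - coactivation_gain, 1)
  }
  structure(out, class = "rt_condition_table")
}

# Default per-variable sampling distributions for the cohort generator:
# plausible scales for each battery measure (mean, sd, lower, upper).
default_predictor_distributions <- function() {
  d <- rbind(
    acc_d = c(0.55, 0.20, 0, 1),       acc_c = c(0.65, 0.20, -0.5, 1),
    con_d = c(5.5, 1.5, 1, 9),         con_c = c(5.5, 1.5, 1, 9),
    aw_d = c(0.25, 0.15, 0, 1),        aw_c = c(0.25, 0.15, 0, 1),
    maia_m1 = c(3.2, 1.0, 0, 5),       maia_m2 = c(2.4, 1.0, 0, 5),
    maia_m3 = c(2.6, 1.0, 0, 5),       maia_m4 = c(3.0, 1.0, 0, 5),
    maia_m5 = c(3.4, 1.0, 0, 5),       maia_m6 = c(2.9, 1.1, 0, 5),
    maia_m7 = c(2.3, 1.1, 0, 5),       maia_m8 = c(3.3, 1.2, 0, 5),
    bpq_boa = c(30, 8, 12, 60),        bpq_sup = c(12, 4, 6, 30),
    bpq_boa_sub = c(8, 2.5, 4, 20),
    mean_hr = c(72, 10, 45, 110),      hf_log_power = c(5.5, 1.2, 2, 9),
    lf_hf = c(1.8, 1.0, 0.1, 8),       breath_freq = c(15, 3, 8, 25),
    delta_ar = c(0.5, 2.0, -8, 8),     c_che = c(80, 12, 30, 100),
    c_arm = c(70, 14, 20, 100),        hit = c(22, 3, 10, 28),
    auc_av = c(0.03, 0.03, 0, 0.3),    auc_at = c(0.03, 0.03, 0, 0.3),
    auc_vt = c(0.02, 0.02, 0, 0.3),
    jnd_sj = c(120, 40, 20, 300),      pse_pps = c(45, 15, 5, 100),
    jnd_toju = c(60, 25, 10, 200),     jnd_tojc = c(110, 45, 10, 400),
    sc = c(8, 4, 0, 30),
    mre_lh = c(2.0, 0.8, 0, 6),        mre_rh = c(1.8, 0.8, 0, 6)
  )
  colnames(d) <- c("mean", "sd", "lower", "upper")
  as.data.frame(d)
}

#' Simulate a scored cohort with planted predictor-outcome effects
#'
#' Draws every registry predictor from a truncated-Gaussian distribution,
#' standardizes internally, and builds each SF-36 outcome as a linear
#' combination of standardized predictors plus Gaussian noise. The latent
#' outcome is mapped to the 0-100 subscale range by the fixed affine map
#' `50 + 15 * latent / sd_theory` (then clipped), where
#' `sd_theory = sqrt(sum(beta^2) + noise_sd^2)` is the theoretical latent
#' s.d., so the map never depends on the realized sample. The ground-truth
#' coefficients and the affine map are returned alongside the table.
#'
#' @param n_participants >= 3.
#' @param seed integer master seed.
#' @param latent_effects data.frame with columns `outcome`, `predictor`,
#'   `beta` (standardized coefficients); empty means a null cohort.
#' @param noise_sd residual s.d. on the latent outcome scale: scalar or
#'   named per-outcome vector; >= 0.
#' @param predictor_distributions data.frame as
#'   [default_predictor_distributions()]; row names are variable names.
#' @return A list of class `cohort_sim`: `cohort` (data.frame, one row per
#'   participant, all registry columns), `ground_truth` (effects, noise_sd,
#'   affine map per outcome), `seed`.
#' @export
#' @examples
#' eff <- data.frame(outcome = "sf36_energy_fatigue",
#'                   predictor = "mean_hr", beta = 0.8)
#' sim <- simulate_cohort(60, seed = 1, latent_effects = eff, noise_sd = 0.6)
#' dim(sim$cohort)
simulate_cohort <- function(n_participants = 60, seed = 1L,
                            latent_effects = NULL, noise_sd = 1,
                            predictor_distributions =
                              default_predictor_distributions()) {
  stopifnot(n_participants >= 3, all(noise_sd >= 0))
  reg <- variable_registry()
  pred_names <- reg$name[reg$role != "outcome"]
  out_names <- sf36_outcomes()
  if (is.null(latent_effects)) {
    latent_effects <- data.frame(outcome = character(0),
                                 predictor = character(0),
                                 beta = numeric(0))
  }
  bad <- setdiff(unique(c(latent_effects$outcome, latent_effects$predictor)),
                 reg$name)
  if (length(bad) > 0) {
    stop("unknown variable name(s) in latent_effects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  miss_dist <- setdiff(pred_names, rownames(predictor_distributions))
  if (length(miss_dist) > 0) {
    stop("no sampling distribution for predictor(s): ",
         paste(miss_dist, collapse = ", "), call. = FALSE)
  }

  set.seed(split_seed(seed, 1L))
  n <- n_participants
  X <- sapply(pred_names, function(v) {
    d <- predictor_distributions[v, ]
    x <- stats::rnorm(n, d$mean, d$sd)
    pmin(pmax(x, d$lower), d$upper)
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, pred_names))
  Z <- scale(X)
  # degenerate sds (all-clipped columns) would give NaN; guard
  Z[, attr(Z, "scaled:scale") == 0] <- 0

  noise <- if (length(noise_sd) == 1) {
    stats::setNames(rep(noise_sd, length(out_names)), out_names)
  } else {
    stopifnot(all(out_names %in% names(noise_sd)))
    noise_sd[out_names]
  }

  set.seed(split_seed(seed, 2L))
  outcomes <- matrix(NA_real_, n, length(out_names),
                     dimnames = list(NULL, out_names))
  affine <- list()
  for (o in out_names) {
    eff <- latent_effects[latent_effects$outcome == o, , drop = FALSE]
    latent <- as.numeric(Z[, eff$predictor, drop = FALSE] %*% eff$beta) +
      stats::rnorm(n, sd = noise[[o]])
    sd_theory <- sqrt(sum(eff$beta^2) + noise[[o]]^2)
    if (sd_theory == 0) sd_theory <- 1
    y <- 50 + 15 * latent / sd_theory
    outcomes[, o] <- pmin(pmax(y, 0), 100)
    affine[[o]] <- c(center = 50, scale = 15 / sd_theory)
  }

  cohort <- data.frame(participant = seq_len(n), X, outcomes,
                       check.names = FALSE)
  structure(
    list(cohort = cohort,
         ground_truth = list(effects = latent_effects, noise_sd = noise,
                             affine = affine),
         seed = seed),
    class = "cohort_sim"
  )
}

#' Write a simulated cohort to CSV plus a ground-truth JSON sidecar
#' @param sim a `cohort_sim`; @param path CSV path (sidecar gets `.truth.json`).
#' @export
write_cohort <- function(sim, path) {
  stopifnot(inherits(sim, "cohort_sim"))
  utils::write.csv(sim$cohort, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(sim$ground_truth, paste0(side, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
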