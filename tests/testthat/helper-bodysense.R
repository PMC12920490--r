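# Fraction of planted event times matched by a detection within `tol` s,
# one detection per planted event.
match_sensitivity <- function(planted, detected, tol = 0.010) {
  if (length(planted) == 0) return(NA_real_)
  hits <- vapply(planted, function(t) any(abs(detected - t) <= tol),
                 logical(1))
  mean(hits)
}

# A tapping trial with beats at `beat_times` and taps at a fixed latency
# after the beats indexed by `tapped`.
make_tap_trial <- function(beat_times, tapped = seq_along(beat_times),
                           latency = 0.3) {
  list(tap_times = beat_times[tapped] + latency,
       r_peak_times = beat_times,
       trial_duration = max(beat_times) + 1)
}

# Psychometric table with exact (expected-value) counts for a cumulative
# Gaussian, for quantile-identity checks.
exact_cg_table <- function(levels, mu, sigma, n = 1000L) {
  p <- pnorm((levels - mu) / sigma)
  structure(
    data.frame(stimulus_level = levels, n_presented = n,
               n_positive = as.integer(round(p * n))),
    class = c("psychometric_table", "data.frame")
  )
}

planted_two_step_effects <- function() {
  data.frame(
    outcome = c("sf36_role_physical", "sf36_emotional_wellbeing",
                "sf36_emotional_wellbeing", "sf36_energy_fatigue",
                "sf36_energy_fatigue"),
    predictor = c("maia_m6", "maia_m6", "maia_m8", "mean_hr", "delta_ar"),
    beta = c(1.0, 0.7, 0.7, 0.8, 0.6)
  )
}
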