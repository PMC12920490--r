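#' Heart-rate category for heartbeat-detection scoring
#'
#' Slow if mean HR < 69.75 bpm, fast if > 94.25, mid otherwise; both
#' boundaries are assigned to the mid category.
#'
#' @param mean_hr beats/min, > 0.
#' @return `"slow"`, `"mid"` or `"fast"`.
#' @export
categorize_hr <- function(mean_hr) {
  if (!is.finite(mean_hr) || mean_hr <= 0) {
    stop("mean_hr must be positive", call. = FALSE)
  }
  if (mean_hr < 69.75) "slow" else if (mean_hr > 94.25) "fast" else "mid"
}

#' Default per-category tapping windows (s after the R-peak)
#'
#' The scoring tradition uses HR-dependent acceptance windows; these
#' defaults are deliberately exposed because the window choice is a scoring
#' parameter, not a fixed constant, and should be reported with any result.
#' @export
default_tap_windows <- function() {
  list(slow = c(0.100, 0.500), mid = c(0.100, 0.400), fast = c(0.050, 0.300))
}

# One-to-one greedy beat<->tap matching: among all (beat, tap) pairs whose
# tap latency after the beat falls in `window`, accept pairs in order of
# increasing latency, each beat and tap used at most once.
match_taps <- function(r_peaks, taps, window) {
  if (length(r_peaks) == 0 || length(taps) == 0) return(0L)
  pairs <- expand.grid(b = seq_along(r_peaks), p = seq_along(taps))
  lat <- taps[pairs$p] - r_peaks[pairs$b]
  ok <- lat >= window[1] & lat <= window[2]
  pairs <- pairs[ok, , drop = FALSE]
  lat <- lat[ok]
  if (nrow(pairs) == 0) return(0L)
  ord <- order(lat)
  used_b <- logical(length(r_peaks))
  used_p <- logical(length(taps))
  n_match <- 0L
  for (i in ord) {
    b <- pairs$b[i]; p <- pairs$p[i]
    if (!used_b[b] && !used_p[p]) {
      used_b[b] <- TRUE; used_p[p] <- TRUE
      n_match <- n_match + 1L
    }
  }
  n_match
}

#' Heartbeat-detection (tapping) accuracy
#'
#' Each trial's taps are matched one-to-one to R-peaks within the acceptance
#' window of the trial's HR category; correct counts are pooled across
#' trials by category (corr_69 / corr_betw / corr_94) and scored as
#' `1 - |recorded - (corr_69 + corr_betw + corr_94)| / recorded`, clipped to
#' \[0, 1\].
#'
#' @param trials list of trials, each a list with `tap_times`, `r_peak_times`
#'   (s, non-decreasing) and `trial_duration` (s).
#' @param windows per-category windows as [default_tap_windows()].
#' @return List: `acc_d`, plus the pooled per-category correct counts and
#'   total recorded beats.
#' @export
detection_accuracy <- function(trials, windows = default_tap_windows()) {
  stopifnot(length(trials) >= 1)
  corr <- c(slow = 0L, mid = 0L, fast = 0L)
  recorded <- 0L
  for (tr in trials) {
    rp <- tr$r_peak_times
    if (length(rp) == 0) stop("trial with zero R-peaks", call. = FALSE)
    recorded <- recorded + length(rp)
    hr <- if (length(rp) >= 2) {
      60 * (length(rp) - 1) / (rp[length(rp)] - rp[1])
    } else {
      60 * length(rp) / tr$trial_duration
    }
    cat <- categorize_hr(hr)
    corr[cat] <- corr[cat] + match_taps(rp, tr$tap_times, windows[[cat]])
  }
  acc <- 1 - abs(recorded - sum(corr)) / recorded
  list(acc_d = min(max(acc, 0), 1),
       corr_69 = unname(corr["slow"]), corr_betw = unname(corr["mid"]),
       corr_94 = unname(corr["fast"]), recorded = recorded)
}

#' Heartbeat-counting accuracy (Schandry score)
#'
#' Mean over trials of `1 - |recorded - counted| / recorded`. The score is
#' not clipped: counting more than twice the recorded beats yields a
#' negative term, as the standard formula implies.
#'
#' @param recorded_beats,counted_beats integer vectors, one entry per trial.
#' @param n_trials expected trial count (default 4).
#' @return `acc_c`, a single number <= 1.
#' @export
counting_accuracy <- function(recorded_beats, counted_beats, n_trials = 4L) {
  if (length(recorded_beats) != n_trials ||
      length(counted_beats) != n_trials) {
    stop("expected exactly ", n_trials, " trials", call. = FALSE)
  }
  if (any(recorded_beats <= 0)) {
    stop("recorded heartbeats must be >= 1 in every trial", call. = FALSE)
  }
  if (any(counted_beats < 0)) stop("counted heartbeats must be >= 0",
                                   call. = FALSE)
  mean(1 - abs(recorded_beats - counted_beats) / recorded_beats)
}

#' Mean confidence rating
#' @param ratings integer vector of 1-9 ratings (2 for detection, 4 for
#'   counting).
#' @return arithmetic mean.
#' @export
mean_confidence <- function(ratings) {
  if (any(ratings < 1 | ratings > 9 | ratings != round(ratings))) {
    stop("confidence ratings must be integers in 1..9", call. = FALSE)
  }
  mean(ratings)
}

#' Interoceptive awareness as accuracy-confidence discrepancy
#'
#' Min-max normalizes accuracy and confidence across the cohort to \[0, 1\]
#' and returns the per-participant absolute difference. Cohort-relative by
#' construction, hence invariant to affine rescaling of either input.
#'
#' @param accuracies,confidences numeric vectors of equal length >= 2.
#' @return numeric vector in \[0, 1\].
#' @export
awareness_discrepancy <- function(accuracies, confidences) {
  stopifnot(length(accuracies) == length(confidences),
            length(accuracies) >= 2)
  norm01 <- function(v, what) {
    rg <- range(v)
    if (diff(rg) == 0) {
      stop("degenerate ", what, " vector: zero range, cannot min-max ",
           "normalize", call. = FALSE)
    }
    (v - rg[1]) / diff(rg)
  }
  abs(norm01(accuracies, "accuracy") - norm01(confidences, "confidence"))
}

#' Load a questionnaire item map from YAML
#'
#' A map names the instrument, the item-to-subscale assignment, the
#' reverse-coded items, the response range and the aggregation rule.
#' Defaults for the MAIA (32 items, 8 subscales, 0-5 scale, mean
#' aggregation, items 5-9 reverse-coded) and a 22-item BPQ layout (three
#' factors, sum aggregation) ship under `inst/extdata/`. The BPQ
#' item-to-factor assignment is an editable placeholder (the three-factor
#' 22-item layout is instrument-specific and should be replaced by the
#' user's own mapping); the MAIA map follows the published version-1 layout.
#'
#' @param path YAML file; or use [maia_map()] / [bpq_map()].
#' @return A `questionnaire_map` list.
#' @export
read_questionnaire_map <- function(path) {
  m <- yaml::read_yaml(path)
  stopifnot(!is.null(m$instrument), !is.null(m$subscales),
            !is.null(m$range), !is.null(m$aggregate))
  m$aggregate <- match.arg(m$aggregate, c("mean", "sum"))
  m$subscales <- lapply(m$subscales, function(x) as.character(unlist(x)))
  m$reverse <- as.character(unlist(m$reverse))
  m$range <- as.numeric(unlist(m$range))
  items <- unlist(m$subscales, use.names = FALSE)
  if (anyDuplicated(items)) stop("item assigned to two subscales",
                                 call. = FALSE)
  if (!all(m$reverse %in% items)) stop("reverse-coded item not in map",
                                       call. = FALSE)
  structure(m, class = "questionnaire_map")
}

#' @rdname read_questionnaire_map
#' @export
maia_map <- function() {
  read_questionnaire_map(system.file("extdata", "maia_map.yaml",
                                     package = "bodysense", mustWork = TRUE))
}

#' @rdname read_questionnaire_map
#' @export
bpq_map <- function() {
  read_questionnaire_map(system.file("extdata", "bpq_map.yaml",
                                     package = "bodysense", mustWork = TRUE))
}

#' Score a questionnaire against an item map
#'
#' Reverse-coded items are flipped within the response range; each subscale
#' aggregates its items by the map's rule. A subscale with more than 20%
#' missing items is returned as `NA`; with up to 20% missing, the mean rule
#' averages available items and the sum rule prorates
#' (mean(available) * n_items).
#'
#' @param responses named numeric vector, names are item identifiers.
#' @param map a `questionnaire_map`.
#' @return Named numeric vector of subscale scores.
#' @export
score_questionnaire <- function(responses, map) {
  all_items <- unlist(map$subscales, use.names = FALSE)
  unknown <- setdiff(names(responses), all_items)
  if (length(unknown) > 0) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lo <- map$range[[1]]; hi <- map$range[[2]]
  if (any(responses < lo | responses > hi, na.rm = TRUE)) {
    stop("response outside the instrument range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  vals <- responses
  rev_items <- intersect(map$reverse, names(vals))
  vals[rev_items] <- lo + hi - vals[rev_items]
  out <- vapply(map$subscales, function(items) {
    v <- vals[match(items, names(vals))]
    n_miss <- sum(is.na(v))
    if (n_miss / length(items) > 0.2) return(NA_real_)
    if (map$aggregate == "mean") {
      mean(v, na.rm = TRUE)
    } else {
      mean(v, na.rm = TRUE) * length(items)
    }
  }, numeric(1))
  out
}

#' Score the interoceptive predictor block for one participant
#'
#' @param tapping list of tapping trials (see [detection_accuracy()]).
#' @param tapping_conf 2 confidence ratings (1-9).
#' @param counting list with `recorded_beats`, `counted_beats` (4 each).
#' @param counting_conf 4 confidence ratings (1-9).
#' @param maia_responses,bpq_responses named item responses.
#' @param windows tapping windows.
#' @return Named list with `acc_d`, `acc_c`, `con_d`, `con_c` and the
#'   questionnaire subscales (`maia_m1`..`maia_m8`, `bpq_boa`, `bpq_sup`,
#'   `bpq_boa_sub`). Awareness indices are cohort-level quantities; see
#'   [awareness_discrepancy()].
#' @export
score_interoception <- function(tapping, tapping_conf, counting,
                                counting_conf, maia_responses, bpq_responses,
                                windows = default_tap_windows()) {
  maia <- score_questionnaire(maia_responses, maia_map())
  bpq <- score_questionnaire(bpq_responses, bpq_map())
  c(
    list(
      acc_d = detection_accuracy(tapping, windows)$acc_d,
      acc_c = counting_accuracy(counting$recorded_beats,
                                counting$counted_beats),
      con_d = mean_confidence(tapping_conf),
      con_c = mean_confidence(counting_conf)
    ),
    as.list(stats::setNames(maia, paste0("maia_", tolower(names(maia))))),
    as.list(stats::setNames(bpq, paste0("bpq_", tolower(names(bpq)))))
  )
}
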