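#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' Classic chain: zero-phase band-pass 5-15 Hz, five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual-threshold
#' peak classification with a 200 ms refractory period and a search-back at
#' half threshold when the running RR estimate says a beat was missed.
#' Each accepted detection is refined to the raw-signal maximum within
#' +/- 50 ms.
#'
#' @param ecg a `sampled_signal` (fields `samples`, `sampling_rate`).
#' @return An `r_peak_series` with detected `times` (s).
#' @export
detect_r_peaks <- function(ecg) {
  x <- ecg$samples
  fs <- ecg$sampling_rate
  if (length(x) < 2 * fs) {
    stop("ECG signal shorter than 2 s", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    warning("flat ECG signal: no R-peaks detected")
    return(structure(list(times = numeric(0)), class = "r_peak_series"))
  }

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # centred 5-point derivative (no group delay)
  dk <- c(1, 2, 0, -2, -1) / 8
  xd <- as.numeric(stats::filter(xf, dk, sides = 2))
  xd[is.na(xd)] <- 0
  xs <- xd^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(xs, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate local maxima separated by the refractory period
  refr <- round(0.2 * fs)
  is_max <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_max & mwi > 0)
  # keep only peaks dominating their +/- refractory neighbourhood, so
  # filter-ringing side lobes never enter the adaptive threshold logic
  n_mwi <- length(mwi)
  dominant <- vapply(cand, function(i) {
    lo <- max(1L, i - refr); hi <- min(n_mwi, i + refr)
    mwi[i] >= max(mwi[lo:hi])
  }, logical(1))
  cand <- cand[dominant]
  if (length(cand) == 0) {
    warning("no candidate peaks in integrated signal")
    return(structure(list(times = numeric(0)), class = "r_peak_series"))
  }

  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)

  beats <- integer(0)
  rr_avg <- NA_real_
  last_considered <- 0L
  for (i in cand) {
    if (length(beats) > 0 && (i - beats[length(beats)]) < refr) next
    # search-back: expected beat missed?
    if (length(beats) > 0 && !is.na(rr_avg) &&
        (i - beats[length(beats)]) > 1.66 * rr_avg) {
      gap <- cand[cand > beats[length(beats)] + refr & cand < i]
      if (length(gap) > 0) {
        gbest <- gap[which.max(mwi[gap])]
        if (mwi[gbest] > 0.5 * thr()) {
          beats <- c(beats, gbest)
          spki <- 0.25 * mwi[gbest] + 0.75 * spki
        }
      }
    }
    if (mwi[i] > thr()) {
      if (length(beats) > 0 && (i - beats[length(beats)]) < refr) next
      beats <- c(beats, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
      if (length(beats) >= 2) {
        rr_new <- diff(utils::tail(beats, 2))
        rr_avg <- if (is.na(rr_avg)) rr_new else 0.875 * rr_avg + 0.125 * rr_new
      }
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    last_considered <- i
  }
  if (length(beats) == 0) {
    warning("no peaks exceeded the adaptive threshold")
    return(structure(list(times = numeric(0)), class = "r_peak_series"))
  }

  # refine to raw-signal maximum within +/- 50 ms
  hw <- round(0.05 * fs)
  n <- length(x)
  refined <- vapply(beats, function(i) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # drop refinements collapsing onto the same raw peak within refractory
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  times <- (refined - 1) / fs
  structure(list(times = times), class = "r_peak_series")
}

#' Build the tachogram (successive R-R intervals) from an R-peak series
#'
#' Optional artifact correction replaces intervals outside 0.3-2.0 s or
#' deviating more than 30% from the local (11-point) running median by cubic
#' interpolation over the surrounding valid intervals.
#'
#' @param peaks an `r_peak_series` with >= 2 peaks.
#' @param correct_artifacts logical, default FALSE.
#' @return A `tachogram`: list with `rr_intervals` (s) and `rr_times`
#'   (time of each interval's end, s).
#' @export
build_tachogram <- function(peaks, correct_artifacts = FALSE) {
  times <- if (inherits(peaks, "r_peak_series")) peaks$times else as.numeric(peaks)
  if (length(times) < 2) stop("need at least 2 R-peaks", call. = FALSE)
  rr <- diff(times)
  rr_t <- times[-1]
  if (correct_artifacts && length(rr) >= 3) {
    k <- min(11L, length(rr) - (1 - length(rr) %% 2))  # odd, <= n
    locmed <- stats::runmed(rr, k)
    bad <- rr < 0.3 | rr > 2.0 | abs(rr - locmed) / locmed > 0.3
    if (any(bad) && sum(!bad) >= 4) {
      rr[bad] <- stats::spline(rr_t[!bad], rr[!bad], xout = rr_t[bad],
                               method = "natural")$y
    }
  }
  structure(list(rr_intervals = rr, rr_times = rr_t), class = "tachogram")
}

# Smoothness-priors detrending (second-difference penalty): the trend is
# (I + lambda^2 D2'D2)^{-1} z; we return z minus the trend.
smoothness_priors_detrend <- function(z, lambda = 500) {
  n <- length(z)
  if (n < 4) return(z - mean(z))
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2),
                                            rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + (lambda^2) * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, z))
  z - trend
}

# Welch PSD: Hann window, 50% overlap; one-sided density in units^2/Hz.
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- n
  seg_len <- min(seg_len, n)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / (fs * sum(win^2))
    p <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when seg_len even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (seg_len %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = acc / length(starts))
}

#' Frequency-domain heart-rate-variability features
#'
#' The RR series (ms) is cubic-spline interpolated onto a uniform 4 Hz grid,
#' detrended (smoothness-priors by default, mirroring the Kubios toolchain),
#' and analysed with a Hann-windowed 50%-overlap Welch periodogram (120 s
#' segments, or the full record when shorter). HF power is integrated over
#' 0.15-0.4 Hz and LF over 0.04-0.15 Hz (standard Task-Force bands);
#' `hf_log_power` is the natural log of integrated HF power in ms^2. Mean HR
#' is 60 / mean(RR) from the raw (uninterpolated) intervals.
#'
#' @param tach a `tachogram` spanning >= 60 s.
#' @param detrend `"smoothness_priors"` (default), `"linear"` or `"none"`.
#' @param lambda smoothness-priors regularization (default 500).
#' @param interp_rate interpolation rate in Hz (default 4).
#' @param seg_len_s Welch segment length in s (default 120).
#' @return An `hrv_features` list: `mean_hr`, `hf_log_power`, `lf_hf_ratio`,
#'   `hf_power`, `lf_power` (ms^2).
#' @export
hrv_frequency_features <- function(tach, detrend = c("smoothness_priors",
                                                     "linear", "none"),
                                   lambda = 500, interp_rate = 4,
                                   seg_len_s = 120) {
  detrend <- match.arg(detrend)
  rr <- tach$rr_intervals
  tt <- tach$rr_times
  span <- tt[length(tt)] - tt[1]
  if (span < 60) stop("tachogram spans less than 60 s", call. = FALSE)
  mean_hr <- 60 / mean(rr)

  grid <- seq(tt[1], tt[length(tt)], by = 1 / interp_rate)
  z <- stats::spline(tt, rr * 1000, xout = grid, method = "fmm")$y
  z <- switch(detrend,
    smoothness_priors = smoothness_priors_detrend(z, lambda),
    linear = stats::residuals(stats::lm(z ~ grid)),
    none = z - mean(z)
  )
  seg <- min(length(z), round(seg_len_s * interp_rate))
  sp <- welch_psd(z, interp_rate, seg_len = seg)
  df <- sp$freq[2] - sp$freq[1]
  band_power <- function(lo, hi) {
    sum(sp$psd[sp$freq >= lo & sp$freq < hi]) * df
  }
  hf <- band_power(0.15, 0.40)
  lf <- band_power(0.04, 0.15)
  if (!is.finite(hf) || hf <= .Machine$double.eps) {
    stop("degenerate spectrum: HF band power is zero", call. = FALSE)
  }
  structure(
    list(mean_hr = mean_hr,
         hf_log_power = log(hf),
         lf_hf_ratio = lf / hf,
         hf_power = hf, lf_power = lf),
    class = "hrv_features"
  )
}

#' Breath frequency from a respiration trace
#'
#' The trace is low-pass filtered at 1 Hz, inhalation onsets are taken as
#' positive-going crossings of the signal mean, gated by excursion size
#' (the rise after a crossing must exceed a quarter of the trace s.d., so
#' ripple does not count) and a minimum cycle length of 1 s. Breath
#' frequency is complete cycles divided by the covered span, in breaths/min.
#'
#' @param resp a `sampled_signal` of >= 30 s.
#' @return A `breath_features` list: `breath_frequency` (breaths/min) and
#'   `cycle_onsets` (s).
#' @export
breath_frequency <- function(resp) {
  x <- resp$samples
  fs <- resp$sampling_rate
  if (length(x) < 30 * fs) stop("respiration signal shorter than 30 s",
                                call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("flat respiration signal: breath frequency set to 0")
    return(structure(list(breath_frequency = 0, cycle_onsets = numeric(0)),
                     class = "breath_features"))
  }
  if (fs > 2.5) {
    lp <- signal::butter(4, 1 / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  m <- mean(x)
  s <- stats::sd(x)
  up <- which(x[-length(x)] < m & x[-1] >= m)
  if (length(up) >= 2) {
    # gate on excursion: the following half-cycle must rise appreciably
    keep <- vapply(seq_along(up), function(j) {
      hi <- if (j < length(up)) up[j + 1] else length(x)
      max(x[up[j]:hi]) > m + 0.25 * s
    }, logical(1))
    up <- up[keep]
    # enforce minimum cycle length 1 s
    if (length(up) > 1) {
      sel <- c(TRUE, diff(up) >= fs)
      up <- up[sel]
    }
  }
  if (length(up) < 2) {
    warning("fewer than 2 inhalation onsets detected: breath frequency 0")
    return(structure(list(breath_frequency = 0,
                          cycle_onsets = (up - 1) / fs),
                     class = "breath_features"))
  }
  onsets <- (up - 1) / fs
  cycles <- length(onsets) - 1
  span_min <- (onsets[length(onsets)] - onsets[1]) / 60
  structure(list(breath_frequency = cycles / span_min, cycle_onsets = onsets),
            class = "breath_features")
}

#' Score the four physiological predictors from raw traces
#'
#' Convenience wrapper running the full chain: R-peak detection, tachogram,
#' frequency-domain HRV, and breath counting.
#'
#' @param ecg,resp `sampled_signal`s.
#' @param ... passed to [hrv_frequency_features()].
#' @return Named list: `mean_hr`, `hf_log_power`, `lf_hf`, `breath_freq`.
#' @export
score_physiology <- function(ecg, resp, ...) {
  peaks <- detect_r_peaks(ecg)
  tach <- build_tachogram(peaks)
  hrv <- hrv_frequency_features(tach, ...)
  br <- breath_frequency(resp)
  list(mean_hr = hrv$mean_hr,
       hf_log_power = hrv$hf_log_power,
       lf_hf = hrv$lf_hf_ratio,
       breath_freq = br$breath_frequency)
}
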