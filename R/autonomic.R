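# Trial-level autonomic reactivity: inter-beat-interval artifact correction,
# heart-rate deceleration (HRD), electrodermal pre-processing, a simplified
# continuous-decomposition SCR statistic (CDA.SCR), non-responder screening
# and basic resting HRV indices.

#' Detect and correct inter-beat-interval artifacts
#'
#' Distribution-based artifact detection in the spirit of quartile-deviation
#' beat screening: a beat is flagged when its IBI deviates from the median of
#' its neighbours (sliding window, the beat itself excluded) by more than the
#' criterion `max(min(k * QD, cap_frac * median IBI), floor_ms)`, where QD is
#' half the interquartile range of the successive IBI differences. The
#' physiological cap keeps the criterion meaningful when artifacts themselves
#' inflate the difference distribution (e.g. alternating missed/extra beats).
#' Flagged beats are replaced by cubic-spline interpolation through the clean
#' beats. The exact detection constants are free parameters with documented
#' defaults.
#'
#' @param ibi Numeric vector of IBIs (ms), or tibble with columns
#'   `beat_time_ms`, `ibi_ms`.
#' @param k Multiplier on the quartile deviation (default 4.5).
#' @param floor_ms Minimum deviation treated as an artifact (default 120 ms).
#' @param cap_frac Upper bound on the criterion as a fraction of the median
#'   IBI (default 0.3).
#' @param window Sliding window size in beats (odd, default 11).
#' @return A list: `ibi` (tibble `beat_time_ms`, `ibi_ms`, `corrected`),
#'   `n_flagged`, `fraction_flagged`. Errors if more than half the beats are
#'   flagged.
#' @export
correct_ibi <- function(ibi, k = 4.5, floor_ms = 120, cap_frac = 0.3,
                        window = 11) {
  if (is.numeric(ibi)) {
    ibi <- tibble::tibble(beat_time_ms = cumsum(ibi), ibi_ms = ibi)
  }
  abort_if(!all(c("beat_time_ms", "ibi_ms") %in% names(ibi)),
           "ibi needs columns beat_time_ms, ibi_ms")
  v <- ibi$ibi_ms
  n <- length(v)
  abort_if(n < 4, "need at least four beats")
  abort_if(any(v <= 0), "IBIs must be positive")

  qd <- stats::IQR(diff(v)) / 2
  thr <- max(min(k * qd, cap_frac * median(v)), floor_ms)
  half <- window %/% 2
  ref <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    median(v[setdiff(idx, i)])
  }, numeric(1))
  flagged <- abs(v - ref) > thr

  frac <- mean(flagged)
  abort_if(frac > 0.5,
           sprintf("%.0f%% of beats flagged as artifacts; record rejected",
                   100 * frac))
  out <- v
  if (any(flagged)) {
    good <- which(!flagged)
    sp <- spline(good, v[good], xout = which(flagged), method = "natural")
    out[flagged] <- sp$y
  }
  list(ibi = tibble::tibble(beat_time_ms = ibi$beat_time_ms, ibi_ms = out,
                            corrected = flagged),
       n_flagged = sum(flagged), fraction_flagged = frac)
}

#' Heart-rate deceleration (HRD) for one trial
#'
#' Instantaneous heart rate (bpm = 60000 / IBI, assigned at beat times) is
#' interpolated onto a uniform grid; HRD is the mean heart rate in the 2 s
#' before stimulus onset minus the minimum heart rate in the 6 s after onset.
#' Positive values indicate cardiac deceleration (the orienting response).
#'
#' @param ibi Tibble with `beat_time_ms`, `ibi_ms` (artifact-corrected).
#' @param stim_onset_s Stimulus onset on the trial clock (s).
#' @param pre,post Windows (s relative to onset), defaults `c(-2, 0)` and
#'   `c(0, 6)`.
#' @param grid_hz Interpolation grid rate (default 10 Hz).
#' @return A one-row tibble: `hrd_bpm`, `pre_mean_bpm`, `post_min_bpm`.
#'   Errors if the beats do not cover both windows.
#' @export
hrd <- function(ibi, stim_onset_s, pre = c(-2, 0), post = c(0, 6),
                grid_hz = 10) {
  abort_if(!all(c("beat_time_ms", "ibi_ms") %in% names(ibi)),
           "ibi needs columns beat_time_ms, ibi_ms")
  bt <- ibi$beat_time_ms / 1000
  hr <- 60000 / ibi$ibi_ms
  lo <- stim_onset_s + pre[1]
  hi <- stim_onset_s + post[2]
  abort_if(min(bt) > lo || max(bt) < hi,
           "beats do not cover the pre/post analysis windows; trial dropped")
  grid <- seq(lo, hi, by = 1 / grid_hz)
  hr_g <- approx(bt, hr, xout = grid, rule = 1)$y
  pre_idx <- grid >= lo & grid <= stim_onset_s + pre[2]
  post_idx <- grid > stim_onset_s + post[1] & grid <= hi
  pre_mean <- mean(hr_g[pre_idx])
  post_min <- min(hr_g[post_idx])
  tibble::tibble(hrd_bpm = pre_mean - post_min, pre_mean_bpm = pre_mean,
                 post_min_bpm = post_min)
}

# zero-phase filtering with edge-replication padding: signal::filtfilt alone
# zero-pads internally and leaves large transients at the trace ends
zero_phase <- function(bf, x, pad = 120) {
  n <- length(x)
  p <- min(pad, n - 1)
  xp <- c(rep(x[1], p), x, rep(x[n], p))
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

gaussian_kernel <- function(width) {
  # gausswin-style: alpha = 2.5, sd = (width - 1) / (2 * alpha)
  half <- (width - 1) / 2
  s <- (width - 1) / 5
  k <- exp(-0.5 * ((seq_len(width) - 1 - half) / s)^2)
  k / sum(k)
}

#' Pre-process an electrodermal trace
#'
#' Down-samples to 10 Hz, applies a zero-phase second-order 1-Hz low-pass
#' Butterworth filter, then smooths with a 10-point (1-s) Gaussian window.
#'
#' @param eda Tibble with `time_s`, `conductance_uS`, or numeric vector.
#' @param fs Input sampling rate (Hz, >= 10 and a multiple of 10).
#' @return Tibble `time_s`, `conductance_uS` at 10 Hz.
#' @export
preprocess_eda <- function(eda, fs) {
  if (is.numeric(eda)) {
    eda <- tibble::tibble(time_s = (seq_along(eda) - 1) / fs,
                          conductance_uS = eda)
  }
  abort_if(fs < 10, "EDA sampling rate must be >= 10 Hz")
  abort_if(any(!is.finite(eda$conductance_uS)), "EDA trace must be finite")
  x <- eda$conductance_uS
  q <- fs / 10
  abort_if(q != round(q), "sampling rate must be a multiple of 10 Hz")
  abort_if(length(x) < 40 * q, "trace shorter than filter warm-up")
  if (q > 1) {
    # block-mean decimation: constant-preserving, zero-phase; residual
    # aliasing is removed by the 1-Hz zero-phase Butterworth that follows
    n_blk <- floor(length(x) / q)
    x <- colMeans(matrix(x[seq_len(n_blk * q)], nrow = q))
  }
  bf <- signal::butter(2, 1 / (10 / 2), type = "low")
  bf$b <- bf$b * (sum(bf$a) / sum(bf$b))  # exact unity DC gain
  x <- zero_phase(bf, x)
  k <- gaussian_kernel(10)
  padded <- c(rep(x[1], 5), x, rep(x[length(x)], 5))
  sm <- stats::filter(padded, k, sides = 2)
  x <- as.numeric(sm[(5 + 1):(5 + length(x))])
  tibble::tibble(time_s = eda$time_s[1] + (seq_along(x) - 1) / 10,
                 conductance_uS = x)
}

bateman_kernel <- function(t, tau) {
  b <- ifelse(t < 0, 0, exp(-t / tau[2]) - exp(-t / tau[1]))
  pk <- max(b)
  if (pk > 0) b / pk else b
}

#' Continuous-decomposition SCR statistic (CDA.SCR) for one trial
#'
#' Recovers the phasic sudomotor driver by ridge-regularized non-negative
#' deconvolution of the (pre-processed, 10-Hz) conductance trace with a
#' peak-normalized Bateman impulse response, after removing a linear tonic
#' trend fitted to the pre-stimulus segment. `CDA.SCR` is the mean driver
#' (uS/s) within the 1-6-s response window; `responded` is true when the
#' reconstructed phasic response in the window reaches the 0.05-uS amplitude
#' threshold. This is a deliberate simplification of full
#' continuous-decomposition analysis: the Bateman constants are fixed (but
#' configurable) rather than optimized per subject.
#'
#' @param eda 10-Hz pre-processed tibble (`time_s`, `conductance_uS`).
#' @param stim_onset_s Stimulus onset (s, trace clock).
#' @param window Response window relative to onset (s), default `c(1, 6)`.
#' @param tau Bateman time constants (s), default `c(0.75, 2)`.
#' @param threshold SCR amplitude threshold (uS), default 0.05.
#' @param lambda Ridge penalty on the discretized driver (default 0.002; small
#'   relative to the kernel column norms so shrinkage of recovered amplitudes
#'   stays below a few percent).
#' @return One-row tibble: `cda_scr` (uS/s), `responded`, `peak_phasic_uS`.
#' @export
cda_scr <- function(eda, stim_onset_s, window = c(1, 6), tau = c(0.75, 2),
                    threshold = 0.05, lambda = 0.002) {
  abort_if(any(!is.finite(eda$conductance_uS)), "EDA trace must be finite")
  fs <- 10
  dt <- 1 / fs
  seg_lo <- stim_onset_s - 3
  seg_hi <- stim_onset_s + window[2] + 2
  seg <- eda[eda$time_s >= seg_lo - 1e-9 & eda$time_s <= seg_hi + 1e-9, ]
  abort_if(nrow(seg) < (window[2] + 3) * fs,
           "EDA trace does not cover the response window")
  t_rel <- seg$time_s - stim_onset_s
  x <- seg$conductance_uS

  # tonic: linear fit through the pre-onset segment, extended over the trial
  pre <- t_rel <= -0.5
  fit <- stats::lm.fit(cbind(1, t_rel[pre]), x[pre])
  tonic <- cbind(1, t_rel) %*% fit$coefficients
  resid <- x - as.vector(tonic)

  # driver grid: allow onsets from -1 s to the end of the window
  drv_idx <- which(t_rel >= -1 & t_rel <= window[2] + 1)
  K <- vapply(drv_idx, function(j) {
    bateman_kernel(t_rel - t_rel[j], tau) * dt
  }, numeric(length(t_rel)))
  Ka <- rbind(K, sqrt(lambda) * diag(ncol(K)))
  xa <- c(resid, rep(0, ncol(K)))
  # K columns already carry dt, so the coefficients are a rate in uS/s
  d <- pracma::lsqnonneg(Ka, xa)$x

  in_win <- t_rel[drv_idx] >= window[1] & t_rel[drv_idx] <= window[2]
  value <- mean(d[in_win])
  phasic <- as.vector(K %*% d)
  win_t <- t_rel > window[1] & t_rel <= window[2]
  peak <- max(c(phasic[win_t], 0))
  tibble::tibble(cda_scr = value, responded = peak >= threshold,
                 peak_phasic_uS = peak)
}

#' Screen electrodermal non-responders
#'
#' A subject is excluded from electrodermal analyses when they responded to
#' fewer than 20% of negative stimuli in the baseline (T0) session of either
#' condition.
#'
#' @param trials Tibble with columns `subject`, `condition`, `session`,
#'   `stimulus_type`, `responded`.
#' @param min_fraction Responder criterion (default 0.20).
#' @return Tibble: `subject`, `min_response_fraction`, `keep`.
#' @export
screen_nonresponders <- function(trials, min_fraction = 0.20) {
  need <- c("subject", "condition", "session", "stimulus_type", "responded")
  abort_if(!all(need %in% names(trials)),
           paste("trials needs columns:", paste(need, collapse = ", ")))
  t0 <- trials[trials$session == "T0" & trials$stimulus_type == "negative", ]
  abort_if(nrow(t0) == 0, "no T0 negative trials present")
  t0 |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(frac = mean(.data$responded), .groups = "drop") |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(min_response_fraction = min(.data$frac),
                     .groups = "drop") |>
    dplyr::mutate(keep = .data$min_response_fraction >= min_fraction)
}

#' Resting time-domain heart-rate-variability indices
#'
#' SDNN (SD of IBIs), RMSSD (root-mean-square of successive differences) and
#' mean heart rate over an artifact-corrected resting segment of at least two
#' minutes.
#'
#' @param ibi Numeric vector of IBIs (ms) or tibble with `ibi_ms`.
#' @param min_duration_s Minimum segment duration (default 120 s).
#' @return One-row tibble: `sdnn_ms`, `rmssd_ms`, `mean_hr_bpm`, `duration_s`.
#' @export
resting_hrv <- function(ibi, min_duration_s = 120) {
  v <- if (is.numeric(ibi)) ibi else ibi$ibi_ms
  abort_if(any(v <= 0), "IBIs must be positive")
  dur <- sum(v) / 1000
  abort_if(dur < min_duration_s,
           sprintf("segment too short (%.1f s < %g s)", dur, min_duration_s))
  tibble::tibble(
    sdnn_ms = sd(v),
    rmssd_ms = sqrt(mean(diff(v)^2)),
    mean_hr_bpm = 60000 / mean(v),
    duration_s = dur
  )
}
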