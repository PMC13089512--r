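# Shared fixtures, built in code.

tiny_config <- function(seed = 1, n_subjects = 4, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed, ...)
}

# deterministic pseudo-random hypnogram fixture on the 5-stage alphabet
random_hypnogram <- function(n, seed, p = c(0.1, 0.15, 0.4, 0.15, 0.2)) {
  set.seed(seed)
  hypnogram(sample(c("W", "N1", "N2", "N3", "REM"), n, replace = TRUE,
                   prob = p))
}

# brute-force pair-counting oracle for transition matrices
oracle_transitions <- function(stages) {
  lv <- c("W", "N1", "N2", "N3", "REM")
  counts <- matrix(0L, 5, 5, dimnames = list(lv, lv))
  for (i in seq_len(length(stages) - 1)) {
    counts[stages[i], stages[i + 1]] <- counts[stages[i], stages[i + 1]] + 1L
  }
  counts
}

# brute-force REM-interruption oracle: scans the epoch sequence directly
oracle_remfr <- function(stages, events, epoch_len = 30) {
  rem <- stages == "REM"
  if (!any(rem)) return(NA_real_)
  ev_epoch <- floor(events$onset_s / epoch_len) + 1L
  in_rem <- ev_epoch >= 1 & ev_epoch <= length(stages)
  in_rem[in_rem] <- rem[ev_epoch[in_rem]]
  n_arousal <- sum(events$type == "arousal" & in_rem)
  n_move <- sum(events$type == "body_movement" & in_rem)
  arousal_epochs <- ev_epoch[events$type == "arousal" & in_rem]
  n_bouts <- 0L
  i <- 1L
  while (i <= length(stages)) {
    if (!rem[i]) {
      j <- i
      while (j <= length(stages) && !rem[j]) j <- j + 1L
      if (i > 1L && rem[i - 1L] && j <= length(stages)) {
        if (!((i - 1L) %in% arousal_epochs)) n_bouts <- n_bouts + 1L
      }
      i <- j
    } else i <- i + 1L
  }
  (n_arousal + n_move + n_bouts) / (sum(rem) * epoch_len / 3600)
}

# single-channel sinusoid epochs with optional post-stimulus amplitude change
sinusoid_epochs <- function(freq_hz, n_epochs, fs = 125, amp_pre = 1,
                            amp_post = amp_pre, noise_sd = 0.01,
                            window = c(-3, 15), seed = 1) {
  set.seed(seed)
  n_t <- round(diff(window) * fs) + 1L
  times <- window[1] + (seq_len(n_t) - 1) / fs
  amp <- ifelse(times >= 0, amp_post, amp_pre)
  dat <- array(0, dim = c(n_t, 1, n_epochs))
  for (e in seq_len(n_epochs)) {
    phase <- runif(1, 0, 2 * pi)
    dat[, 1, e] <- amp * sin(2 * pi * freq_hz * times + phase) +
      rnorm(n_t, 0, noise_sd)
  }
  structure(list(data = dat, fs = fs, times = times, channels = "Cz",
                 montage = NULL), class = "eeg_epochs")
}

# synthetic Bateman SCR trace on a 10-Hz grid
scr_trace <- function(amp, latency_s = 2, onset_s = 5, tonic = 2,
                      length_s = 14, tau = c(0.75, 2)) {
  tt <- seq(0, length_s, by = 0.1)
  b <- ifelse(tt - onset_s - latency_s < 0, 0,
              exp(-(tt - onset_s - latency_s) / tau[2]) -
                exp(-(tt - onset_s - latency_s) / tau[1]))
  pk <- max(b, 1e-12)
  tibble::tibble(time_s = tt, conductance_uS = tonic + amp * b / pk)
}

constant_ibi <- function(ibi_ms = 1000, duration_s = 14) {
  n <- floor(duration_s * 1000 / ibi_ms)
  tibble::tibble(beat_time_ms = seq_len(n) * ibi_ms, ibi_ms = ibi_ms)
}
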