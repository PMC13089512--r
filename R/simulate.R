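# Synthetic two-condition within-subject cohort with planted ground truth.
# Every generator is a pure function of (config, subject, condition, session):
# sub-stream seeds are derived from the single global seed by fixed offsets.

#' Default per-condition sleep-stage transition matrices
#'
#' Row-stochastic 5x5 matrices over (W, N1, N2, N3, REM), one per condition.
#' The fragmentation (FRG) matrix differs from control (CTR) in the REM row
#' (REM->REM lowered, REM->N1 raised) and a lowered N1->N2, emulating sensory
#' fragmentation of REM sleep that spares wake transitions.
#'
#' @return Named list of matrices `CTR`, `FRG`.
#' @export
default_transitions <- function() {
  ctr <- matrix(c(
    0.880, 0.100, 0.020, 0.000, 0.000,
    0.030, 0.600, 0.330, 0.000, 0.040,
    0.010, 0.030, 0.890, 0.045, 0.025,
    0.005, 0.005, 0.060, 0.930, 0.000,
    0.010, 0.030, 0.025, 0.000, 0.935
  ), 5, 5, byrow = TRUE, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  frg <- ctr
  frg["N1", ]  <- c(0.030, 0.600, 0.250, 0.000, 0.120)
  frg["REM", ] <- c(0.010, 0.130, 0.025, 0.000, 0.835)
  list(CTR = ctr, FRG = frg)
}

#' Cohort configuration for the synthetic generators
#'
#' Bundles every planted parameter of the synthetic study: condition-dependent
#' stage-transition dynamics, the escalating vibrotactile stimulation protocol,
#' EEG background/burst parameters, autonomic response amplitudes, the
#' recognition signal-detection model, and the subject-level coupling between
#' planted posterior alpha power and the change in cardiac deceleration.
#'
#' @param n_subjects Number of subjects (>= 2; default 17).
#' @param seed Global integer seed; all sub-streams derive from it.
#' @param epoch_len Hypnogram epoch length in seconds (default 30).
#' @param n_epochs Epochs per night (default 960, i.e. 8 h).
#' @param transition Named list of row-stochastic 5x5 matrices per condition.
#' @param stim Stimulation-protocol parameters: `n_steps` intensity steps,
#'   `on_s`/`off_s` vibration/pause durations (s), `suspend_s` suspension after
#'   an elicited arousal (s), `arousal_prob` per-step arousal probability,
#'   `spont_arousal_rate`/`spont_movement_rate` spontaneous event rates during
#'   REM (events per second).
#' @param eeg EEG parameters: sampling rate `fs`, `montage`, `noise_exponent`
#'   (1/f^beta background), `window` epoch window (s), `bursts` table of
#'   planted band-limited post-stimulus bursts (band, db, onset_s, duration_s,
#'   posterior_weight, anterior_weight), `alpha_subject_sd` between-subject SD
#'   of the planted alpha effect (dB).
#' @param autonomic Autonomic parameters: baseline `hr_bpm`, planted `hrd_amp`
#'   table (condition x session x stimulus_type deceleration amplitudes, bpm),
#'   `hrd_noise_sd` trial-level amplitude noise (bpm), SCR driver amplitudes
#'   (`scr_amp_negative`/`scr_amp_neutral`, uS), response probabilities,
#'   Bateman time constants `tau` (s), EDA sampling rate `fs_eda`.
#' @param memory Signal-detection parameters: planted `dprime` per session,
#'   `valence_boost` added to d-prime for negative stimuli, `criterion`,
#'   `subject_sd` between-subject d-prime SD.
#' @param coupling Subject-level coupling of planted alpha (dB) to the
#'   T1-T0 change in HRD: `slope` and `noise_sd` (default gives r ~ 0.7).
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17,
                          seed = 1,
                          epoch_len = 30,
                          n_epochs = 960,
                          transition = default_transitions(),
                          stim = list(),
                          eeg = list(),
                          autonomic = list(),
                          memory = list(),
                          coupling = list()) {
  stim_def <- list(
    n_steps = 7L, on_s = 3, off_s = 3, suspend_s = 40,
    arousal_prob = c(0.04, 0.08, 0.15, 0.25, 0.40, 0.55, 0.70),
    spont_arousal_rate = 0.004, spont_movement_rate = 0.0008
  )
  eeg_def <- list(
    fs = 125, montage = montage_1020(), noise_exponent = 1,
    window = c(-3, 15),
    bursts = tibble::tibble(
      band = c("alpha", "sigma", "beta", "low_gamma"),
      db = c(3, 2.5, 2, 1.5),
      onset_s = 0,
      duration_s = c(6, 6, 6, 2),
      posterior_weight = c(1, 1, 1, 1),
      anterior_weight = c(0.5, 0.9, 0.9, 0.35)
    ),
    alpha_subject_sd = 1
  )
  auto_def <- list(
    hr_bpm = 70, hr_subject_sd = 4,
    hrd_amp = tidyr::expand_grid(
      condition = c("CTR", "FRG"), session = c("T0", "T1", "T2"),
      stimulus_type = c("negative", "neutral")
    ) |>
      dplyr::mutate(amp = dplyr::case_when(
        .data$condition == "CTR" & .data$session == "T0" ~ 5,
        .data$condition == "CTR" ~ 2.5,
        .data$condition == "FRG" ~ 5
      ) * ifelse(.data$stimulus_type == "neutral", 0.6, 1)),
    hrd_noise_sd = 6, hrd_subject_sd = 1.5, hrd_stimulus_sd = 0.8,
    dip_onset_s = 0.5, dip_duration_s = 4,
    scr_amp_negative = 0.4, scr_amp_neutral = 0.15, scr_amp_cv = 0.4,
    p_respond_negative = 0.65, p_respond_neutral = 0.35,
    tau = c(0.75, 2), fs_eda = 50, eda_noise_sd = 0.01, tonic_uS = 2,
    n_trials_per_type = 14
  )
  mem_def <- list(
    dprime = c(T0 = 2, T1 = 1.6, T2 = 1.3),
    valence_boost = 0.2, criterion = 0, subject_sd = 0.3,
    n_old_per_type = 20, n_new_per_type = 20
  )
  # slope/noise give a measured subject-level correlation of ~0.7 once the
  # trial-averaging noise of the HRD session means (hrd_noise_sd * sqrt(2/28))
  # is folded in
  coup_def <- list(slope = 1.9, noise_sd = 1.02, alpha_base_db = 3,
                   topo_noise_sd = 0.8)

  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    epoch_len = epoch_len, n_epochs = as.integer(n_epochs),
    transition = transition,
    stim = utils::modifyList(stim_def, stim),
    eeg = utils::modifyList(eeg_def, eeg),
    autonomic = utils::modifyList(auto_def, autonomic),
    memory = utils::modifyList(mem_def, memory),
    coupling = utils::modifyList(coup_def, coupling)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  abort_if(cfg$n_subjects < 2, "n_subjects must be >= 2")
  abort_if(cfg$epoch_len <= 0, "epoch_len must be positive")
  for (cond in names(cfg$transition)) {
    P <- cfg$transition[[cond]]
    abort_if(!all(dim(P) == c(5, 5)), paste0(cond, ": transition matrix must be 5x5"))
    abort_if(any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9),
             paste0(cond, ": transition rows must be stochastic (sum to 1)"))
  }
  s <- cfg$stim
  abort_if(any(c(s$on_s, s$off_s, s$suspend_s) <= 0), "stim durations must be > 0")
  abort_if(length(s$arousal_prob) != s$n_steps ||
             any(s$arousal_prob < 0 | s$arousal_prob > 1),
           "arousal_prob must be one probability per intensity step")
  abort_if(any(!is.finite(cfg$eeg$bursts$db)), "burst dB effects must be finite")
  abort_if(any(cfg$eeg$bursts$duration_s <= 0), "burst durations must be > 0")
  abort_if(cfg$eeg$fs < 100, "EEG sampling rate must be >= 100 Hz")
  abort_if(cfg$autonomic$hr_bpm <= 0, "baseline heart rate must be positive")
  abort_if(any(c(cfg$autonomic$scr_amp_negative, cfg$autonomic$scr_amp_neutral) < 0),
           "SCR driver amplitudes must be non-negative")
  abort_if(any(cfg$memory$dprime < 0), "planted d-prime must be >= 0")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects, seed %d, %d epochs of %g s\n",
              x$n_subjects, x$seed, x$n_epochs, x$epoch_len))
  invisible(x)
}

#' Simulate one night: hypnogram plus event log
#'
#' Draws a stage sequence from the condition's Markov transition matrix
#' (epoch-resolution, starting awake at lights-off) and, for the FRG
#' condition, simulates the escalating vibrotactile stimulation protocol over
#' every REM period: trains of 3-s vibrations separated by 3-s pauses,
#' intensity escalating one step per unanswered stimulation, a 40-s suspension
#' after an elicited arousal with resumption at the previously effective
#' intensity, and a reset to minimum intensity at each new REM period. A
#' stimulation interrupted by the end of a REM period is logged with outcome
#' `stage_shift`. Spontaneous arousals and body movements during REM occur at
#' the configured Poisson rates in both conditions.
#'
#' @param config A [cohort_config()].
#' @param subject Subject index.
#' @param condition `"CTR"` or `"FRG"`.
#' @return A list with elements `hypnogram` (a [hypnogram()]) and `events`
#'   (tibble: `onset_s`, `duration_s`, `type`, `intensity_step`, `train_id`,
#'   `outcome`).
#' @export
simulate_hypnogram <- function(config, subject = 1L, condition = c("CTR", "FRG")) {
  condition <- match.arg(condition)
  P <- config$transition[[condition]]
  abort_if(is.null(P), paste0("no transition matrix for condition ", condition))
  set.seed(stream_seed(config$seed, subject, condition, stream = 1L))

  n <- config$n_epochs
  cum <- t(apply(P, 1, cumsum))
  u <- runif(n)
  idx <- integer(n)
  cur <- 1L  # W at lights-off
  for (i in seq_len(n)) {
    cur <- 1L + sum(u[i] > cum[cur, ])
    idx[i] <- cur
  }
  stages <- SLEEP_STAGES[idx]
  h <- hypnogram(stages, lights_off = 0L, lights_on = n, epoch_len = config$epoch_len)

  ev <- simulate_rem_events(config, stages, condition)
  list(hypnogram = h, events = ev)
}

# Stimulation trains + spontaneous REM events for a fixed stage sequence.
simulate_rem_events <- function(config, stages, condition) {
  el <- config$epoch_len
  s <- config$stim
  rem <- stages == "REM"
  runs <- rle(rem)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rem_periods <- tibble::tibble(start = starts[runs$values], end = ends[runs$values])

  onset <- numeric(0); dur_v <- numeric(0); type <- character(0)
  step_v <- integer(0); train_v <- integer(0); outcome_v <- character(0)
  add <- function(o, d, ty, st, tr, oc) {
    onset <<- c(onset, o); dur_v <<- c(dur_v, d); type <<- c(type, ty)
    step_v <<- c(step_v, st); train_v <<- c(train_v, tr)
    outcome_v <<- c(outcome_v, oc)
  }
  train_id <- 0L
  if (condition == "FRG") {
    for (k in seq_len(nrow(rem_periods))) {
      t0 <- (rem_periods$start[k] - 1L) * el
      t_end <- rem_periods$end[k] * el
      t <- t0
      step <- 1L
      train_id <- train_id + 1L
      while (t + s$on_s <= t_end) {
        aroused <- runif(1) < s$arousal_prob[step]
        shift <- (t + s$on_s + s$off_s > t_end)  # REM period ends at this stim
        outcome <- if (shift) "stage_shift" else if (aroused) "arousal" else "none"
        add(t, s$on_s, "stimulation", step, train_id, outcome)
        if (shift) break
        if (aroused) {
          add(t + s$on_s, 3, "arousal", NA_integer_, NA_integer_, NA_character_)
          t <- t + s$on_s + s$suspend_s
          train_id <- train_id + 1L
          # resume at previously effective intensity within the same REM period
        } else {
          t <- t + s$on_s + s$off_s
          step <- min(step + 1L, s$n_steps)
        }
      }
    }
  }
  # spontaneous arousals / body movements during REM (both conditions)
  for (k in seq_len(nrow(rem_periods))) {
    t0 <- (rem_periods$start[k] - 1L) * el
    dur <- (rem_periods$end[k] - rem_periods$start[k] + 1L) * el
    for (tp in c("arousal", "body_movement")) {
      rate <- if (tp == "arousal") s$spont_arousal_rate else s$spont_movement_rate
      n_ev <- stats::rpois(1, rate * dur)
      if (n_ev > 0) {
        add(sort(t0 + runif(n_ev, 0, dur)), rep(3, n_ev), rep(tp, n_ev),
            rep(NA_integer_, n_ev), rep(NA_integer_, n_ev),
            rep(NA_character_, n_ev))
      }
    }
  }
  ev <- tibble::tibble(onset_s = onset, duration_s = dur_v, type = type,
                       intensity_step = step_v, train_id = train_v,
                       outcome = outcome_v)
  ev[order(ev$onset_s), ]
}

# Hermitian spectral synthesis shared by background and burst noise: returns a
# real series whose one-sided amplitude spectrum is `amp` (length n %/% 2 + 1).
spectral_noise <- function(n, amp) {
  half <- n %/% 2 + 1L
  phase <- runif(half, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  spec[1] <- 0
  full <- complex(length.out = n)
  full[seq_len(half)] <- spec
  if (n %% 2 == 0) {
    full[half] <- Re(spec[half])
    if (half > 2) full[n:(half + 1L)] <- Conj(spec[2:(half - 1L)])
  } else {
    full[n:(half + 1L)] <- Conj(spec[2:half])
  }
  Re(fft(full, inverse = TRUE)) / n
}

#' Simulate stimulation-locked EEG epochs with planted band bursts
#'
#' Each epoch is 1/f^beta background noise per channel plus, for the planted
#' bands, additive band-limited noise bursts whose power is calibrated per
#' frequency bin so that the instantaneous power ratio during the burst equals
#' the planted dB effect. Bursts plateau over `[onset_s, onset_s + duration_s]`
#' with 0.3-s cosine ramps outside the plateau, so the analysis window sees
#' full burst amplitude and the baseline window none. Channel weighting
#' multiplies the dB effect (`posterior_weight` on parieto-occipital channels,
#' `anterior_weight` elsewhere).
#'
#' @param config A [cohort_config()].
#' @param subject Subject index (determines the subject's planted alpha dB).
#' @param n_epochs Number of epochs to generate.
#' @param alpha_db Optional override of the subject's planted alpha effect (dB);
#'   `NA` entries of `config$eeg$bursts$db` are never planted.
#' @param channels Optional channel subset (default: full montage).
#' @return A list with `epochs` (class `eeg_epochs`: `data` array time x
#'   channel x epoch, `fs`, `times`, `channels`, `montage`) and `truth`
#'   (tibble of planted per-band dB for this subject, including the
#'   posterior-mean alpha dB).
#' @export
simulate_eeg_epochs <- function(config, subject = 1L, n_epochs = 20L,
                                alpha_db = NULL, channels = NULL) {
  eegp <- config$eeg
  montage <- eegp$montage
  if (!is.null(channels)) montage <- montage[montage$channel %in% channels, ]
  fs <- eegp$fs
  win <- eegp$window
  abort_if(diff(win) < max(eegp$bursts$onset_s + eegp$bursts$duration_s) - win[1],
           "epoch window shorter than the planted burst")
  n_t <- round(diff(win) * fs) + 1L
  times <- win[1] + (seq_len(n_t) - 1L) / fs

  set.seed(stream_seed(config$seed, subject, "EEG", stream = 3L))
  bursts <- eegp$bursts
  subj_alpha <- if (!is.null(alpha_db)) alpha_db else {
    bursts$db[bursts$band == "alpha"] + rnorm(1, 0, eegp$alpha_subject_sd)
  }
  bursts$db[bursts$band == "alpha"] <- subj_alpha

  post <- posterior_channels(montage)
  n_ch <- nrow(montage)
  bands <- eeg_bands()

  half <- n_t %/% 2 + 1L
  f_grid <- (seq_len(half) - 1L) * fs / n_t
  amp_bg <- c(0, f_grid[-1]^(-eegp$noise_exponent / 2))

  # per-band templates: bin mask and plateau window. Burst spectra are padded
  # by 1.5 wavelet frequency-SDs (sigma_f = f / cycles(f) for the 7..42 cycle
  # ramp) into unplanted spectrum, so wavelet smoothing does not dilute the
  # planted ratio at analysis-band boundary bins; where two planted bands
  # abut, each burst extends to the midpoint of the gap instead.
  planted <- bursts[is.finite(bursts$db) & bursts$db != 0, ]
  planted_edges <- dplyr::left_join(planted, bands, by = "band")
  band_info <- purrr::pmap(bursts, function(band, db, onset_s, duration_s, ...) {
    b <- bands[bands$band == band, ]
    abort_if(nrow(b) == 0, paste0("unknown burst band: ", band))
    below <- planted_edges$hi[planted_edges$hi <= b$lo]
    above <- planted_edges$lo[planted_edges$lo >= b$hi]
    lo_eff <- if (length(below)) (max(below) + b$lo) / 2 else
      b$lo - 1.5 * b$lo / (b$lo + 2)
    hi_eff <- if (length(above)) (min(above) + b$hi) / 2 else
      b$hi + 1.5 * b$hi / (b$hi + 2)
    mask <- f_grid >= lo_eff & f_grid <= hi_eff
    ramp <- 0.3
    w <- rep(0, n_t)
    core <- times >= onset_s & times <= onset_s + duration_s
    w[core] <- 1
    up <- times >= onset_s - ramp & times < onset_s
    w[up] <- (1 + cos(pi * (times[up] - onset_s) / ramp)) / 2
    dn <- times > onset_s + duration_s & times <= onset_s + duration_s + ramp
    w[dn] <- (1 + cos(pi * (times[dn] - onset_s - duration_s) / ramp)) / 2
    list(mask = mask, w = w, db = db)
  })

  dat <- array(0, dim = c(n_t, n_ch, n_epochs))
  for (e in seq_len(n_epochs)) {
    for (c_i in seq_len(n_ch)) {
      x <- spectral_noise(n_t, amp_bg)
      for (b_i in seq_along(band_info)) {
        bi <- band_info[[b_i]]
        if (is.na(bi$db)) next
        w_ch <- if (montage$channel[c_i] %in% post) bursts$posterior_weight[b_i]
                else bursts$anterior_weight[b_i]
        eff <- bi$db * w_ch
        if (abs(eff) < 1e-12) next
        amp_b <- amp_bg * ifelse(bi$mask, sqrt(10^(eff / 10) - 1), 0)
        x <- x + spectral_noise(n_t, amp_b) * bi$w
      }
      dat[, c_i, e] <- x
    }
  }
  epochs <- structure(list(data = dat, fs = fs, times = times,
                           channels = montage$channel, montage = montage),
                      class = "eeg_epochs")
  truth <- dplyr::mutate(
    bursts[, c("band", "db")],
    subject = subject,
    posterior_db = .data$db * bursts$posterior_weight,
    anterior_db = .data$db * bursts$anterior_weight
  )
  list(epochs = epochs, truth = truth)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (%g..%g s)\n",
              dim(x$data)[3], dim(x$data)[2], dim(x$data)[1], x$fs,
              min(x$times), max(x$times)))
  invisible(x)
}

raised_cosine_dip <- function(t, onset, duration) {
  ifelse(t >= onset & t <= onset + duration,
         (1 - cos(2 * pi * (t - onset) / duration)) / 2, 0)
}

bateman <- function(t, tau) {
  b <- ifelse(t < 0, 0, exp(-t / tau[2]) - exp(-t / tau[1]))
  pk <- max(b)
  if (pk > 0) b / pk else b
}

#' Simulate one session of autonomic trials
#'
#' 28 trials (14 negative, 14 neutral) per session. Each trial carries an
#' inter-beat-interval series with a planted raised-cosine heart-rate dip
#' (onset 0.5 s post-stimulus, configured amplitude plus trial-level Gaussian
#' amplitude noise) and an electrodermal trace with Bateman-kernel skin
#' conductance responses at 1-3 s latency. Planted deceleration amplitudes
#' follow the configured condition x session table: by default the control
#' condition habituates from T0 to T1 while fragmentation stays flat.
#'
#' @param config A [cohort_config()].
#' @param subject Subject index.
#' @param condition `"CTR"` or `"FRG"`.
#' @param session `"T0"`, `"T1"` or `"T2"`.
#' @param hrd_shift Optional additive shift (bpm) applied to every planted
#'   deceleration amplitude of this session (used to plant subject-level
#'   coupling effects).
#' @return A tibble with one row per trial: metadata columns, the planted
#'   amplitude, and list-columns `ibi` (tibble `beat_time_ms`, `ibi_ms`) and
#'   `eda` (tibble `time_s`, `conductance_uS`), plus `stim_onset_s` within the
#'   trial clock and the planted `scr_amp`.
#' @export
simulate_autonomic_trials <- function(config, subject = 1L,
                                      condition = c("CTR", "FRG"),
                                      session = c("T0", "T1", "T2"),
                                      hrd_shift = 0) {
  condition <- match.arg(condition)
  session <- match.arg(session)
  a <- config$autonomic
  subj_re <- hrd_subject_effect(config, subject)
  stim_re <- hrd_stimulus_effects(config, condition)
  set.seed(stream_seed(config$seed, subject, condition, session, stream = 4L))

  n_per <- a$n_trials_per_type
  types <- sample(rep(c("negative", "neutral"), each = n_per))
  stim_k <- stats::ave(seq_along(types), types, FUN = seq_along)
  base_hr <- a$hr_bpm + rnorm(1, 0, a$hr_subject_sd)
  abort_if(base_hr <= 0, "nonpositive baseline heart rate")
  stim_onset <- 5        # trial clock: -5..+9 s around stimulus
  t_span <- c(0, 14)
  fs_eda <- a$fs_eda
  tau <- a$tau

  trials <- purrr::map(seq_along(types), function(i) {
    ty <- types[i]
    sid <- paste(condition, ty, stim_k[i], sep = "_")
    amp_planted <- a$hrd_amp$amp[a$hrd_amp$condition == condition &
                                   a$hrd_amp$session == session &
                                   a$hrd_amp$stimulus_type == ty] + hrd_shift
    amp <- amp_planted + subj_re + stim_re[[sid]] + rnorm(1, 0, a$hrd_noise_sd)
    # beats from the integrated instantaneous rate, so each IBI reflects the
    # mean heart rate over its interval rather than a delayed point sample
    tg <- seq(t_span[1], t_span[2], by = 0.01)
    hr_t <- pmax(base_hr - amp * raised_cosine_dip(tg - stim_onset,
                                                   a$dip_onset_s,
                                                   a$dip_duration_s), 25)
    cum_beats <- cumsum(hr_t / 60) * 0.01
    beats <- approx(cum_beats, tg, xout = seq_len(floor(max(cum_beats))))$y
    ibi <- tibble::tibble(beat_time_ms = beats * 1000,
                          ibi_ms = c(beats[1] - t_span[1], diff(beats)) * 1000)

    # EDA: tonic + drift + planted SCR(s) + noise
    tt <- seq(t_span[1], t_span[2], by = 1 / fs_eda)
    responds <- runif(1) < (if (ty == "negative") a$p_respond_negative
                            else a$p_respond_neutral)
    scr_amp <- 0
    eda <- a$tonic_uS + 0.01 * (tt - mean(tt)) / diff(t_span) +
      rnorm(length(tt), 0, a$eda_noise_sd)
    if (responds) {
      mu <- if (ty == "negative") a$scr_amp_negative else a$scr_amp_neutral
      scr_amp <- max(rnorm(1, mu, mu * a$scr_amp_cv), 0.06)
      lat <- runif(1, 1, 3)
      eda <- eda + scr_amp * bateman(tt - stim_onset - lat, tau)
    }
    tibble::tibble(
      trial = i, stimulus_type = ty, stimulus_id = sid,
      planted_hrd = amp_planted,
      scr_amp = scr_amp, stim_onset_s = stim_onset,
      ibi = list(ibi),
      eda = list(tibble::tibble(time_s = tt, conductance_uS = eda))
    )
  })
  dplyr::bind_rows(trials) |>
    dplyr::mutate(subject = subject, condition = condition, session = session,
                  .before = 1)
}

# subject- and stimulus-level random intercepts shared across sessions: the
# same stimuli recur within a condition and a subject's orienting response is
# correlated across the whole study
hrd_subject_effect <- function(config, subject) {
  set.seed(stream_seed(config$seed, subject, "hrd-subject", stream = 12L))
  rnorm(1, 0, config$autonomic$hrd_subject_sd)
}

hrd_stimulus_effects <- function(config, condition) {
  a <- config$autonomic
  set.seed(stream_seed(config$seed, 0L, condition, "hrd-stimuli", stream = 13L))
  ids <- paste(condition, rep(c("negative", "neutral"), each = a$n_trials_per_type),
               rep(seq_len(a$n_trials_per_type), times = 2), sep = "_")
  stats::setNames(rnorm(length(ids), 0, a$hrd_stimulus_sd), ids)
}

#' Trial-level heart-rate-deceleration measurements (shortcut generator)
#'
#' Produces, for the whole cohort, the deceleration values the full
#' physiological pipeline would measure, without synthesising beat and
#' conductance traces: measured HRD is the planted cell amplitude plus
#' subject and stimulus random intercepts plus trial noise, floored at zero
#' (a trial whose planted amplitude is negative shows no dip, so the
#' pre-mean-minus-post-minimum readout is ~0). A calibration test keeps this
#' shortcut consistent with the signal-level path. Used by the
#' inference-power studies where thousands of cohorts are needed.
#'
#' @param config A [cohort_config()].
#' @param hrd_shift Optional per-subject additive shift applied to FRG
#'   post-sleep sessions (vector of length `n_subjects`).
#' @return Long tibble: `subject`, `condition`, `session`, `stimulus_type`,
#'   `stimulus_id`, `trial`, `planted_hrd`, `hrd_bpm`.
#' @export
simulate_hrd_measurements <- function(config, hrd_shift = NULL) {
  a <- config$autonomic
  if (is.null(hrd_shift)) hrd_shift <- rep(0, config$n_subjects)
  cells <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects), condition = c("CTR", "FRG"),
    session = c("T0", "T1", "T2"),
    stimulus_type = c("negative", "neutral"),
    k = seq_len(a$n_trials_per_type)
  )
  cells <- dplyr::left_join(cells, a$hrd_amp,
                            by = c("condition", "session", "stimulus_type"))
  subj_re <- vapply(seq_len(config$n_subjects), function(s) {
    hrd_subject_effect(config, s)
  }, numeric(1))
  stim_re <- c(hrd_stimulus_effects(config, "CTR"),
               hrd_stimulus_effects(config, "FRG"))
  cells$stimulus_id <- paste(cells$condition, cells$stimulus_type, cells$k,
                             sep = "_")
  shift <- ifelse(cells$condition == "FRG" & cells$session != "T0",
                  hrd_shift[cells$subject], 0)
  set.seed(stream_seed(config$seed, 0L, "hrd-shortcut", stream = 14L))
  amp <- cells$amp + shift + subj_re[cells$subject] +
    stim_re[cells$stimulus_id] + rnorm(nrow(cells), 0, a$hrd_noise_sd)
  tibble::tibble(
    subject = cells$subject, condition = cells$condition,
    session = cells$session, stimulus_type = cells$stimulus_type,
    stimulus_id = cells$stimulus_id, trial = cells$k,
    planted_hrd = cells$amp + shift, hrd_bpm = pmax(amp, 0)
  )
}

#' Simulate one recognition test from an equal-variance signal-detection model
#'
#' 40 OLD and 40 NEW items (half negative, half neutral). OLD evidence is
#' N(d', 1), NEW evidence N(0, 1); the response is OLD when evidence exceeds
#' the criterion placed at `d'/2 + criterion`.
#'
#' @param config A [cohort_config()].
#' @param subject,condition,session As in [simulate_autonomic_trials()].
#' @param dprime Optional override of the planted d-prime (single value applied
#'   to both stimulus types).
#' @return Tibble: `trial`, `truth` (`OLD`/`NEW`), `stimulus_type`, `response`.
#' @export
simulate_recognition <- function(config, subject = 1L,
                                 condition = c("CTR", "FRG"),
                                 session = c("T0", "T1", "T2"),
                                 dprime = NULL) {
  condition <- match.arg(condition)
  session <- match.arg(session)
  m <- config$memory
  set.seed(stream_seed(config$seed, subject, condition, session, stream = 5L))
  subj_dp <- rnorm(1, 0, m$subject_sd)

  grid <- tidyr::expand_grid(
    truth = c("OLD", "NEW"),
    stimulus_type = c("negative", "neutral")
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = ifelse(.data$truth == "OLD", m$n_old_per_type,
                             m$n_new_per_type)) |>
    dplyr::ungroup()
  out <- purrr::pmap(grid, function(truth, stimulus_type, n) {
    dp <- if (!is.null(dprime)) dprime else {
      max(m$dprime[[session]] +
            ifelse(stimulus_type == "negative", m$valence_boost, 0) + subj_dp, 0)
    }
    abort_if(dp < 0, "planted d-prime must be >= 0")
    ev <- rnorm(n, mean = ifelse(truth == "OLD", dp, 0), sd = 1)
    resp <- ifelse(ev > dp / 2 + m$criterion, "OLD", "NEW")
    tibble::tibble(truth = truth, stimulus_type = stimulus_type, response = resp)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(subject = subject, condition = condition, session = session,
                  .before = 1)
}

#' Simulate a coupled cohort of band topographies and HRD changes
#'
#' The subject-level shortcut used for inference-calibration studies: each
#' subject's planted alpha effect (base + Gaussian subject deviation) is
#' mapped onto the scalp through the configured posterior/anterior weights
#' with per-channel measurement noise, and the over-session change in heart
#' rate deceleration is `slope * alpha + noise`. With the default slope 1,
#' subject SD 1 and noise SD 1.02 the planted subject-level correlation is
#' ~0.7. Setting `couple = FALSE` gives a fully decoupled (null) behaviour
#' vector; `null_topography = TRUE` removes the planted topographic effect.
#'
#' @param config A [cohort_config()].
#' @param band Which planted band to map (default `"alpha"`).
#' @param couple Couple behaviour to the planted alpha? (default TRUE)
#' @param null_topography Zero out the planted effect? (default FALSE)
#' @param seed Optional integer overriding the config-derived stream seed.
#' @return List: `topography` (subjects x channels matrix of band dB),
#'   `behavior` (ΔHRD per subject, bpm), `alpha` (planted subject effects),
#'   `montage`, `planted_r` (implied subject-level correlation).
#' @export
simulate_coupled_topographies <- function(config, band = "alpha",
                                          couple = TRUE,
                                          null_topography = FALSE,
                                          seed = NULL) {
  set.seed(if (is.null(seed)) stream_seed(config$seed, 0L, "coupling", stream = 6L)
           else seed)
  cp <- config$coupling
  eegp <- config$eeg
  montage <- eegp$montage
  post <- montage$channel %in% posterior_channels(montage)
  b <- eegp$bursts[eegp$bursts$band == band, ]
  abort_if(nrow(b) == 0, paste0("band ", band, " not planted in config"))
  w <- ifelse(post, b$posterior_weight, b$anterior_weight)

  n <- config$n_subjects
  alpha <- cp$alpha_base_db + rnorm(n, 0, eegp$alpha_subject_sd)
  eff <- if (null_topography) rep(0, n) else alpha
  topo <- outer(eff, w) + matrix(rnorm(n * nrow(montage), 0, cp$topo_noise_sd),
                                 n, nrow(montage))
  colnames(topo) <- montage$channel
  # behaviour is the measured session-mean difference, so it carries both the
  # subject-level coupling noise and the trial-averaging noise of two
  # 28-trial session means
  a <- config$autonomic
  meas_sd <- a$hrd_noise_sd * sqrt(2 / (2 * a$n_trials_per_type))
  noise_tot <- sqrt(cp$noise_sd^2 + meas_sd^2)
  behavior <- if (couple) cp$slope * (alpha - cp$alpha_base_db) +
    rnorm(n, 0, noise_tot) else rnorm(n, 0, noise_tot)
  sd_a <- eegp$alpha_subject_sd
  planted_r <- cp$slope * sd_a / sqrt(cp$slope^2 * sd_a^2 + noise_tot^2)
  list(topography = topo, behavior = behavior, alpha = alpha,
       montage = montage, planted_r = if (couple) planted_r else 0)
}
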