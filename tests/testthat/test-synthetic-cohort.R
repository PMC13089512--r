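test_that("generators are pure functions of (config, subject, condition, session)", {
  cfg <- tiny_config(seed = 9)
  a <- simulate_hypnogram(cfg, 2, "FRG")
  b <- simulate_hypnogram(cfg, 2, "FRG")
  expect_identical(a, b)
  expect_false(identical(a$hypnogram$stages,
                         simulate_hypnogram(cfg, 3, "FRG")$hypnogram$stages))

  e1 <- simulate_eeg_epochs(cfg, 1, n_epochs = 3, channels = c("Cz", "Oz"))
  e2 <- simulate_eeg_epochs(cfg, 1, n_epochs = 3, channels = c("Cz", "Oz"))
  expect_identical(e1$epochs$data, e2$epochs$data)

  r1 <- simulate_recognition(cfg, 1, "CTR", "T1")
  r2 <- simulate_recognition(cfg, 1, "CTR", "T1")
  expect_identical(r1, r2)
})

test_that("control nights carry no stimulations; forced arousal gives 1-stim trains", {
  cfg <- tiny_config(seed = 2)
  ctr <- simulate_hypnogram(cfg, 1, "CTR")
  expect_equal(sum(ctr$events$type == "stimulation"), 0)

  cfg1 <- tiny_config(seed = 2, stim = list(arousal_prob = rep(1, 7)))
  frg <- simulate_hypnogram(cfg1, 1, "FRG")
  stim <- frg$events[frg$events$type == "stimulation", ]
  per_train <- table(stim$train_id[stim$outcome != "stage_shift"])
  expect_true(all(per_train == 1))
  # and every non-terminal stimulation elicited an arousal at step 1
  expect_true(all(stim$intensity_step[stim$outcome == "arousal"] == 1))
})

test_that("empirical transition frequencies match the generator matrix", {
  cfg <- cohort_config(n_subjects = 2, seed = 5, n_epochs = 10000)
  h <- simulate_hypnogram(cfg, 1, "CTR")$hypnogram
  tm <- transition_matrix(h)
  P <- cfg$transition$CTR
  n_row <- rowSums(tm$counts)
  for (i in which(n_row > 200)) {
    se <- sqrt(P[i, ] * (1 - P[i, ]) / n_row[i])
    expect_true(all(abs(tm$P[i, ] - P[i, ]) <= 3 * se + 1e-12),
                info = paste("row", SLEEP_STAGES[i]))
  }
})

test_that("planted EEG band bursts are recovered and nulls stay at 0 dB", {
  cfg <- tiny_config(seed = 3)
  # null construction: no planted effects at all
  null_bursts <- cfg$eeg$bursts
  null_bursts$db <- 0
  cfg0 <- tiny_config(seed = 3, eeg = list(bursts = null_bursts,
                                           alpha_subject_sd = 0))
  sim0 <- simulate_eeg_epochs(cfg0, 1, n_epochs = 50, channels = "Pz")
  db0 <- baseline_db(morlet_ersp(sim0$epochs, freqs = seq(5, 40, 0.5)))
  post <- db0$times >= 0 & db0$times <= 6
  vals <- db0$values[1, , post][db0$valid[, post]]
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.2)

  # planted +3 dB alpha burst recovered within 0.5 dB on posterior channels
  sim3 <- simulate_eeg_epochs(cfg, 1, n_epochs = 120, alpha_db = 3,
                              channels = c("Pz", "Oz"))
  db3 <- band_topography(baseline_db(morlet_ersp(sim3$epochs,
                                                 freqs = seq(5, 40, 0.5))))
  alpha <- db3$db[db3$band == "alpha"]
  expect_true(all(abs(alpha - 3) < 0.5))
})

test_that("planted HRD amplitudes and SCR drivers behave as configured", {
  # zero planted deceleration, small noise -> measured HRD ~ 0
  amp0 <- tidyr::expand_grid(condition = c("CTR", "FRG"),
                             session = c("T0", "T1", "T2"),
                             stimulus_type = c("negative", "neutral"))
  amp0$amp <- 0
  cfg0 <- tiny_config(seed = 4, autonomic = list(
    hrd_amp = amp0, hrd_noise_sd = 0.2, hrd_subject_sd = 0,
    hrd_stimulus_sd = 0))
  tr0 <- simulate_autonomic_trials(cfg0, 1, "CTR", "T0")
  h0 <- purrr::pmap_dbl(tr0, function(ibi, stim_onset_s, ...) {
    hrd(ibi, stim_onset_s)$hrd_bpm
  })
  expect_lt(abs(mean(h0)), 3 * 0.2 / sqrt(length(h0)) + 0.15)

  # planted 5 bpm with 1 bpm noise -> mean recovered within 1 bpm at 28 trials
  amp5 <- amp0; amp5$amp <- 5
  cfg5 <- tiny_config(seed = 4, autonomic = list(
    hrd_amp = amp5, hrd_noise_sd = 1, hrd_subject_sd = 0,
    hrd_stimulus_sd = 0))
  tr5 <- simulate_autonomic_trials(cfg5, 1, "CTR", "T0")
  h5 <- purrr::pmap_dbl(tr5, function(ibi, stim_onset_s, ...) {
    hrd(ibi, stim_onset_s)$hrd_bpm
  })
  expect_lt(abs(mean(h5) - 5), 1)

  # zero SCR driver -> all trials below the response threshold
  cfg_noscr <- tiny_config(seed = 4, autonomic = list(
    p_respond_negative = 0, p_respond_neutral = 0))
  trn <- simulate_autonomic_trials(cfg_noscr, 1, "CTR", "T0")
  resp <- purrr::pmap_lgl(trn, function(eda, stim_onset_s, ...) {
    eda10 <- preprocess_eda(eda, fs = cfg_noscr$autonomic$fs_eda)
    cda_scr(eda10, stim_onset_s)$responded
  })
  expect_false(any(resp))
})

test_that("the trial-level HRD shortcut is calibrated against the signal path", {
  cfg <- cohort_config(n_subjects = 2, seed = 6,
                       autonomic = list(hrd_noise_sd = 1))
  full <- simulate_autonomic_trials(cfg, 1, "FRG", "T0")
  measured <- purrr::pmap_dbl(full, function(ibi, stim_onset_s, ...) {
    hrd(correct_ibi(ibi)$ibi, stim_onset_s)$hrd_bpm
  })
  short <- simulate_hrd_measurements(cfg)
  short <- short[short$subject == 1 & short$condition == "FRG" &
                   short$session == "T0", ]
  # same planted model: cell means agree within the combined sampling error
  expect_lt(abs(mean(measured) - mean(short$hrd_bpm)), 1.5)
})

test_that("recognition responses follow the signal-detection model", {
  cfg <- tiny_config(seed = 5)
  # d' = 0, criterion 0: hit rate and false-alarm rate both near 0.5
  r0 <- purrr::map_dfr(1:30, function(s)
    simulate_recognition(cfg, s, "CTR", "T0", dprime = 0))
  counts <- recognition_counts(r0)
  expect_lt(abs(counts$hits / counts$n_old - 0.5), 0.05)
  expect_lt(abs(counts$false_alarms / counts$n_new - 0.5), 0.05)

  # criterion -> +Inf: everything called NEW
  cfg_inf <- tiny_config(seed = 5, memory = list(criterion = Inf))
  r_inf <- simulate_recognition(cfg_inf, 1, "CTR", "T0")
  expect_true(all(r_inf$response == "NEW"))

  # planted d' = 2 recovered within 0.35 over 200 simulated subjects
  cfg2 <- cohort_config(n_subjects = 200, seed = 8,
                        memory = list(subject_sd = 0))
  dps <- purrr::map_dbl(1:200, function(s) {
    tab <- dprime_table(simulate_recognition(cfg2, s, "CTR", "T0", dprime = 2))
    tab$dprime
  })
  expect_lt(abs(mean(dps) - 2), 0.35)

  expect_error(simulate_recognition(cfg, 1, "CTR", "T0", dprime = -1), ">= 0")
})

test_that("config validation rejects malformed parameter blocks", {
  expect_error(cohort_config(n_subjects = 1), ">= 2")
  bad_tr <- default_transitions()
  bad_tr$CTR[1, ] <- c(0.5, 0.1, 0.1, 0.1, 0.1)
  expect_error(cohort_config(transition = bad_tr), "stochastic")
  expect_error(cohort_config(stim = list(on_s = -1)), "> 0")
  expect_error(cohort_config(memory = list(dprime = c(T0 = -0.5, T1 = 1, T2 = 1))),
               "d-prime")
  expect_error(simulate_hypnogram(tiny_config(), 1, "XXX"))
})
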