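test_that("IBI artifact correction flags and interpolates spurious beats", {
  clean <- correct_ibi(constant_ibi())
  expect_equal(clean$n_flagged, 0)
  expect_equal(clean$ibi$ibi_ms, rep(1000, nrow(clean$ibi)))

  # one 400-ms spurious beat inside a 1000-ms rhythm
  v <- rep(1000, 20); v[10] <- 400
  out <- correct_ibi(tibble::tibble(beat_time_ms = cumsum(v), ibi_ms = v))
  expect_equal(which(out$ibi$corrected), 10)
  expect_equal(out$ibi$ibi_ms[10], 1000, tolerance = 1e-6)

  # three planted artifacts, exactly those flagged by the criterion oracle
  set.seed(3)
  v2 <- 1000 + rnorm(60, 0, 15)
  art_idx <- c(12, 30, 49)
  v2[art_idx] <- c(420, 1800, 500)
  got <- correct_ibi(tibble::tibble(beat_time_ms = cumsum(v2), ibi_ms = v2))
  # oracle: same sliding-median criterion computed by direct loops
  qd <- IQR(diff(v2)) / 2
  thr <- max(min(4.5 * qd, 0.3 * median(v2)), 120)
  flags <- vapply(seq_along(v2), function(i) {
    idx <- setdiff(max(1, i - 5):min(length(v2), i + 5), i)
    abs(v2[i] - median(v2[idx])) > thr
  }, logical(1))
  expect_equal(which(got$ibi$corrected), which(flags))
  expect_setequal(which(flags), art_idx)

  # majority-artifact records are rejected with a diagnostic
  bad <- rep(c(400, 1600), 10)
  expect_error(correct_ibi(tibble::tibble(beat_time_ms = cumsum(bad),
                                          ibi_ms = bad)), "rejected")
  expect_error(correct_ibi(c(1000, 1000, 1000)), "four beats")
})

test_that("HRD implements pre-mean minus post-minimum with its invariances", {
  # constant 60 bpm -> 0
  expect_equal(hrd(constant_ibi(1000), 5)$hrd_bpm, 0)

  # constructed trial: 60 bpm before, one 55-bpm dip after onset -> 5 bpm
  bt <- cumsum(rep(1000, 14))
  hr_vals <- rep(60, 14)
  hr_vals[9:10] <- 55                       # 3-4 s post-onset (onset at 5 s)
  ibi <- tibble::tibble(beat_time_ms = bt, ibi_ms = 60000 / hr_vals)
  expect_equal(hrd(ibi, 5)$hrd_bpm, 5, tolerance = 1e-9)

  # translation in time: shifting beats and onset together changes nothing
  ibi_shift <- dplyr::mutate(ibi, beat_time_ms = beat_time_ms + 3000)
  expect_equal(hrd(ibi_shift, 8)$hrd_bpm, hrd(ibi, 5)$hrd_bpm)

  # uniform HR offset leaves the deceleration unchanged
  ibi_off <- tibble::tibble(beat_time_ms = bt, ibi_ms = 60000 / (hr_vals + 20))
  expect_equal(hrd(ibi_off, 5)$hrd_bpm, hrd(ibi, 5)$hrd_bpm, tolerance = 0.2)

  # insufficient coverage is an explicit error
  expect_error(hrd(constant_ibi(1000, duration_s = 8), 5), "cover")
})

test_that("EDA pre-processing decimates, low-passes and smooths as specified", {
  fs <- 50
  const <- preprocess_eda(rep(2.5, fs * 30), fs)
  expect_equal(diff(const$time_s)[1], 0.1)
  expect_lt(max(abs(const$conductance_uS - 2.5)), 1e-9)

  # a 5-Hz oscillation is attenuated below 5% of its input amplitude
  tt <- seq(0, 30, by = 1 / fs)
  osc <- preprocess_eda(2 + sin(2 * pi * 5 * tt), fs)
  mid <- osc$conductance_uS[osc$time_s > 2 & osc$time_s < 28]
  expect_lt((max(mid) - min(mid)) / 2, 0.05)

  # a step input becomes a monotone smoothed ramp without large overshoot
  step <- c(rep(1, fs * 15), rep(2, fs * 15))
  sm <- preprocess_eda(step, fs)
  core <- sm$conductance_uS[sm$time_s > 5 & sm$time_s < 25]
  expect_lt(max(core), 2 + 0.08)        # 2nd-order Butterworth overshoot bound
  expect_gt(min(core), 1 - 0.08)
  ramp <- sm$conductance_uS[sm$time_s > 13 & sm$time_s < 17]
  expect_true(all(diff(ramp) > -0.02))

  expect_error(preprocess_eda(rep(1, 20), 50), "warm-up")
  expect_error(preprocess_eda(rep(1, 500), 8), ">= 10")
})

test_that("CDA.SCR recovers planted drivers and applies the threshold rule", {
  flat <- tibble::tibble(time_s = seq(0, 14, 0.1),
                         conductance_uS = rep(2, 141))
  s0 <- cda_scr(flat, 5)
  expect_equal(s0$cda_scr, 0)
  expect_false(s0$responded)

  # single Bateman SCR with driver mass m at 2-s latency:
  # mean driver over the 5-s window = m / 5 within 10%
  for (m in c(0.2, 0.5, 0.8)) {
    s <- cda_scr(scr_trace(m), 5)
    expect_lt(abs(s$cda_scr - m / 5) / (m / 5), 0.1)
  }

  # approximate linearity across a 4x amplitude range
  v1 <- cda_scr(scr_trace(0.2), 5)$cda_scr
  v4 <- cda_scr(scr_trace(0.8), 5)$cda_scr
  expect_lt(abs(v4 / v1 - 4) / 4, 0.1)

  # 0.04-uS response stays below the 0.05-uS threshold
  expect_false(cda_scr(scr_trace(0.04), 5)$responded)
  expect_true(cda_scr(scr_trace(0.10), 5)$responded)
})

test_that("non-responder screening applies the 20% negative-T0 rule", {
  mk <- function(subject, condition, n_resp) {
    tibble::tibble(subject = subject, condition = condition, session = "T0",
                   stimulus_type = "negative",
                   responded = c(rep(TRUE, n_resp), rep(FALSE, 14 - n_resp)))
  }
  trials <- dplyr::bind_rows(
    mk(1, "CTR", 2), mk(1, "FRG", 10),   # 2/14 = 14.3% in CTR -> excluded
    mk(2, "CTR", 3), mk(2, "FRG", 3),    # 3/14 = 21.4% in both -> retained
    mk(3, "CTR", 12), mk(3, "FRG", 1)    # fails in FRG -> excluded
  )
  out <- screen_nonresponders(trials)
  expect_equal(out$keep, c(FALSE, TRUE, FALSE))

  # cohort fixture equals the rule applied by hand
  set.seed(8)
  co <- tidyr::expand_grid(subject = 1:10, condition = c("CTR", "FRG"),
                           trial = 1:14)
  co$session <- "T0"; co$stimulus_type <- "negative"
  co$responded <- runif(nrow(co)) < 0.3
  got <- screen_nonresponders(co)
  oracle <- co |>
    dplyr::group_by(subject, condition) |>
    dplyr::summarise(f = mean(responded), .groups = "drop") |>
    dplyr::group_by(subject) |>
    dplyr::summarise(keep = min(f) >= 0.2)
  expect_equal(got$keep, oracle$keep)
})

test_that("resting HRV indices match closed forms", {
  expect_error(resting_hrv(rep(1000, 30)), "too short")
  const <- resting_hrv(rep(1000, 130))
  expect_equal(const$sdnn_ms, 0)
  expect_equal(const$rmssd_ms, 0)
  expect_equal(const$mean_hr_bpm, 60)

  alt <- resting_hrv(rep(c(990, 1010), 65))
  expect_equal(alt$rmssd_ms, 20)
  expect_equal(alt$mean_hr_bpm, 60, tolerance = 1e-3)

  set.seed(2)
  v <- 900 + runif(150, 0, 200)
  got <- resting_hrv(v)
  expect_equal(got$sdnn_ms, sd(v))
  expect_equal(got$rmssd_ms, sqrt(mean(diff(v)^2)))
})
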