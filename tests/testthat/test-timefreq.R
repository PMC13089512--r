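test_that("a pure tone localizes to its frequency bin", {
  ep <- sinusoid_epochs(10, n_epochs = 3, noise_sd = 0)
  ersp <- morlet_ersp(ep, freqs = seq(5, 40, 0.2))
  mid <- which.min(abs(ersp$times - 5))
  prof <- ersp$values[1, , mid]
  expect_lte(abs(ersp$freqs[which.max(prof)] - 10), 0.2)
})

test_that("averaging identity: duplicated epochs give the identical ERSP", {
  ep1 <- sinusoid_epochs(12, n_epochs = 1, noise_sd = 0.05)
  ep2 <- ep1
  ep2$data <- array(ep1$data[, , c(1, 1)], dim = c(dim(ep1$data)[1], 1, 2))
  e1 <- morlet_ersp(ep1, freqs = seq(5, 40, 1))
  e2 <- morlet_ersp(ep2, freqs = seq(5, 40, 1))
  expect_equal(e1$values, e2$values, tolerance = 1e-10)
})

test_that("cycle ramp, grid and validity mask follow the analysis definition", {
  ep <- sinusoid_epochs(10, 1, noise_sd = 0)
  ersp <- morlet_ersp(ep)
  expect_equal(range(ersp$freqs), c(5, 40))
  expect_equal(diff(ersp$freqs)[1], 0.2, tolerance = 1e-12)
  expect_equal(diff(ersp$times)[1], 0.016)
  # edges with wavelet support outside the epoch are invalid; baseline valid
  expect_false(ersp$valid[1, 1])
  base_idx <- ersp$times >= -2 & ersp$times <= -1
  expect_true(all(ersp$valid[, base_idx]))
  expect_error(morlet_ersp(ep, freqs = seq(5, 70, 0.2)), "Nyquist")
})

test_that("dB baseline correction implements 10*log10(power/baseline)", {
  ep <- sinusoid_epochs(10, 1, noise_sd = 0)
  ersp <- morlet_ersp(ep, freqs = seq(8, 12, 0.2))
  db <- baseline_db(ersp)
  # stationary tone: ratio 1 -> 0 dB at the tone frequency, everywhere valid
  i10 <- which.min(abs(db$freqs - 10))
  vals <- db$values[1, i10, db$valid[i10, ]]
  expect_lt(max(abs(vals)), 0.05)

  # multiplying power by k shifts every dB value by 10*log10(k)
  ersp_k <- ersp
  ersp_k$values <- ersp$values * 4
  db_k <- baseline_db(ersp_k)
  expect_equal(db_k$values, db$values, tolerance = 1e-9)

  # doubling the amplitude post-stimulus: +10*log10(4) = 6.02 dB
  ep2 <- sinusoid_epochs(10, n_epochs = 20, amp_pre = 1, amp_post = 2,
                         noise_sd = 0.01)
  db2 <- baseline_db(morlet_ersp(ep2, freqs = seq(8, 12, 0.2)))
  post <- db2$times >= 1 & db2$times <= 5
  expect_equal(mean(db2$values[1, i10, post]), 10 * log10(4), tolerance = 0.2)

  # zero baseline power is flagged, not propagated as -Inf
  ersp0 <- ersp
  ersp0$values[1, 1, ] <- 0
  db0 <- baseline_db(ersp0)
  expect_true(attr(db0, "flagged")[1, 1])
  expect_true(all(is.na(db0$values[1, 1, ])))
})

test_that("stationary noise is flat in time after dB correction", {
  set.seed(31)
  fs <- 125
  n_t <- round(18 * fs) + 1
  dat <- array(rnorm(n_t * 150), dim = c(n_t, 1, 150))
  ep <- structure(list(data = dat, fs = fs,
                       times = -3 + (seq_len(n_t) - 1) / fs,
                       channels = "Cz", montage = NULL),
                  class = "eeg_epochs")
  db <- baseline_db(morlet_ersp(ep, freqs = seq(5, 40, 2.5)))
  grand <- numeric(0)
  for (f_i in seq_along(db$freqs)) {
    v <- db$values[1, f_i, db$valid[f_i, ]]
    # stationarity: no drift between the epoch halves beyond 10%, and the
    # time-mean stays within 20% of the 1-s baseline estimate (whose own
    # sampling noise dominates the per-frequency spread at this epoch count)
    half <- seq_len(length(v) %/% 2)
    expect_lt(abs(mean(v[half]) - mean(v[-half])), 10 * log10(1.1))
    expect_lt(abs(mean(v)), 10 * log10(1.2))
    grand <- c(grand, mean(v))
  }
  # averaged over frequencies the correction is unbiased within 10%
  expect_lt(abs(mean(grand)), 10 * log10(1.1))
})

test_that("band topographies average the right grid cells", {
  # constructed dB object: +3 exactly on the alpha grid, 0 elsewhere
  freqs <- seq(5, 40, 0.2)
  times <- seq(-3, 15, 0.016)
  vals <- array(0, dim = c(2, length(freqs), length(times)))
  vals[, freqs >= 8 & freqs <= 11.8, ] <- 3
  ersp <- structure(list(values = vals, freqs = freqs, times = times,
                         valid = matrix(TRUE, length(freqs), length(times)),
                         channels = c("Cz", "Pz"), montage = NULL,
                         scale = "dB", baseline_window = c(-2, -1)),
                    class = "ersp")
  topo <- band_topography(ersp)
  expect_equal(topo$db[topo$band == "alpha"], c(3, 3))
  expect_equal(topo$db[topo$band != "alpha"], rep(0, 8))

  # all-zero map gives an all-zero topography
  ersp0 <- ersp; ersp0$values[] <- 0
  expect_true(all(band_topography(ersp0)$db == 0))

  # random map agrees with an independent loop-based oracle
  set.seed(7)
  ersp$values[] <- rnorm(length(ersp$values))
  got <- band_topography(ersp, window = c(0, 6))
  bands <- eeg_bands()
  for (b in seq_len(nrow(bands))) {
    fi <- which(freqs >= bands$lo[b] - 1e-9 & freqs <= bands$hi[b] + 1e-9)
    ti <- which(times >= 0 & times <= 6)
    for (ch in 1:2) {
      acc <- 0; n <- 0
      for (f in fi) for (t in ti) { acc <- acc + ersp$values[ch, f, t]; n <- n + 1 }
      expect_equal(got$db[got$band == bands$band[b]][ch], acc / n)
    }
  }

  expect_error(band_topography(ersp, bands = "delta"), "unknown band")
})
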