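test_that("macrostructure of degenerate records matches closed forms", {
  all_n2 <- hypnogram(rep("N2", 960), 0, 960)
  m <- score_macrostructure(all_n2)
  expect_equal(m$tst_min, 480)
  expect_equal(m$sol_min, 0)
  expect_equal(m$waso_min, 0)
  expect_equal(m$se_pct, 100)
  expect_equal(m$n2_pct, 100)

  all_w <- hypnogram(rep("W", 100))
  mw <- score_macrostructure(all_w)
  expect_equal(mw$tst_min, 0)
  expect_equal(mw$se_pct, 0)
  expect_false(mw$sol_defined)
  expect_true(is.na(mw$sol_min))
  expect_false(mw$rem_defined)
})

test_that("macrostructure of a constructed mixed record equals hand counts", {
  # epochs (30 s each):  W W N1 N2 N2 N3 N3 REM REM W N2 N2 REM REM REM W W N2 N2 W
  st <- c("W", "W", "N1", "N2", "N2", "N3", "N3", "REM", "REM", "W",
          "N2", "N2", "REM", "REM", "REM", "W", "W", "N2", "N2", "W")
  h <- hypnogram(st, 0, 20)
  m <- score_macrostructure(h)
  expect_equal(m$tib_min, 10)
  expect_equal(m$sol_min, 1)            # two leading W epochs
  expect_equal(m$tst_min, 7)            # 14 sleep epochs
  expect_equal(m$waso_min, 1.5)         # W at 10, 16, 17 (epoch 20 after last sleep)
  expect_equal(m$n1_min, 0.5)
  expect_equal(m$n2_min, 3)
  expect_equal(m$n3_min, 1)
  expect_equal(m$rem_min, 2.5)
  expect_equal(m$rem_latency_min, 2.5)  # sleep onset epoch 3, first REM epoch 8
  expect_equal(m$n_awakenings, 2)       # W bout at 10, W bout at 16-17
  expect_equal(m$se_pct, 70)
  expect_equal(m$n1_pct + m$n2_pct + m$n3_pct + m$rem_pct, 100)
})

test_that("scoring ignores epochs after lights_on and event relabeling", {
  st <- c("W", "N1", "N2", "REM", "REM", "N2")
  h1 <- hypnogram(st, 0, 6)
  h2 <- hypnogram(c(st, "W", "W", "REM"), 0, 6)
  ev <- tibble::tibble(onset_s = c(100, 130), duration_s = 3,
                       type = c("arousal", "body_movement"))
  expect_equal(score_macrostructure(h1, ev), score_macrostructure(h2, ev))
  # permuting event rows changes nothing
  expect_equal(score_macrostructure(h1, ev[2:1, ]),
               score_macrostructure(h1, ev))
})

test_that("REM fragmentation index matches its closed forms", {
  # 120 REM epochs = 60 min, no events
  h <- hypnogram(c("N2", rep("REM", 120), "N2"), 0, 122)
  expect_equal(rem_fragmentation_index(h)$remfr, 0)

  # 60 REM epochs = 30 min with 10 arousals during REM -> 20 events/h
  h2 <- hypnogram(c("N2", rep("REM", 60), "N2"), 0, 62)
  ev <- tibble::tibble(onset_s = 30 + seq(10, 1700, length.out = 10),
                       duration_s = 3, type = "arousal")
  expect_equal(rem_fragmentation_index(h2, ev)$remfr, 20)

  # no REM -> undefined flag, not an exception
  h3 <- hypnogram(rep("N2", 10))
  out <- rem_fragmentation_index(h3)
  expect_false(out$defined)
  expect_true(is.na(out$remfr))
})

test_that("REM fragmentation index equals a brute-force scan on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    st <- sample(c("W", "N1", "N2", "REM"), 200, replace = TRUE,
                 prob = c(0.1, 0.15, 0.35, 0.4))
    h <- hypnogram(st, 0, 200)
    n_ev <- 15
    ev <- tibble::tibble(
      onset_s = sort(runif(n_ev, 0, 200 * 30)), duration_s = 3,
      type = sample(c("arousal", "body_movement"), n_ev, replace = TRUE)
    )
    got <- rem_fragmentation_index(h, ev)
    want <- oracle_remfr(st, ev)
    if (is.na(want)) expect_false(got$defined) else expect_equal(got$remfr, want)
  }
})

test_that("transition matrices match direct pair counting", {
  # alternating stages
  h <- hypnogram(rep(c("N1", "N2"), 25))
  tm <- transition_matrix(h)
  expect_equal(tm$P["N1", "N2"], 1)
  expect_equal(tm$P["N2", "N1"], 1)

  # constant record: one defined row, others undefined
  hc <- hypnogram(rep("N2", 50))
  tmc <- transition_matrix(hc)
  expect_equal(tmc$P["N2", "N2"], 1)
  expect_setequal(tmc$undefined_rows, c("W", "N1", "N3", "REM"))
  expect_true(all(is.na(tmc$P["W", ])))

  # random record vs oracle, exact equality of counts and row-stochastic P
  h5 <- random_hypnogram(500, seed = 42)
  tm5 <- transition_matrix(h5)
  expect_equal(tm5$counts, oracle_transitions(h5$stages))
  defined <- rowSums(tm5$counts) > 0
  expect_equal(unname(rowSums(tm5$P[defined, ])), rep(1, sum(defined)))

  expect_error(transition_matrix(hypnogram("N2", 0, 1)), "two epochs")
})

test_that("paired matrix comparison handles identity and degenerate cells", {
  mats <- lapply(1:6, function(s) transition_matrix(random_hypnogram(300, s)))
  self <- compare_transition_matrices(mats, mats)
  comp <- self[self$computable, ]
  expect_equal(nrow(comp), 0)  # zero-variance differences are not computable
  expect_true(all(!self$computable))

  # planted difference in one cell is detected, and Bonferroni caps at 1
  A <- lapply(1:10, function(s) transition_matrix(random_hypnogram(400, s)))
  B <- lapply(1:10, function(s) {
    tm <- transition_matrix(random_hypnogram(400, s + 100))
    tm$P["REM", "N1"] <- tm$P["REM", "N1"] + 0.3
    tm$P["REM", "REM"] <- tm$P["REM", "REM"] - 0.3
    tm
  })
  out <- compare_transition_matrices(B, A)
  expect_true(all(out$p_adj[out$computable] <= 1))
  cell <- out[out$from == "REM" & out$to == "N1", ]
  expect_true(cell$computable && cell$p_adj < 0.05 && cell$t > 0)
})

test_that("a planted REM->N1 shift is detected after Bonferroni in most cohorts", {
  # paired design: 17 subjects, FRG-like matrices shift REM->N1 by +0.15
  tr <- default_transitions()
  shifted <- tr$CTR
  shifted["REM", "N1"] <- shifted["REM", "N1"] + 0.15
  shifted["REM", "REM"] <- shifted["REM", "REM"] - 0.15
  n_rep <- 60
  hits <- 0
  for (r in seq_len(n_rep)) {
    cfg_a <- cohort_config(n_subjects = 17, seed = 4000 + r,
                           transition = list(CTR = tr$CTR, FRG = shifted))
    A <- lapply(1:17, function(s)
      transition_matrix(simulate_hypnogram(cfg_a, s, "FRG")$hypnogram))
    B <- lapply(1:17, function(s)
      transition_matrix(simulate_hypnogram(cfg_a, s, "CTR")$hypnogram))
    out <- compare_transition_matrices(A, B)
    cell <- out[out$from == "REM" & out$to == "N1", ]
    if (isTRUE(cell$computable) && cell$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("sleep-parameter comparison reproduces printed-table arithmetic", {
  ref <- reference_sleep_parameters()
  expect_equal(condition_difference(ref, "rem_min"), -22.94)
  expect_equal(condition_difference(ref, "n1_pct"), 4.71)
})
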