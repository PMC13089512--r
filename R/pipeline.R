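# End-to-end orchestration on a synthetic cohort: simulate -> sleep scoring ->
# stimulation-epoch selection -> ERSP -> topographies -> cluster inference ->
# autonomic trial statistics -> recognition memory -> mixed models ->
# topography-behaviour correlation. Every stage consumes and produces plain
# tabular objects so it can also be run in isolation from files.

#' Run the full synthetic-cohort analysis pipeline
#'
#' Deterministic under a fixed `config$seed`: the same configuration yields a
#' byte-identical report. Compute-heavy stages are scaled by the pipeline
#' arguments (number of EEG epochs per subject, channel subset, frequency
#' step, permutation count) without touching the planted study conditions in
#' `config`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, stage outputs are written as
#'   TSV/JSON files with a provenance block.
#' @param n_perm Monte Carlo permutations for cluster tests (default 500).
#' @param n_eeg_epochs EEG epochs simulated per subject (default 12).
#' @param eeg_channels Optional channel subset for the EEG stages.
#' @param freq_step ERSP frequency resolution in Hz (default 0.2).
#' @param run_eeg,run_autonomic,run_memory Stage switches (all TRUE).
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         n_perm = 500, n_eeg_epochs = 12,
                         eeg_channels = NULL, freq_step = 0.2,
                         run_eeg = TRUE, run_autonomic = TRUE,
                         run_memory = TRUE) {
  abort_if(!inherits(config, "cohort_config"), "config must be a cohort_config")
  validate_cohort_config(config)
  subjects <- seq_len(config$n_subjects)
  conditions <- c("CTR", "FRG")

  ## --- sleep stage -----------------------------------------------------
  nights <- tidyr::expand_grid(subject = subjects, condition = conditions)
  nights$record <- purrr::pmap(nights, function(subject, condition) {
    simulate_hypnogram(config, subject, condition)
  })
  macro <- purrr::pmap(nights, function(subject, condition, record) {
    dplyr::mutate(score_macrostructure(record$hypnogram, record$events),
                  subject = subject, condition = condition, .before = 1)
  }) |> dplyr::bind_rows()
  sleep_comparison <- compare_sleep_parameters(macro)

  tm <- function(cond) {
    purrr::map(subjects, function(s) {
      transition_matrix(nights$record[[which(nights$subject == s &
                                               nights$condition == cond)]]$hypnogram)
    })
  }
  tm_ctr <- tm("CTR"); tm_frg <- tm("FRG")
  transition_comparison <- compare_transition_matrices(tm_frg, tm_ctr)

  ## --- stimulation epoch selection ------------------------------------
  selection <- purrr::map(subjects, function(s) {
    rec <- nights$record[[which(nights$subject == s &
                                  nights$condition == "FRG")]]
    sel <- select_stim_epochs(rec$events, rec$hypnogram)
    dplyr::mutate(sel, subject = s, .before = 1)
  }) |> dplyr::bind_rows()
  selection_summary <- selection |>
    dplyr::count(.data$subject, .data$kept, .data$reason)

  ## --- EEG: ERSP, band topographies, cluster tests --------------------
  topographies <- NULL; topo_tests <- NULL; alpha_truth <- NULL
  montage_used <- config$eeg$montage
  if (!is.null(eeg_channels)) {
    montage_used <- montage_used[montage_used$channel %in% eeg_channels, ]
  }
  if (run_eeg) {
    freqs <- seq(5, 40, by = freq_step)
    per_subj <- purrr::map(subjects, function(s) {
      n_kept <- sum(selection$kept[selection$subject == s])
      sim <- simulate_eeg_epochs(config, s, n_epochs = max(4, min(n_kept, n_eeg_epochs)),
                                 channels = montage_used$channel)
      ersp <- morlet_ersp(sim$epochs, freqs = freqs)
      topo <- band_topography(baseline_db(ersp))
      list(topo = dplyr::mutate(topo, subject = s, .before = 1),
           truth = sim$truth)
    })
    topographies <- dplyr::bind_rows(purrr::map(per_subj, "topo"))
    alpha_truth <- dplyr::bind_rows(purrr::map(per_subj, "truth")) |>
      dplyr::filter(.data$band == "alpha") |>
      dplyr::select("subject", planted_alpha_db = "db")
    adj <- channel_adjacency(montage_used)
    topo_tests <- purrr::map(eeg_bands()$band, function(b) {
      m <- as_subject_matrix(
        dplyr::filter(topographies, .data$band == b), value_col = "db")
      m <- m[, adj$channels, drop = FALSE]
      topo_cluster_test(m, adj, n_perm = n_perm,
                        seed = stream_seed(config$seed, 0L, b, stream = 7L))
    }) |> stats::setNames(eeg_bands()$band)
  }

  ## --- autonomic stage -------------------------------------------------
  hrd_table <- NULL; scr_table <- NULL; hrd_model <- NULL; scr_model <- NULL
  screening <- NULL; delta_hrd <- NULL
  if (run_autonomic) {
    set.seed(stream_seed(config$seed, 0L, "coupling-shift", stream = 8L))
    alpha_c <- if (!is.null(alpha_truth)) {
      alpha_truth$planted_alpha_db
    } else rep(config$coupling$alpha_base_db, config$n_subjects)
    shift <- config$coupling$slope * (alpha_c - config$coupling$alpha_base_db) +
      rnorm(config$n_subjects, 0, config$coupling$noise_sd)

    cells <- tidyr::expand_grid(subject = subjects, condition = conditions,
                                session = c("T0", "T1", "T2"))
    trial_stats <- purrr::pmap(cells, function(subject, condition, session) {
      sh <- if (condition == "FRG" && session != "T0") shift[subject] else 0
      trials <- simulate_autonomic_trials(config, subject, condition, session,
                                          hrd_shift = sh)
      purrr::pmap(trials, function(subject, condition, session, trial,
                                   stimulus_type, stimulus_id, planted_hrd,
                                   scr_amp, stim_onset_s, ibi, eda) {
        cor_ibi <- correct_ibi(ibi)
        h <- hrd(cor_ibi$ibi, stim_onset_s)
        eda10 <- preprocess_eda(eda, fs = config$autonomic$fs_eda)
        scr <- cda_scr(eda10, stim_onset_s)
        tibble::tibble(subject = subject, condition = condition,
                       session = session, trial = trial,
                       stimulus_type = stimulus_type,
                       stimulus_id = stimulus_id,
                       hrd_bpm = h$hrd_bpm, cda_scr = scr$cda_scr,
                       responded = scr$responded)
      }) |> dplyr::bind_rows()
    })
    hrd_table <- dplyr::bind_rows(trial_stats)

    screening <- screen_nonresponders(hrd_table)
    scr_keep <- screening$subject[screening$keep]
    scr_table <- dplyr::filter(hrd_table, .data$subject %in% scr_keep)

    hrd_model <- fit_and_contrast(hrd_table, "hrd_bpm")
    scr_model <- if (length(unique(scr_table$subject)) >= 3) {
      fit_and_contrast(scr_table, "cda_scr")
    } else NULL

    delta_hrd <- hrd_table |>
      dplyr::filter(.data$condition == "FRG",
                    .data$session %in% c("T0", "T1")) |>
      dplyr::group_by(.data$subject, .data$session) |>
      dplyr::summarise(m = mean(.data$hrd_bpm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "session", values_from = "m") |>
      dplyr::mutate(delta_hrd = .data$T1 - .data$T0)
  }

  ## --- memory stage -----------------------------------------------------
  memory_table <- NULL; memory_model <- NULL
  if (run_memory) {
    cells <- tidyr::expand_grid(subject = subjects, condition = conditions,
                                session = c("T0", "T1", "T2"))
    responses <- purrr::pmap(cells, function(subject, condition, session) {
      simulate_recognition(config, subject, condition, session)
    }) |> dplyr::bind_rows()
    memory_table <- dprime_table(responses, .data$subject, .data$condition,
                                 .data$session, .data$stimulus_type)
    memory_model <- fit_and_contrast(memory_table, "dprime",
                                     stimulus_random = FALSE)
  }

  ## --- topography-behaviour correlation --------------------------------
  correlation_test <- NULL
  if (run_eeg && run_autonomic && !is.null(delta_hrd) &&
      nrow(delta_hrd) >= 4) {
    adj <- channel_adjacency(montage_used)
    alpha_topo <- as_subject_matrix(
      dplyr::filter(topographies, .data$band == "alpha"), value_col = "db")
    alpha_topo <- alpha_topo[, adj$channels, drop = FALSE]
    beh <- delta_hrd$delta_hrd[match(as.numeric(rownames(alpha_topo)),
                                     delta_hrd$subject)]
    correlation_test <- topo_cluster_correlation(
      alpha_topo, beh, adj, n_perm = n_perm,
      seed = stream_seed(config$seed, 0L, "corr", stream = 9L))
  }

  report <- structure(list(
    provenance = list(seed = config$seed, n_subjects = config$n_subjects,
                      config_hash = rlang::hash(config),
                      package_version = as.character(utils::packageVersion("remfrag"))),
    macro = macro, sleep_comparison = sleep_comparison,
    transition_comparison = transition_comparison,
    selection_summary = selection_summary,
    topographies = topographies,
    topo_tests = if (!is.null(topo_tests)) purrr::map(topo_tests, tidy) else NULL,
    alpha_truth = alpha_truth,
    hrd_table = hrd_table,
    screening = screening,
    hrd_anova = if (!is.null(hrd_model)) hrd_model$anova else NULL,
    hrd_contrasts = if (!is.null(hrd_model)) hrd_model$contrasts else NULL,
    scr_anova = if (!is.null(scr_model)) scr_model$anova else NULL,
    scr_contrasts = if (!is.null(scr_model)) scr_model$contrasts else NULL,
    memory_table = memory_table,
    memory_anova = if (!is.null(memory_model)) memory_model$anova else NULL,
    memory_contrasts = if (!is.null(memory_model)) memory_model$contrasts else NULL,
    delta_hrd = delta_hrd,
    correlation_clusters = if (!is.null(correlation_test)) tidy(correlation_test) else NULL
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$provenance$seed, "|",
      x$provenance$n_subjects, "subjects\n")
  cat("\nSleep parameters (condition comparison):\n")
  print(as.data.frame(x$sleep_comparison), digits = 3)
  sig <- x$transition_comparison |>
    dplyr::filter(.data$computable, .data$p_adj < 0.05)
  cat("\nSignificant transition-probability differences (FRG - CTR):\n")
  print(as.data.frame(sig), digits = 3)
  if (!is.null(x$correlation_clusters) && nrow(x$correlation_clusters)) {
    cat("\nAlpha-topography / delta-HRD correlation clusters:\n")
    print(as.data.frame(
      x$correlation_clusters[, setdiff(names(x$correlation_clusters), "members")]),
      digits = 3)
  }
  invisible(x)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(obj, name) {
    if (!is.null(obj) && is.data.frame(obj)) {
      drop <- vapply(obj, is.list, logical(1))
      readr::write_tsv(obj[, !drop, drop = FALSE],
                       file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  wt(report$macro, "macrostructure")
  wt(report$sleep_comparison, "sleep_comparison")
  wt(report$transition_comparison, "transition_comparison")
  wt(report$selection_summary, "epoch_selection")
  wt(report$topographies, "band_topographies")
  wt(report$hrd_table, "autonomic_trials")
  wt(report$screening, "eda_screening")
  wt(report$hrd_contrasts, "hrd_contrasts")
  wt(report$memory_table, "dprime")
  wt(report$delta_hrd, "delta_hrd")
  jsonlite::write_json(
    list(provenance = report$provenance,
         topo_tests = purrr::map(report$topo_tests, function(t) {
           if (is.null(t)) NULL else t[, setdiff(names(t), "members")]
         }),
         correlation_clusters = if (is.null(report$correlation_clusters)) NULL else
           report$correlation_clusters[, setdiff(names(report$correlation_clusters),
                                                 "members")]),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
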