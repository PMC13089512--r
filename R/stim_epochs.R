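# Selection of stimulation-locked EEG epochs under the four exclusion rules,
# and extraction of fixed windows from a continuous recording.

# Accept either one row per stimulation (type == "stimulation") or paired
# stim_on / stim_off rows; the latter are collapsed into single stimulations.
normalize_stim_events <- function(events) {
  if (!"type" %in% names(events)) rlang::abort("events need a type column")
  if (any(events$type %in% c("stim_on", "stim_off"))) {
    on <- events[events$type == "stim_on", ]
    off <- events[events$type == "stim_off", ]
    abort_if(nrow(on) != nrow(off), "unmatched stim_on/stim_off pairs")
    on <- on[order(on$onset_s), ]
    off <- off[order(off$onset_s), ]
    abort_if(any(off$onset_s < on$onset_s),
             "unmatched stim_on/stim_off pairs")
    stim <- on
    stim$type <- "stimulation"
    stim$duration_s <- off$onset_s - on$onset_s
    events <- dplyr::bind_rows(stim,
                               events[!events$type %in% c("stim_on", "stim_off"), ])
  }
  dplyr::arrange(events, .data$onset_s)
}

#' Select stimulation-locked epochs
#'
#' Applies the four exclusion rules, in order: (1) drop stimulations whose
#' onset falls outside REM sleep; (2) keep only the final stimulation of each
#' train; (3) drop epochs overlapping an artifact interval; (4) drop epochs in
#' which the stimulation was followed by a full awakening (any wake epoch
#' intersecting the post-stimulus window). Reasons are mutually exclusive with
#' this precedence. Trains are taken from a `train_id` column when present,
#' otherwise derived by the gap rule: an onset more than `train_gap_s` after
#' the previous onset starts a new train.
#'
#' @param events Event tibble (one row per stimulation, or paired
#'   `stim_on`/`stim_off` rows).
#' @param h The night's [hypnogram()].
#' @param artifacts Optional tibble of artifact intervals (`onset_s`, `duration_s`).
#' @param window Epoch window around stimulation onset in seconds
#'   (default `c(-3, 15)`).
#' @param train_gap_s Gap (onset-to-onset, s) beyond which a new train starts
#'   (default 40, the protocol's suspension time).
#' @return A tibble with one row per candidate stimulation: `stim_id`,
#'   `onset_s`, `train_id`, `kept`, `reason`
#'   (`outside_REM`, `not_final_in_train`, `artifact`, `full_awakening`, or
#'   `NA` when kept).
#' @export
select_stim_epochs <- function(events, h, artifacts = NULL,
                               window = c(-3, 15), train_gap_s = 40) {
  events <- normalize_stim_events(events)
  stim <- events[events$type == "stimulation", ]
  if (nrow(stim) == 0) {
    return(tibble::tibble(stim_id = integer(), onset_s = numeric(),
                          train_id = integer(), kept = logical(),
                          reason = character()))
  }
  stim <- dplyr::arrange(stim, .data$onset_s)
  stim$stim_id <- seq_len(nrow(stim))

  if (!"train_id" %in% names(stim) || any(is.na(stim$train_id))) {
    gaps <- c(Inf, diff(stim$onset_s))
    stim$train_id <- cumsum(gaps > train_gap_s)
  }

  ep_s <- h$epoch_len
  stage_at <- function(t) {
    idx <- floor(t / ep_s) + 1L
    ifelse(idx >= 1 & idx <= length(h$stages), h$stages[pmin(pmax(idx, 1L),
                                                             length(h$stages))],
           NA_character_)
  }
  reason <- rep(NA_character_, nrow(stim))

  # (1) outside REM
  outside <- stage_at(stim$onset_s) != "REM"
  outside[is.na(outside)] <- TRUE
  reason[outside] <- "outside_REM"

  # (2) final stimulation per train, among those still in REM
  keep_final <- rep(FALSE, nrow(stim))
  for (tr in unique(stim$train_id[!outside])) {
    i <- which(stim$train_id == tr & !outside)
    keep_final[i[which.max(stim$onset_s[i])]] <- TRUE
  }
  drop2 <- !outside & !keep_final
  reason[drop2] <- "not_final_in_train"

  # (3) artifact overlap with the epoch window
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    art <- is.na(reason) & vapply(stim$onset_s, function(t) {
      any(artifacts$onset_s < t + window[2] &
            artifacts$onset_s + artifacts$duration_s > t + window[1])
    }, logical(1))
    reason[art] <- "artifact"
  }

  # (4) full awakening: any W epoch intersecting the post-stimulus window
  awake <- is.na(reason) & vapply(stim$onset_s, function(t) {
    ep0 <- floor(t / ep_s) + 1L
    ep1 <- floor((t + window[2]) / ep_s) + 1L
    idx <- ep0:min(ep1, length(h$stages))
    any(h$stages[idx] == "W")
  }, logical(1))
  reason[awake] <- "full_awakening"

  tibble::tibble(stim_id = stim$stim_id, onset_s = stim$onset_s,
                 train_id = stim$train_id, kept = is.na(reason),
                 reason = reason)
}

#' Extract fixed-window epochs from a continuous recording
#'
#' Cuts `window` (seconds around each onset, inclusive of both endpoints on
#' the sample grid) out of a continuous multichannel recording. Onsets whose
#' window falls outside the recording are dropped with a reason rather than
#' silently truncated.
#'
#' @param rec An [eeg_recording()].
#' @param onsets Numeric vector of stimulation onsets (s, recording clock).
#' @param window Epoch window (s) relative to onset, default `c(-3, 15)`.
#' @return A list: `epochs` (class `eeg_epochs`; array time x channel x epoch),
#'   `log` (tibble `onset_s`, `kept`, `reason`).
#' @export
extract_epochs <- function(rec, onsets, window = c(-3, 15)) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  fs <- rec$fs
  n <- nrow(rec$data)
  n_t <- round(diff(window) * fs) + 1L
  rel <- round(window[1] * fs)

  log <- tibble::tibble(onset_s = onsets, kept = NA, reason = NA_character_)
  keep_idx <- list()
  for (i in seq_along(onsets)) {
    s0 <- round((onsets[i] - rec$start_s) * fs) + 1L + rel
    s1 <- s0 + n_t - 1L
    if (s0 < 1 || s1 > n) {
      log$kept[i] <- FALSE
      log$reason[i] <- if (s0 < 1) "window_underflow" else "window_overflow"
    } else {
      log$kept[i] <- TRUE
      keep_idx[[length(keep_idx) + 1L]] <- s0:s1
    }
  }
  kept <- which(log$kept)
  dat <- array(0, dim = c(n_t, ncol(rec$data), length(kept)))
  for (j in seq_along(kept)) dat[, , j] <- rec$data[keep_idx[[j]], ]
  times <- window[1] + (seq_len(n_t) - 1L) / fs
  epochs <- structure(list(data = dat, fs = fs, times = times,
                           channels = rec$channels, montage = NULL),
                      class = "eeg_epochs")
  list(epochs = epochs, log = log)
}
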