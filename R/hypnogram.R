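#' Hypnogram container
#'
#' An ordered sequence of 30-s epoch sleep-stage labels with lights-off /
#' lights-on boundary markers. Markers follow the boundary convention:
#' `lights_off` epochs precede the in-bed period, and `lights_on` is the epoch
#' count at the final lights-on, so the in-bed window covers epochs
#' `lights_off + 1 .. lights_on` and time in bed is
#' `(lights_on - lights_off) * epoch_len`.
#'
#' @param stages Character vector of labels from `W, N1, N2, N3, REM`.
#' @param lights_off,lights_on Boundary epoch counts,
#'   `0 <= lights_off < lights_on <= length(stages)`.
#' @param epoch_len Epoch length in seconds (default 30).
#' @return An object of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N2", "REM", "REM", "W"))
#' score_macrostructure(h)
hypnogram <- function(stages, lights_off = 0L, lights_on = length(stages),
                      epoch_len = 30) {
  stages <- as.character(stages)
  abort_if(length(stages) < 1, "hypnogram must contain at least one epoch")
  st <- match_stage(stages)
  abort_if(!(lights_off >= 0 && lights_off < lights_on &&
               lights_on <= length(stages)),
           "need 0 <= lights_off < lights_on <= number of epochs")
  structure(list(stages = as.character(st), lights_off = as.integer(lights_off),
                 lights_on = as.integer(lights_on), epoch_len = epoch_len),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %g s, in bed %d..%d\n",
              length(x$stages), x$epoch_len, x$lights_off + 1L, x$lights_on))
  invisible(x)
}

#' @export
#' @rdname hypnogram
#' @param x A `hypnogram`.
#' @param ... Unused.
tidy.hypnogram <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$stages),
    stage = x$stages,
    onset_s = (seq_along(x$stages) - 1) * x$epoch_len,
    in_bed = seq_along(x$stages) > x$lights_off &
      seq_along(x$stages) <= x$lights_on
  )
}

#' Write / read a hypnogram as TSV
#'
#' Columns `epoch_index`, `stage`; boundary markers stored in a comment-free
#' side-band via two pseudo-rows is avoided — markers travel in a second file
#' or are passed explicitly to `read_hypnogram()`.
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @param lights_off,lights_on Markers for `read_hypnogram` (defaults: whole
#'   record in bed).
#' @param epoch_len Epoch length in seconds.
#' @export
write_hypnogram <- function(h, path) {
  readr::write_tsv(tibble::tibble(epoch_index = seq_along(h$stages),
                                  stage = h$stages), path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, lights_off = 0L, lights_on = NULL,
                           epoch_len = 30) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  abort_if(!all(c("epoch_index", "stage") %in% names(d)),
           "hypnogram file must have columns epoch_index, stage")
  d <- d[order(d$epoch_index), ]
  hypnogram(d$stage, lights_off, lights_on %||% nrow(d), epoch_len)
}

in_bed_stages <- function(h) h$stages[(h$lights_off + 1L):h$lights_on]

#' Score sleep macrostructure
#'
#' Computes the standard polysomnographic summary from a staged hypnogram:
#' total sleep time (TST), sleep-onset latency (SOL, to the first N1 or N2
#' epoch), wake after sleep onset (WASO, wake minutes between sleep onset and
#' the final awakening), sleep efficiency (SE = TST / time-in-bed x 100),
#' per-stage minutes and percentages of TST, REM latency from sleep onset,
#' number of awakenings (wake bouts of at least one epoch after sleep onset
#' and before the final awakening), and the REM fragmentation index from
#' [rem_fragmentation_index()].
#'
#' @param h A [hypnogram()].
#' @param events Optional event log tibble (see [simulate_hypnogram()]); used
#'   for the REM fragmentation index.
#' @return A one-row tibble. Undefined quantities (no sleep, no REM) are `NA`
#'   with companion logical flags `sol_defined`, `rem_defined`.
#' @export
score_macrostructure <- function(h, events = NULL) {
  abort_if(!inherits(h, "hypnogram"), "h must be a hypnogram")
  st <- in_bed_stages(h)
  ep_min <- h$epoch_len / 60
  tib <- length(st) * ep_min
  sleep <- st != "W"

  onset_pos <- which(st %in% c("N1", "N2"))[1]
  last_sleep <- if (any(sleep)) max(which(sleep)) else NA_integer_

  tst <- sum(sleep) * ep_min
  sol <- if (!is.na(onset_pos)) (onset_pos - 1) * ep_min else NA_real_
  waso <- if (!is.na(onset_pos) && !is.na(last_sleep)) {
    sum(st[onset_pos:last_sleep] == "W") * ep_min
  } else NA_real_
  se <- tst / tib * 100

  stage_min <- vapply(c("N1", "N2", "N3", "REM"),
                      function(s) sum(st == s) * ep_min, numeric(1))
  stage_pct <- if (tst > 0) stage_min / tst * 100 else rep(NA_real_, 4)

  first_rem <- which(st == "REM")[1]
  rem_lat <- if (!is.na(onset_pos) && !is.na(first_rem) && first_rem >= onset_pos) {
    (first_rem - onset_pos) * ep_min
  } else NA_real_

  n_awak <- 0L
  if (!is.na(onset_pos) && !is.na(last_sleep) && last_sleep > onset_pos) {
    r <- rle(st[onset_pos:last_sleep] == "W")
    n_awak <- sum(r$values)
  }

  fr <- rem_fragmentation_index(h, events)

  tibble::tibble(
    tib_min = tib, tst_min = tst, sol_min = sol, waso_min = waso, se_pct = se,
    n1_min = stage_min[["N1"]], n2_min = stage_min[["N2"]],
    n3_min = stage_min[["N3"]], rem_min = stage_min[["REM"]],
    n1_pct = stage_pct[[1]], n2_pct = stage_pct[[2]],
    n3_pct = stage_pct[[3]], rem_pct = stage_pct[[4]],
    rem_latency_min = rem_lat, n_awakenings = n_awak,
    remfr = fr$remfr, sol_defined = !is.na(onset_pos),
    rem_defined = fr$defined
  )
}

#' REM sleep fragmentation index
#'
#' Interrupting events per hour of REM sleep. The numerator counts cortical
#' arousals occurring during REM epochs, body movements during REM epochs, and
#' interrupting bouts: maximal runs of non-REM or wake epochs with REM epochs
#' on both sides within the in-bed window. An arousal logged within the final
#' REM epoch immediately preceding an interrupting bout and the bout itself
#' are counted once (the arousal takes precedence). The denominator is total
#' REM duration in hours.
#'
#' @param h A [hypnogram()].
#' @param events Optional event tibble with columns `onset_s`, `type`
#'   (`arousal`, `body_movement` counted).
#' @return A one-row tibble: `remfr` (events/h, `NA` when no REM), `n_events`,
#'   `rem_hours`, `defined`.
#' @export
rem_fragmentation_index <- function(h, events = NULL) {
  st <- in_bed_stages(h)
  ep_s <- h$epoch_len
  rem <- st == "REM"
  rem_hours <- sum(rem) * ep_s / 3600
  if (rem_hours == 0) {
    return(tibble::tibble(remfr = NA_real_, n_events = NA_integer_,
                          rem_hours = 0, defined = FALSE))
  }

  # interrupting bouts: non-REM runs flanked by REM
  r <- rle(rem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_bout <- !r$values & seq_along(r$values) > 1L &
    seq_along(r$values) < length(r$values)
  bout_starts <- starts[is_bout]

  n_arousal <- 0L; n_move <- 0L; arousal_epochs <- integer(0)
  if (!is.null(events) && nrow(events) > 0) {
    # epoch index on the in-bed clock (onset_s counted from recording start)
    ev_epoch <- floor(events$onset_s / ep_s) + 1L - h$lights_off
    in_rem <- ev_epoch >= 1 & ev_epoch <= length(st)
    in_rem[in_rem] <- rem[ev_epoch[in_rem]]
    n_arousal_all <- events$type == "arousal" & in_rem
    n_move <- sum(events$type == "body_movement" & in_rem)
    arousal_epochs <- ev_epoch[n_arousal_all]
    n_arousal <- sum(n_arousal_all)
  }

  # precedence: a bout immediately preceded by a counted arousal epoch merges
  preceded <- bout_starts - 1L
  n_bouts <- sum(!(preceded %in% arousal_epochs))

  n_ev <- n_arousal + n_move + n_bouts
  tibble::tibble(remfr = n_ev / rem_hours, n_events = as.integer(n_ev),
                 rem_hours = rem_hours, defined = TRUE)
}

#' Markov stage-transition matrix
#'
#' Counts all consecutive epoch pairs within the in-bed window and normalizes
#' each row to conditional probabilities `P[i, j] = P(stage j | previous
#' stage i)`. Rows for stages never visited (as origin) are undefined (`NA`).
#'
#' @param h A [hypnogram()] with at least two in-bed epochs.
#' @return An object of class `transition_matrix`: list with `P` (5x5
#'   probabilities), `counts` (5x5 integer), `undefined_rows` (stage labels).
#' @export
transition_matrix <- function(h) {
  st <- in_bed_stages(h)
  abort_if(length(st) < 2, "need at least two epochs for transitions")
  from <- factor(st[-length(st)], levels = SLEEP_STAGES)
  to <- factor(st[-1], levels = SLEEP_STAGES)
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  n_row <- rowSums(counts)
  P <- counts / ifelse(n_row > 0, n_row, NA_real_)
  structure(list(P = P, counts = counts,
                 undefined_rows = SLEEP_STAGES[n_row == 0]),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>\n")
  print(round(x$P, 3))
  invisible(x)
}

#' @export
#' @rdname transition_matrix
#' @param x A `transition_matrix`.
#' @param ... Unused.
tidy.transition_matrix <- function(x, ...) {
  tibble::tibble(
    from = rep(SLEEP_STAGES, times = 5),
    to = rep(SLEEP_STAGES, each = 5),
    p = as.vector(x$P),
    count = as.vector(x$counts)
  )
}

#' Paired comparison of per-subject transition matrices
#'
#' For each of the 25 stage-transition cells, performs a paired t-test across
#' subjects between conditions A and B (A minus B). Subjects with an undefined
#' cell (origin stage never visited) are excluded pairwise; cells with fewer
#' than two complete pairs or zero-variance differences are flagged
#' not-computable (mirroring `NaN` cells in sparse designs). P-values are
#' Bonferroni-corrected by the number of computable cells, capped at 1.
#'
#' @param A,B Lists of [transition_matrix()] objects, same subjects, same order.
#' @return A tibble with one row per cell: `from`, `to`, `n_pairs`,
#'   `mean_diff`, `t`, `df`, `p`, `p_adj`, `computable`.
#' @export
compare_transition_matrices <- function(A, B) {
  abort_if(length(A) != length(B), "A and B must have the same subjects")
  abort_if(length(A) < 2, "need at least two subjects")
  cells <- tidyr::expand_grid(from = SLEEP_STAGES, to = SLEEP_STAGES)
  res <- purrr::pmap(cells, function(from, to) {
    d <- vapply(seq_along(A), function(i) {
      A[[i]]$P[from, to] - B[[i]]$P[from, to]
    }, numeric(1))
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2 || sd(d) < 1e-12) {
      return(tibble::tibble(from = from, to = to, n_pairs = n,
                            mean_diff = if (n > 0) mean(d) else NA_real_,
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            p_adj = NA_real_, computable = FALSE))
    }
    tval <- mean(d) / (sd(d) / sqrt(n))
    tibble::tibble(from = from, to = to, n_pairs = n, mean_diff = mean(d),
                   t = tval, df = n - 1,
                   p = 2 * pt(-abs(tval), n - 1), p_adj = NA_real_,
                   computable = TRUE)
  })
  out <- dplyr::bind_rows(res)
  m <- sum(out$computable)
  out$p_adj <- ifelse(out$computable, pmin(1, out$p * m), NA_real_)
  out
}

#' Paired condition comparison of sleep parameters
#'
#' Mean +/- SD per condition plus a paired t-test per parameter (FRG minus
#' CTR order by default), without multiple-comparison correction: the intent
#' is an equivalence-style check of macrostructure.
#'
#' @param macro Tibble of per-record macrostructure rows (from
#'   [score_macrostructure()]) with `subject` and `condition` columns.
#' @param conditions Length-2 character: comparison is
#'   `conditions[1] - conditions[2]`.
#' @param vars Parameter columns to compare (default: the numeric summary set).
#' @return Tibble: `variable`, means/SDs per condition, `mean_diff`, `t`,
#'   `df`, `p`.
#' @export
compare_sleep_parameters <- function(macro, conditions = c("FRG", "CTR"),
                                     vars = NULL) {
  vars <- vars %||% intersect(
    c("tst_min", "sol_min", "waso_min", "se_pct", "n1_min", "n2_min", "n3_min",
      "rem_min", "n1_pct", "n2_pct", "n3_pct", "rem_pct", "rem_latency_min",
      "n_awakenings", "remfr"), names(macro))
  purrr::map(vars, function(v) {
    wide <- macro |>
      dplyr::select(dplyr::all_of(c("subject", "condition", v))) |>
      tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(v))
    a <- wide[[conditions[1]]]; b <- wide[[conditions[2]]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    d <- a - b
    n <- length(d)
    tv <- if (n >= 2 && sd(d) > 1e-12) mean(d) / (sd(d) / sqrt(n)) else NA_real_
    tibble::tibble(
      variable = v,
      mean_1 = mean(a), sd_1 = sd(a), mean_2 = mean(b), sd_2 = sd(b),
      mean_diff = mean(d), t = tv, df = n - 1,
      p = if (is.na(tv)) NA_real_ else 2 * pt(-abs(tv), n - 1)
    ) |>
      stats::setNames(c("variable",
                        paste0(c("mean_", "sd_"), conditions[1]),
                        paste0(c("mean_", "sd_"), conditions[2]),
                        "mean_diff", "t", "df", "p"))
  }) |>
    dplyr::bind_rows()
}
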