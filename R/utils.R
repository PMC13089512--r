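#' @importFrom rlang %||% .data
#' @importFrom stats qt qnorm pt sd var median quantile approx spline fft
#'   mvfft rnorm runif rbinom complete.cases anova setNames coef cor
#' @importFrom utils head tail
NULL

# Canonical five-state sleep-stage alphabet (AASM labels), fixed order.
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

# Frequency bands (Hz, inclusive bounds on the 0.2-Hz analysis grid).
#' Frequency band table
#'
#' The five analysis bands used throughout the package: theta (5-7.8 Hz),
#' alpha (8-11.8 Hz), sigma (12-15.8 Hz), beta (16-29.8 Hz) and low-gamma
#' (30-40 Hz). Bounds are inclusive on the 0.2-Hz frequency grid and the bands
#' partition 5-40 Hz without overlap.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "sigma", "beta", "low_gamma"),
    lo   = c(5, 8, 12, 16, 30),
    hi   = c(7.8, 11.8, 15.8, 29.8, 40)
  )
}

#' Derive a reproducible sub-stream seed
#'
#' All generators are pure functions of `(seed, subject, condition, session,
#' stream)`: one global seed plus fixed offsets, so any subject or session can
#' be regenerated in isolation.
#'
#' @param seed Global integer seed.
#' @param subject Subject index (integer, >= 1) or 0 for cohort-level streams.
#' @param condition,session Optional labels folded into the stream key.
#' @param stream Integer offset distinguishing generators sharing the other keys.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
stream_seed <- function(seed, subject = 0L, condition = "", session = "", stream = 0L) {
  key <- paste(condition, session, sep = "|")
  h <- sum(utf8ToInt(key) * seq_len(nchar(key) + 1L)[seq_along(utf8ToInt(key))])
  if (length(h) == 0L) h <- 0
  as.integer((as.numeric(seed) * 7 + as.numeric(subject) * 10007 +
                h * 131 + as.numeric(stream) * 523) %% 2147483629)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) rlang::abort(msg)

match_stage <- function(stages) {
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  abort_if(length(bad) > 0,
           paste0("unknown sleep stage label(s): ", paste(bad, collapse = ", ")))
  factor(stages, levels = SLEEP_STAGES)
}
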