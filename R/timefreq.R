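# Morlet-wavelet event-related spectral perturbation (ERSP).
#
# Convolution is done in the frequency domain with zero padding to a power of
# two; the wavelet is an analytic Morlet whose cycle count grows linearly from
# `cycles[1]` at the lowest to `cycles[2]` at the highest analysis frequency,
# trading temporal precision for the frequency precision needed to separate
# adjacent bands. Time points whose wavelet support (3 temporal SDs) extends
# beyond the epoch are marked invalid and excluded from baseline and
# statistics instead of being zero-padded into the estimates.

#' Morlet-wavelet ERSP of stimulation-locked epochs
#'
#' Computes per-epoch spectral power by complex Morlet convolution and averages
#' power across epochs per channel, returning linear power (baseline-correct
#' with [baseline_db()]).
#'
#' @param epochs An `eeg_epochs` object (array time x channel x epoch).
#' @param freqs Analysis frequencies in Hz (default 5 to 40 Hz in 0.2-Hz steps).
#' @param time_step Output time resolution in seconds (default 0.016); rounded
#'   to the nearest whole number of samples.
#' @param cycles Length-2: wavelet cycles at the anchor frequencies
#'   (default `c(7, 42)`), interpolated linearly in frequency.
#' @param cycle_anchor Frequencies (Hz) at which `cycles` applies (default
#'   `c(5, 40)`), so a sub-grid analysis keeps the same cycle ramp as the
#'   full 5-40-Hz analysis.
#' @return An object of class `ersp`: `values` (channel x frequency x time,
#'   linear power), `freqs`, `times` (s), `valid` (frequency x time logical),
#'   `channels`, `montage`, `scale = "power"`.
#' @export
morlet_ersp <- function(epochs, freqs = seq(5, 40, by = 0.2),
                        time_step = 0.016, cycles = c(7, 42),
                        cycle_anchor = c(5, 40)) {
  abort_if(!inherits(epochs, "eeg_epochs"), "epochs must be an eeg_epochs object")
  fs <- epochs$fs
  abort_if(max(freqs) >= fs / 2,
           sprintf("sampling rate %g Hz too low for %g Hz analysis (Nyquist)",
                   fs, max(freqs)))
  abort_if(any(diff(freqs) <= 0), "freqs must be strictly increasing")
  dims <- dim(epochs$data)
  n_t <- dims[1]; n_ch <- dims[2]; n_ep <- dims[3]
  abort_if(n_ep < 1, "need at least one epoch")

  n_cyc <- cycles[1] + (freqs - cycle_anchor[1]) *
    (cycles[2] - cycles[1]) / (cycle_anchor[2] - cycle_anchor[1])
  sigma_t <- n_cyc / (2 * pi * freqs)

  step <- max(1L, round(time_step * fs))
  keep <- seq(1L, n_t, by = step)
  times_out <- epochs$times[keep]

  nfft <- 2^ceiling(log2(n_t + 2 * max(ceiling(3 * sigma_t * fs))))
  f_grid <- ((seq_len(nfft) - 1 + nfft / 2) %% nfft - nfft / 2) * fs / nfft
  # frequency-domain analytic Morlet, unit peak (scale cancels in dB ratios)
  W <- vapply(seq_along(freqs), function(i) {
    exp(-0.5 * (2 * pi * (f_grid - freqs[i]) * sigma_t[i])^2)
  }, numeric(nfft))

  vals <- array(NA_real_, dim = c(n_ch, length(freqs), length(keep)))
  pad <- matrix(0, nfft - n_t, n_ep)
  for (c_i in seq_len(n_ch)) {
    ch_dat <- matrix(epochs$data[, c_i, ], nrow = n_t, ncol = n_ep)
    X <- mvfft(rbind(ch_dat, pad))
    for (f_i in seq_along(freqs)) {
      Y <- mvfft(X * W[, f_i], inverse = TRUE) / nfft
      p <- rowMeans(Mod(Y)^2)
      vals[c_i, f_i, ] <- p[keep]
    }
  }

  half_sup <- 3 * sigma_t
  valid <- outer(half_sup, times_out,
                 function(h, t) t >= min(epochs$times) + h &
                   t <= max(epochs$times) - h)

  structure(list(values = vals, freqs = freqs, times = times_out,
                 valid = valid, channels = epochs$channels,
                 montage = epochs$montage, scale = "power",
                 baseline_window = NULL),
            class = "ersp")
}

#' @export
print.ersp <- function(x, ...) {
  cat(sprintf("<ersp:%s> %d channels x %d freqs (%g..%g Hz) x %d times (%g..%g s)\n",
              x$scale, dim(x$values)[1], length(x$freqs), min(x$freqs),
              max(x$freqs), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
#' @rdname morlet_ersp
#' @param x An `ersp` object.
#' @param ... Unused.
tidy.ersp <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    channel = rep(x$channels, times = d[2] * d[3]),
    freq = rep(rep(x$freqs, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$values),
    valid = rep(as.vector(x$valid), each = d[1])
  )
}

#' Baseline-correct an ERSP to decibels
#'
#' Divides the epoch-averaged power at every time-frequency point by the mean
#' power of the same frequency within the pre-stimulus baseline window and
#' converts to dB: `10 * log10(power / baseline)`.
#'
#' @param ersp An `ersp` in linear power scale.
#' @param baseline Baseline window in seconds, default `c(-2, -1)`.
#' @return An `ersp` with `scale = "dB"`; channel-frequency combinations with
#'   zero baseline power become `NA` and are recorded in `attr(, "flagged")`.
#' @export
baseline_db <- function(ersp, baseline = c(-2, -1)) {
  abort_if(!inherits(ersp, "ersp"), "ersp object required")
  abort_if(ersp$scale != "power", "baseline_db expects linear power input")
  in_base <- ersp$times >= baseline[1] & ersp$times <= baseline[2]
  abort_if(!any(in_base), "baseline window outside the time grid")

  out <- ersp
  flagged <- matrix(FALSE, dim(ersp$values)[1], dim(ersp$values)[2])
  for (f_i in seq_along(ersp$freqs)) {
    use <- in_base & ersp$valid[f_i, ]
    base <- if (any(use)) {
      rowMeans(ersp$values[, f_i, use, drop = FALSE], na.rm = TRUE)
    } else rep(NA_real_, dim(ersp$values)[1])
    bad <- !is.finite(base) | base <= 0
    flagged[, f_i] <- bad
    base[bad] <- NA_real_
    out$values[, f_i, ] <- 10 * log10(sweep(
      ersp$values[, f_i, , drop = FALSE], 1, base, "/"))[, 1, ]
  }
  out$scale <- "dB"
  out$baseline_window <- baseline
  attr(out, "flagged") <- flagged
  out
}

#' Band-averaged scalp topography of a dB ERSP
#'
#' Means the dB values over all frequency bins inside each band (inclusive
#' bounds on the frequency grid) and all valid time bins inside the analysis
#' window, per channel.
#'
#' @param ersp_db An `ersp` in dB scale.
#' @param bands Band table as from [eeg_bands()] or a character vector of band
#'   names from that palette.
#' @param window Time window in seconds, default `c(0, 6)`.
#' @return A tibble: `channel`, `band`, `db`.
#' @export
band_topography <- function(ersp_db, bands = eeg_bands(), window = c(0, 6)) {
  abort_if(!inherits(ersp_db, "ersp"), "ersp object required")
  abort_if(ersp_db$scale != "dB", "band_topography expects a dB ERSP")
  if (is.character(bands)) {
    pal <- eeg_bands()
    abort_if(!all(bands %in% pal$band),
             paste0("unknown band(s): ",
                    paste(setdiff(bands, pal$band), collapse = ", ")))
    bands <- pal[pal$band %in% bands, ]
  }
  tol <- 1e-9
  out <- purrr::pmap(bands, function(band, lo, hi) {
    f_idx <- which(ersp_db$freqs >= lo - tol & ersp_db$freqs <= hi + tol)
    abort_if(length(f_idx) == 0,
             paste0("band ", band, " has no bins on the frequency grid"))
    vals <- vapply(seq_along(ersp_db$channels), function(c_i) {
      acc <- 0; n_acc <- 0
      for (f_i in f_idx) {
        t_idx <- ersp_db$times >= window[1] & ersp_db$times <= window[2] &
          ersp_db$valid[f_i, ]
        v <- ersp_db$values[c_i, f_i, t_idx]
        v <- v[is.finite(v)]
        acc <- acc + sum(v); n_acc <- n_acc + length(v)
      }
      abort_if(n_acc == 0, paste0("band ", band,
                                  ": no valid time-frequency bins in window"))
      acc / n_acc
    }, numeric(1))
    tibble::tibble(channel = ersp_db$channels, band = band, db = vals)
  })
  dplyr::bind_rows(out)
}
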