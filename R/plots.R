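# ggplot2 visualisations of the main result types.

#' Plot a time-frequency ERSP map
#'
#' @param object An `ersp` object (dB scale recommended).
#' @param channel Channel to plot (default: first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ersp <- function(object, channel = object$channels[1], ...) {
  c_i <- match(channel, object$channels)
  abort_if(is.na(c_i), paste0("unknown channel: ", channel))
  d <- tibble::tibble(
    time = rep(object$times, each = length(object$freqs)),
    freq = rep(object$freqs, times = length(object$times)),
    value = as.vector(object$values[c_i, , ]),
    valid = as.vector(object$valid)
  )
  d <- d[d$valid & is.finite(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = object$scale) +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  title = paste("ERSP -", channel)) +
    ggplot2::theme_minimal()
}

#' Plot a scalp topography with significant cluster channels highlighted
#'
#' @param object A `cluster_result` of type `topography` or `correlation`.
#' @param montage Montage tibble supplying 2-D positions (`px`, `py`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, montage = montage_1020(), ...) {
  abort_if(object$type == "time_frequency",
           "use plot_tf_clusters() for time-frequency results")
  stat <- object$statistic
  value_col <- if ("r" %in% names(stat)) "r" else "t"
  d <- dplyr::left_join(stat, montage[, c("channel", "px", "py")],
                        by = "channel")
  sig_ch <- unlist(object$clusters$members[object$clusters$significant])
  d$in_cluster <- d$channel %in% sig_ch
  ggplot2::ggplot(d, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data[[value_col]],
                                     shape = .data$in_cluster), size = 6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 23),
                                name = "in significant cluster") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = value_col) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2,
                       vjust = -1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a stage-transition probability matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  d <- tidy(object)
  d$from <- factor(d$from, levels = rev(SLEEP_STAGES))
  d$to <- factor(d$to, levels = SLEEP_STAGES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$p), "NA", sprintf("%.2f", .data$p))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 na.value = "grey90", name = "P") +
    ggplot2::labs(x = "To stage", y = "From stage") +
    ggplot2::theme_minimal()
}

#' Plot heart-rate-deceleration trajectories by condition and session
#'
#' Cell means with standard-error bars, the visual analogue of the
#' habituation pattern (control decreasing after sleep, fragmentation flat).
#'
#' @param hrd_table Tibble with `subject`, `condition`, `session`, `hrd_bpm`.
#' @return A ggplot.
#' @export
plot_hrd_trajectories <- function(hrd_table) {
  d <- hrd_table |>
    dplyr::group_by(.data$condition, .data$session) |>
    dplyr::summarise(m = mean(.data$hrd_bpm),
                     se = sd(.data$hrd_bpm) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$session, y = .data$m,
                                  colour = .data$condition,
                                  group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$se,
                                          ymax = .data$m + .data$se)) +
    ggplot2::labs(x = "Session", y = "HRD (bpm)", colour = "Condition") +
    ggplot2::theme_minimal()
}
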