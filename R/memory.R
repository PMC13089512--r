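# Recognition-memory sensitivity from the equal-variance signal-detection
# model, with boundary corrections keeping d-prime finite.

#' Tabulate recognition responses
#'
#' Counts hits, misses, false alarms and correct rejections from a long
#' response table, within the requested grouping.
#'
#' @param responses Tibble with columns `truth` (`"OLD"`/`"NEW"`) and
#'   `response` (`"OLD"`/`"NEW"`), plus any grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `subject, condition,
#'   session, stimulus_type`.
#' @return Tibble of counts: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`, `n_old`, `n_new` per group.
#' @export
recognition_counts <- function(responses, ...) {
  abort_if(!all(c("truth", "response") %in% names(responses)),
           "responses needs columns truth, response")
  responses |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      hits = sum(.data$truth == "OLD" & .data$response == "OLD"),
      misses = sum(.data$truth == "OLD" & .data$response == "NEW"),
      false_alarms = sum(.data$truth == "NEW" & .data$response == "OLD"),
      correct_rejections = sum(.data$truth == "NEW" & .data$response == "NEW"),
      n_old = sum(.data$truth == "OLD"),
      n_new = sum(.data$truth == "NEW"),
      .groups = "drop"
    )
}

#' Recognition sensitivity (d-prime) with boundary corrections
#'
#' `d' = z(HitRate) - z(FalseAlarmRate)` with the inverse standard-normal CDF.
#' Extreme rates are replaced before the z transform: a hit rate of 1 becomes
#' `1 - 1/(2 n_old)` and a false-alarm rate of 0 becomes `1/(2 n_new)`;
#' symmetrically, a hit rate of 0 becomes `1/(2 n_old)` and a false-alarm rate
#' of 1 becomes `1 - 1/(2 n_new)` (an extension keeping d-prime finite in
#' every corner case). Vectorized.
#'
#' @param hits,false_alarms,n_old,n_new Counts.
#' @return Numeric vector of d-prime values.
#' @export
#' @examples
#' dprime(18, 4, 20, 20)   # ~2.123
#' dprime(20, 0, 20, 20)   # 2 * qnorm(0.975) ~ 3.920
dprime <- function(hits, false_alarms, n_old, n_new) {
  abort_if(any(n_old <= 0) || any(n_new <= 0), "n_old and n_new must be positive")
  abort_if(any(hits < 0) || any(false_alarms < 0) ||
             any(hits > n_old) || any(false_alarms > n_new),
           "counts out of range")
  hr <- hits / n_old
  far <- false_alarms / n_new
  hr <- ifelse(hr >= 1, 1 - 1 / (2 * n_old),
               ifelse(hr <= 0, 1 / (2 * n_old), hr))
  far <- ifelse(far <= 0, 1 / (2 * n_new),
                ifelse(far >= 1, 1 - 1 / (2 * n_new), far))
  qnorm(hr) - qnorm(far)
}

#' d-prime per group from a response table
#'
#' Convenience composition of [recognition_counts()] and [dprime()].
#'
#' @inheritParams recognition_counts
#' @return The count table with an extra `dprime` column.
#' @export
dprime_table <- function(responses, ...) {
  recognition_counts(responses, ...) |>
    dplyr::mutate(dprime = dprime(.data$hits, .data$false_alarms,
                                  .data$n_old, .data$n_new))
}
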