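# Plain-text interchange for event logs and trial tables.

#' Write / read an event log as TSV
#'
#' Columns: `onset_s`, `duration_s`, `type` and, for stimulations,
#' `intensity_step`, `train_id`, `outcome`. Paired `stim_on`/`stim_off` rows
#' in external files are accepted by the consumers (see
#' [select_stim_epochs()]).
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  abort_if(!all(c("onset_s", "type") %in% names(ev)),
           "event file needs at least columns onset_s, type")
  ev
}
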