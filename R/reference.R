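#' Reference sleep-parameter summary table
#'
#' Published per-condition summary statistics (mean, SD, paired t) of the
#' polysomnographic sleep parameters from the motivating 17-participant
#' fragmentation study, shipped as a plain-text table. Used as an external
#' verification surface: condition differences recomputed from these printed
#' means must reproduce the printed differences.
#'
#' @return A tibble: `variable`, `mean_FRG`, `sd_FRG`, `mean_CTR`, `sd_CTR`,
#'   `t`, `p_printed`.
#' @export
reference_sleep_parameters <- function() {
  path <- system.file("extdata", "reference_sleep_parameters.tsv",
                      package = "remfrag")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(p_printed = readr::col_character()))
}

#' Condition difference of a summary sleep parameter
#'
#' @param params Summary table as from [reference_sleep_parameters()] or
#'   [compare_sleep_parameters()] output reshaped to the same columns.
#' @param variable Parameter name (row of the table).
#' @param conditions Difference order, default `FRG - CTR`.
#' @return The mean difference (first condition minus second).
#' @export
condition_difference <- function(params, variable,
                                 conditions = c("FRG", "CTR")) {
  i <- match(variable, params$variable)
  abort_if(is.na(i), paste0("unknown variable: ", variable))
  params[[paste0("mean_", conditions[1])]][i] -
    params[[paste0("mean_", conditions[2])]][i]
}
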