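#' Published RAR frequency reference table
#'
#' Stage-stratified carrier frequencies for the 23 recurrently altered
#' regions (18 gains, 5 losses) reported by a 48-sample early breast
#' cancer array-CGH discovery cohort, shipped as a plain-text fixture.
#' Frequencies are integer percents; the `event` column carries the
#' published earlier/later/unclassified timing call, which
#' [classify_event()] reproduces from the two stage frequencies alone.
#'
#' @return data frame with columns `name`, `chrom`, `map_position_mb`,
#'   `size_mb`, `cytoband`, `p_value`, `freq_total_pct`,
#'   `freq_stageI_pct`, `freq_stageII_pct`, `event`.
#' @export
reference_rar_table <- function() {
  path <- system.file("extdata", "reference_rar_table.tsv",
                      package = "rarseek", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
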