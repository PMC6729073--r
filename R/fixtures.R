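#' Published per-facility efficiency results (32 LTCF study)
#'
#' Returns the published per-DMU results of the 32-facility long-term care
#' study shipped with the package: for each facility the CCR technical
#' efficiency (TE), BCC pure technical efficiency (PTE), scale efficiency
#' (SE), returns-to-scale label, SBM efficiency, and the published rank
#' ("order"). Values are an exact transcription of the printed table at its
#' 3-decimal precision; nothing is recomputed.
#'
#' @return a data frame with columns `dmu`, `te`, `pte`, `se`, `rts`, `sbm`,
#'   `order` (32 rows).
#' @seealso [ltcf_table4()], [summarize_efficiency()]
#' @export
ltcf_table3 <- function() {
  path <- system.file("extdata", "ltcf_table3.csv", package = "ltcfdea",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(rts = "character"))
  stopifnot(nrow(df) == 32L, all(df$rts %in% c("CRS", "IRS", "DRS")),
            all(df$te > 0 & df$te <= 1), all(df$sbm > 0 & df$sbm <= 1))
  df
}

#' Published input adjustment table (8 DRS facilities)
#'
#' Returns the published slack-analysis table for the eight facilities under
#' decreasing returns to scale: per facility and per input indicator the
#' number of adjustments (NA = actual - projection) and the adjustment
#' proportion (NA / actual x 100), for administrative staff, medical staff,
#' caregivers, paramedical staff and beds, plus the published mean row.
#' The source table's typesetting is partly ambiguous at the per-cell level;
#' the mean row is the authoritative anchor and the transcribed percentage
#' columns reproduce it.
#'
#' @param include_mean keep the published `"Mean"` row (default `TRUE`).
#' @return a data frame with columns `dmu` and `<indicator>_na`,
#'   `<indicator>_pct` pairs for the five adjusted inputs.
#' @export
ltcf_table4 <- function(include_mean = TRUE) {
  path <- system.file("extdata", "ltcf_table4.csv", package = "ltcfdea",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(dmu = "character"))
  if (!include_mean) df <- df[df$dmu != "Mean", ]
  df
}

#' Published descriptive statistics of the study's inputs and outputs
#'
#' Per-indicator mean, standard deviation and range of the 32-facility
#' input/output table, used as moment targets by [simulate_ltcf()]. The
#' `hard_clip` flag marks the ranges that are unambiguous in the source
#' (caregivers and beds) and enforced as hard truncation bounds.
#'
#' @return a data frame with columns `variable`, `role`, `direction`, `unit`,
#'   `mean`, `sd`, `min`, `max`, `hard_clip`.
#' @export
ltcf_moments <- function() {
  path <- system.file("extdata", "table2_moments.csv", package = "ltcfdea",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(hard_clip = "logical"))
}
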