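#' The published clinical-feature frequency reference
#'
#' Frequencies of the individual clinical features among pathologically
#' confirmed CBD patients, as numerator (documented present) over
#' denominator (documented present or absent), at presentation and during
#' the entire disease course. `published_*` columns hold the pooled
#' multi-centre frequencies of the consensus-criteria report;
#' `cohort_*` columns hold the 19-patient clinicopathological validation
#' series. The bradykinesia/clumsy-limb composite row is accompanied by its
#' two sub-rows, which have no published counterpart (`NA`); the duplicated
#' eye-movement row of the printed table is collapsed to one. The aphasia
#' course denominator of 20 is reproduced verbatim from the printed table.
#'
#' @return A tibble with columns `feature`, `timepoint`, `published_n`,
#'   `published_den`, `cohort_n`, `cohort_den`, plus derived
#'   `published_pct` and `cohort_pct` (full precision, percent scale).
#' @examples
#' armstrong_reference()
#' @export
armstrong_reference <- function() {
  path <- system.file("extdata", "armstrong_reference.csv",
                      package = "cbdcriteria", mustWork = TRUE)
  ref <- readr::read_csv(path, col_types = "ccnnnn", progress = FALSE)
  ref$published_pct <- 100 * ref$published_n / ref$published_den
  ref$cohort_pct <- 100 * ref$cohort_n / ref$cohort_den
  ref
}
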