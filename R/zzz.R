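#' racescreen: promoter-activity screening from 5' RACE-Seq
#'
#' Simulates and analyzes massively parallel screens of randomized promoter
#' initially transcribed regions read out by 5' RACE sequencing. See
#' `vignette("promoter-activity-screening")` for the model and the analysis
#' pipeline.
#'
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

#' @importFrom stats setNames quantile rbinom rmultinom runif cor
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom data.table data.table
#' @importFrom Rcpp evalCpp
#' @useDynLib racescreen, .registration = TRUE
NULL
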