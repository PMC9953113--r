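ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "rheis", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled reference results: per-chemical normalized capacitance
#'
#' Published normalized-capacitance results at 17 kHz on an RhE model for
#' the 20 GD 220 reference chemicals and the assay controls: mean and
#' sample SD over three runs at each post-exposure time (2, 24, 42 h).
#' These tables let the classifier, cut-off optimization, ROC analysis and
#' reproducibility scoring be exercised against real measured summaries
#' without access to raw spectra.
#'
#' @return Data frame: `chemical_casrn`, `role`, `ghs_label`, `time_h`,
#'   `mean`, `sd`.
#' @export
reference_capacitance_means <- function() {
  ref_csv("reference_capacitance_means.csv")
}

#' Bundled reference results: per-run normalized capacitance at 42 h
#'
#' Per-run means (over three tissue replicates) of normalized capacitance
#' at 17 kHz and 42 h, used for within-laboratory reproducibility scoring.
#'
#' @return Data frame: `chemical_casrn`, `role`, `ghs_label`, `run`,
#'   `mean`, `sd`.
#' @export
reference_capacitance_runs <- function() {
  ref_csv("reference_capacitance_runs.csv")
}

#' The 20 GD 220 reference chemicals
#'
#' @return Data frame: `number`, `name`, `chemical_casrn`, `ghs_label`
#'   (in vivo GHS: `NC` or `CAT2`), `physical_state`.
#' @export
reference_chemicals <- function() {
  ref_csv("reference_chemicals.csv")
}
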