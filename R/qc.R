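#' Tissue qualification by barrier integrity (TEER)
#'
#' A tissue qualifies for testing iff its initial transepithelial electrical
#' resistance lies within 600 to 2500 Ohm cm^2, both bounds inclusive;
#' otherwise it is discarded. Bounds are applied exactly, with no tolerance.
#'
#' @param teer_ohm_cm2 TEER value(s) in Ohm cm^2 (>= 0).
#' @return Character vector, `"accept"` or `"discard"`.
#' @export
qualify_tissue <- function(teer_ohm_cm2) {
  stopifnot(all(teer_ohm_cm2 >= 0))
  ifelse(teer_ohm_cm2 >= 600 & teer_ohm_cm2 <= 2500, "accept", "discard")
}

#' Run qualification by assay controls
#'
#' A run is qualified iff the negative-control MTT absorbance lies within
#' 0.40 to 0.70 OD (inclusive) and the positive-control relative viability
#' is strictly below 50%. A non-qualified run invalidates every chemical
#' tested in it (all must be repeated); the verdict always carries the
#' violated criteria.
#'
#' @param negative_control_od Negative-control MTT absorbance (OD 570 nm).
#' @param positive_control_viability Positive-control relative viability, %.
#' @return List with `qualified` (logical) and `reasons` (character vector,
#'   empty when qualified).
#' @export
qualify_run <- function(negative_control_od, positive_control_viability) {
  if (missing(negative_control_od) || missing(positive_control_viability) ||
      is.na(negative_control_od) || is.na(positive_control_viability)) {
    stop(errorCondition("run QC requires both control values",
                        class = "rheis_missing_control"))
  }
  reasons <- character(0)
  if (negative_control_od < 0.40 || negative_control_od > 0.70) {
    reasons <- c(reasons, "negative control OD outside [0.40, 0.70]")
  }
  if (positive_control_viability >= 50) {
    reasons <- c(reasons, "positive control viability not < 50%")
  }
  list(qualified = length(reasons) == 0L, reasons = reasons)
}

#' Flag chemicals for re-testing on replicate variability
#'
#' A chemical is re-tested when the SD of relative viability across its
#' tissue replicates exceeds 18 percentage points (strictly; SD = 18
#' passes).
#'
#' @param viability_sd Named numeric vector or data frame
#'   (`chemical_casrn`, `viability_sd`) of per-chemical replicate SDs.
#' @return Character vector of chemicals to re-test (possibly empty).
#' @export
flag_retests <- function(viability_sd) {
  if (is.data.frame(viability_sd)) {
    stopifnot(all(c("chemical_casrn", "viability_sd") %in%
                    names(viability_sd)))
    sds <- stats::setNames(viability_sd$viability_sd,
                           viability_sd$chemical_casrn)
  } else {
    sds <- viability_sd
  }
  if (length(sds) == 0L) return(character(0))
  names(sds)[sds > 18]
}

#' Apply run and tissue qualification to a study
#'
#' Filters a spectra table exactly as the run-acceptance rules prescribe:
#' tissues with out-of-range TEER are discarded, and all chemicals of a
#' run with failing controls are dropped (the run must be repeated). The
#' filtering is idempotent.
#'
#' @param spectra Long spectra table (see [normalize_study()]).
#' @param qc_teer Optional data frame `tissue_id`, `teer_ohm_cm2`.
#' @param qc_controls Optional data frame `run`, `negative_control_od`,
#'   `positive_control_viability`.
#' @return List with `spectra` (filtered table), `discarded_tissues`,
#'   `non_qualified_runs`, and `run_reasons` (named list).
#' @export
apply_qc <- function(spectra, qc_teer = NULL, qc_controls = NULL) {
  discarded <- character(0)
  bad_runs <- integer(0)
  reasons <- list()
  if (!is.null(qc_teer)) {
    v <- qualify_tissue(qc_teer$teer_ohm_cm2)
    discarded <- qc_teer$tissue_id[v == "discard"]
    spectra <- spectra[!spectra$tissue_id %in% discarded, ]
  }
  if (!is.null(qc_controls)) {
    for (i in seq_len(nrow(qc_controls))) {
      q <- qualify_run(qc_controls$negative_control_od[i],
                       qc_controls$positive_control_viability[i])
      if (!q$qualified) {
        bad_runs <- c(bad_runs, qc_controls$run[i])
        reasons[[as.character(qc_controls$run[i])]] <- q$reasons
      }
    }
    spectra <- spectra[!spectra$run %in% bad_runs, ]
  }
  list(spectra = spectra, discarded_tissues = as.character(discarded),
       non_qualified_runs = bad_runs, run_reasons = reasons)
}
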