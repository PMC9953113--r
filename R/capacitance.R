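#' Construct an impedance spectrum
#'
#' One tissue's frequency sweep of complex impedance at one time point.
#' `time_h = 0` denotes the pre-exposure baseline sweep.
#'
#' @param tissue_id Opaque tissue identifier (length-1 character).
#' @param time_h Hours since end of exposure (0 = pre-exposure baseline).
#' @param frequency_hz Strictly increasing frequencies in Hz (>= 2 points).
#' @param z_real Real part of impedance in Ohm, same length as `frequency_hz`.
#' @param z_imag Imaginary part of impedance in Ohm (signed; capacitive
#'   points are negative by convention).
#' @return A data frame of class `"impedance_spectrum"` with columns
#'   `frequency_hz`, `z_real`, `z_imag` and attributes `tissue_id`, `time_h`.
#' @export
impedance_spectrum <- function(tissue_id, time_h, frequency_hz, z_real, z_imag) {
  if (length(frequency_hz) < 2L) {
    stop("an impedance spectrum needs at least 2 frequency points",
         call. = FALSE)
  }
  check_grid(frequency_hz)
  if (length(z_real) != length(frequency_hz) ||
      length(z_imag) != length(frequency_hz)) {
    stop("`z_real` and `z_imag` must match the length of `frequency_hz`",
         call. = FALSE)
  }
  if (anyNA(z_real) || anyNA(z_imag)) {
    stop("impedance values must not contain NA", call. = FALSE)
  }
  out <- data.frame(frequency_hz = as.numeric(frequency_hz),
                    z_real = as.numeric(z_real),
                    z_imag = as.numeric(z_imag))
  attr(out, "tissue_id") <- as.character(tissue_id)
  attr(out, "time_h") <- as.numeric(time_h)
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}

#' Apparent capacitance from a reactance sweep
#'
#' Converts imaginary impedance to the apparent capacitance
#' \eqn{C(f) = 1 / (2 \pi f |Z''(f)|)}: the capacitance a pure capacitor
#' would need to produce the observed reactance at each frequency. The
#' magnitude of \eqn{Z''} is used so that both sign conventions for
#' capacitive reactance yield positive capacitance.
#'
#' @param frequency_hz Frequencies in Hz.
#' @param z_imag Imaginary impedance in Ohm (signed or unsigned).
#' @return Numeric vector of capacitances in farad.
#' @export
apparent_capacitance <- function(frequency_hz, z_imag) {
  zero <- which(z_imag == 0)
  if (length(zero) > 0L) {
    stop(errorCondition(
      sprintf("degenerate spectrum: Z'' = 0 at %g Hz", frequency_hz[zero[1L]]),
      class = "rheis_degenerate_spectrum"))
  }
  1 / (2 * pi * frequency_hz * abs(z_imag))
}

#' Convert an impedance spectrum to a capacitance series
#'
#' @param spectrum An [impedance_spectrum()] object.
#' @return A data frame of class `"capacitance_series"` with columns
#'   `frequency_hz` and `capacitance_f` (farad); attribute
#'   `normalized = FALSE`.
#' @seealso [apparent_capacitance()] for the underlying vector operation,
#'   [normalize_capacitance()] for the baseline-normalized form.
#' @export
capacitance_from_impedance <- function(spectrum) {
  if (!inherits(spectrum, "impedance_spectrum")) {
    stop("`spectrum` must be an impedance_spectrum", call. = FALSE)
  }
  out <- data.frame(
    frequency_hz = spectrum$frequency_hz,
    capacitance_f = apparent_capacitance(spectrum$frequency_hz,
                                         spectrum$z_imag))
  attr(out, "tissue_id") <- attr(spectrum, "tissue_id")
  attr(out, "time_h") <- attr(spectrum, "time_h")
  attr(out, "normalized") <- FALSE
  class(out) <- c("capacitance_series", "data.frame")
  out
}

#' Group one tissue's spectra across time points
#'
#' Bundles the sweeps of a single tissue (including its mandatory time-0
#' pre-exposure baseline) so post-exposure capacitance can be normalized
#' against the tissue's own baseline.
#'
#' @param spectra List of [impedance_spectrum()] objects for one tissue; all
#'   on the same frequency grid, one of them at `time_h = 0`.
#' @param chemical_casrn,run,replicate Optional study coordinates.
#' @return An object of class `"tissue_series"`.
#' @export
tissue_series <- function(spectra, chemical_casrn = NA_character_,
                          run = NA_integer_, replicate = NA_integer_) {
  if (!is.list(spectra) || length(spectra) == 0L ||
      !all(vapply(spectra, inherits, logical(1), "impedance_spectrum"))) {
    stop("`spectra` must be a non-empty list of impedance_spectrum objects",
         call. = FALSE)
  }
  ids <- unique(vapply(spectra, attr, character(1), "tissue_id"))
  if (length(ids) != 1L) {
    stop("all spectra in a tissue series must share one tissue_id",
         call. = FALSE)
  }
  times <- vapply(spectra, attr, numeric(1), "time_h")
  if (anyDuplicated(times)) {
    stop("duplicate time points in tissue series", call. = FALSE)
  }
  if (!any(times == 0)) {
    stop(errorCondition(
      sprintf("tissue %s has no time-0 baseline sweep", ids),
      class = "rheis_missing_baseline"))
  }
  grid0 <- spectra[[1L]]$frequency_hz
  same <- vapply(spectra, function(s) {
    length(s$frequency_hz) == length(grid0) && all(s$frequency_hz == grid0)
  }, logical(1))
  if (!all(same)) {
    stop(errorCondition(
      sprintf("tissue %s: spectra are not on a shared frequency grid", ids),
      class = "rheis_grid_mismatch"))
  }
  structure(list(tissue_id = ids, chemical_casrn = chemical_casrn,
                 run = run, replicate = replicate,
                 spectra = spectra[order(times)]),
            class = "tissue_series")
}

#' Normalize post-exposure capacitance against the pre-exposure baseline
#'
#' Computes the dimensionless ratio \eqn{C_x(f) / C_0(f)} for every grid
#' frequency, where \eqn{C_0} is the tissue's own capacitance before chemical
#' application (time 0) and \eqn{C_x} its capacitance at `time_h` after
#' exposure. Baselines are strictly per tissue, never a group mean.
#'
#' @param series A [tissue_series()] object.
#' @param time_h Post-exposure time point present in `series`.
#' @return A `"capacitance_series"` data frame with columns `frequency_hz`
#'   and `norm_capacitance`; attribute `normalized = TRUE`.
#' @export
normalize_capacitance <- function(series, time_h) {
  if (!inherits(series, "tissue_series")) {
    stop("`series` must be a tissue_series", call. = FALSE)
  }
  times <- vapply(series$spectra, attr, numeric(1), "time_h")
  ix <- which(times == time_h)
  if (length(ix) != 1L) {
    stop(errorCondition(
      sprintf("tissue %s has no sweep at %g h", series$tissue_id, time_h),
      class = "rheis_missing_time"))
  }
  i0 <- which(times == 0)
  c0 <- capacitance_from_impedance(series$spectra[[i0]])
  cx <- capacitance_from_impedance(series$spectra[[ix]])
  out <- data.frame(frequency_hz = c0$frequency_hz,
                    norm_capacitance = cx$capacitance_f / c0$capacitance_f)
  attr(out, "tissue_id") <- series$tissue_id
  attr(out, "time_h") <- as.numeric(time_h)
  attr(out, "normalized") <- TRUE
  class(out) <- c("capacitance_series", "data.frame")
  out
}

#' Normalize a whole study of impedance spectra
#'
#' Long-format workhorse behind [normalize_capacitance()]: converts every
#' sweep of a study table to apparent capacitance and divides each
#' post-exposure value by the same tissue's time-0 value at the same
#' frequency.
#'
#' @param spectra Long-format data frame with columns `tissue_id`,
#'   `chemical_casrn`, `run`, `replicate`, `time_h`, `frequency_hz`,
#'   `z_real_ohm`, `z_imag_ohm`; `time_h == 0` rows are baselines.
#' @return Data frame with columns `tissue_id`, `chemical_casrn`, `run`,
#'   `replicate`, `time_h`, `frequency_hz`, `norm_capacitance`, containing
#'   only post-exposure (`time_h > 0`) rows.
#' @export
normalize_study <- function(spectra) {
  need <- c("tissue_id", "chemical_casrn", "run", "replicate", "time_h",
            "frequency_hz", "z_real_ohm", "z_imag_ohm")
  miss <- setdiff(need, names(spectra))
  if (length(miss) > 0L) {
    stop(sprintf("spectra table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(spectra) == 0L) stop("spectra table is empty", call. = FALSE)
  cap <- apparent_capacitance(spectra$frequency_hz, spectra$z_imag_ohm)
  key <- paste(spectra$tissue_id, spectra$frequency_hz, sep = "\r")
  is_base <- spectra$time_h == 0
  base_tissues <- unique(spectra$tissue_id[is_base])
  no_base <- setdiff(unique(spectra$tissue_id), base_tissues)
  if (length(no_base) > 0L) {
    stop(errorCondition(
      sprintf("tissue %s has no time-0 baseline sweep", no_base[1L]),
      class = "rheis_missing_baseline"))
  }
  if (anyDuplicated(key[is_base])) {
    stop("duplicate baseline rows for the same tissue and frequency",
         call. = FALSE)
  }
  m <- match(key[!is_base], key[is_base])
  if (anyNA(m)) {
    bad <- which(!is_base)[which(is.na(m))[1L]]
    stop(errorCondition(
      sprintf("tissue %s: no baseline value at %g Hz (grid mismatch)",
              spectra$tissue_id[bad], spectra$frequency_hz[bad]),
      class = "rheis_grid_mismatch"))
  }
  out <- spectra[!is_base, c("tissue_id", "chemical_casrn", "run",
                             "replicate", "time_h", "frequency_hz")]
  out$norm_capacitance <- cap[!is_base] / cap[is_base][m]
  rownames(out) <- NULL
  out
}

#' Frequency of maximum normalized-capacitance response
#'
#' Selects the grid frequency at which the mean normalized capacitance over
#' the supplied series is largest. By study convention the series supplied
#' are the positive-control tissues at the latest measured time point (see
#' [select_analysis_frequency()]); ties are broken toward the lower
#' frequency.
#'
#' @param normalized Data frame with columns `frequency_hz` and
#'   `norm_capacitance` (any number of series stacked in long format).
#' @return The grid frequency (Hz) with maximum mean response.
#' @export
peak_response_frequency <- function(normalized) {
  if (!is.data.frame(normalized) || nrow(normalized) == 0L) {
    stop("`normalized` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("frequency_hz", "norm_capacitance") %in% names(normalized))) {
    stop("`normalized` needs columns frequency_hz and norm_capacitance",
         call. = FALSE)
  }
  f <- sort(unique(normalized$frequency_hz))
  idx <- match(normalized$frequency_hz, f)
  mu <- vapply(seq_along(f), function(i) {
    mean(normalized$norm_capacitance[idx == i])
  }, numeric(1))
  f[which.max(mu)] # first maximum in ascending order: lower frequency
}

#' Select the analysis frequency for a study
#'
#' Applies the peak-response rule to a normalized study table: by default the
#' positive-control tissues at the latest measured time point define the
#' response spectrum whose maximum picks the analysis frequency; optionally
#' all treated tissues are pooled instead.
#'
#' @param normalized Output of [normalize_study()].
#' @param metadata Study metadata with columns `chemical_casrn` and `role`
#'   (`"test"`, `"negative_control"`, `"positive_control"`).
#' @param cohort `"positive_control"` (default) or `"all"` (all tissues
#'   except the negative control).
#' @param time_h Time point to evaluate; `NULL` (default) uses the latest.
#' @return The selected frequency in Hz.
#' @export
select_analysis_frequency <- function(normalized, metadata,
                                      cohort = c("positive_control", "all"),
                                      time_h = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(time_h)) time_h <- max(normalized$time_h)
  keep_casrn <- if (cohort == "positive_control") {
    metadata$chemical_casrn[metadata$role == "positive_control"]
  } else {
    metadata$chemical_casrn[metadata$role != "negative_control"]
  }
  sub <- normalized[normalized$time_h == time_h &
                      normalized$chemical_casrn %in% keep_casrn, ]
  if (nrow(sub) == 0L) {
    stop("no normalized data for the requested cohort/time", call. = FALSE)
  }
  peak_response_frequency(sub)
}
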