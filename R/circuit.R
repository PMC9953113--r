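#' Two-compartment equivalent-circuit parameters for an RhE tissue
#'
#' The simulator models an RhE insert as a series resistance (electrolyte
#' plus electrodes) followed by two parallel resistor/constant-phase-element
#' blocks: the stratum corneum (the principal electrical barrier, high
#' resistance, small capacitance) and the viable epidermis. A constant phase
#' element generalizes the capacitor (`alpha = 1` is ideal) to describe the
#' dispersive dielectric behaviour of tissue.
#'
#' A block resistance of 0 removes that block (single-block reduction).
#'
#' @param r_series Series resistance in Ohm (> 0).
#' @param r_sc,c_sc,cpe_alpha_sc Stratum-corneum block: resistance (Ohm),
#'   capacitance (F) and CPE exponent in (0, 1].
#' @param r_ve,c_ve,cpe_alpha_ve Viable-epidermis block, same units.
#' @return An object of class `"circuit_params"`.
#' @export
circuit_params <- function(r_series, r_sc, c_sc, cpe_alpha_sc = 1,
                           r_ve, c_ve, cpe_alpha_ve = 1) {
  stopifnot(r_series > 0, r_sc >= 0, c_sc > 0, r_ve >= 0, c_ve > 0,
            cpe_alpha_sc > 0, cpe_alpha_sc <= 1,
            cpe_alpha_ve > 0, cpe_alpha_ve <= 1)
  structure(list(r_series = r_series,
                 r_sc = r_sc, c_sc = c_sc, cpe_alpha_sc = cpe_alpha_sc,
                 r_ve = r_ve, c_ve = c_ve, cpe_alpha_ve = cpe_alpha_ve),
            class = "circuit_params")
}

#' Default baseline circuit of the synthetic study
#'
#' Chosen so that a fully damaged stratum corneum produces a
#' normalized-capacitance spectrum with an interior maximum at the canonical
#' grid point \eqn{10^{4.25} \approx 17.8} kHz, with ratio values at that
#' frequency in the 20--35 range for the positive control.
#'
#' @return A [circuit_params()] object.
#' @export
default_circuit_params <- function() {
  circuit_params(r_series = 100,
                 r_sc = 2e4, c_sc = 2e-9, cpe_alpha_sc = 0.90,
                 r_ve = 100, c_ve = 2e-9, cpe_alpha_ve = 0.95)
}

#' Complex impedance of the tissue circuit
#'
#' \deqn{Z(\omega) = R_s + \frac{R_{sc}}{1 + (j\omega R_{sc} C_{sc})^{\alpha_{sc}}}
#'   + \frac{R_{ve}}{1 + (j\omega R_{ve} C_{ve})^{\alpha_{ve}}}}
#' with \eqn{\omega = 2\pi f}. As \eqn{f \to 0} the impedance tends to the
#' purely real sum of resistances; as \eqn{f \to \infty} it tends to
#' `r_series`.
#'
#' @param params A [circuit_params()] object.
#' @param frequency_hz Vector of frequencies in Hz (> 0).
#' @return Complex vector of impedances in Ohm.
#' @export
circuit_impedance <- function(params, frequency_hz) {
  stopifnot(inherits(params, "circuit_params"), all(frequency_hz > 0))
  w <- 2 * pi * frequency_hz
  z <- complex(real = rep(params$r_series, length(w)), imaginary = 0)
  z <- z + cpe_block(params$r_sc, params$c_sc, params$cpe_alpha_sc, w)
  z + cpe_block(params$r_ve, params$c_ve, params$cpe_alpha_ve, w)
}

# R || CPE block; (j w R C)^a computed in polar form. r = 0 removes the block.
cpe_block <- function(r, c, alpha, w) {
  if (r == 0) return(complex(real = numeric(length(w)), imaginary = 0))
  x <- (w * r * c)^alpha
  jwa <- complex(modulus = x, argument = alpha * pi / 2)
  r / (1 + jwa)
}

#' Describe a chemical as a damage archetype
#'
#' The simulator reduces each test chemical to three numbers: a damage
#' `grade` in \[0, 1\] (the asymptotic fraction of barrier disruption), an
#' onset delay `lag_h`, and a first-order `rate_per_h`. The damage level at
#' time \eqn{t} after exposure is
#' \deqn{d(t) = \mathrm{grade} \cdot (1 - e^{-\mathrm{rate} \cdot \max(0,\, t - \mathrm{lag})})}
#' so that \eqn{d(0) = 0} and baselines are unperturbed. Delayed responders
#' (`lag_h > 2`) are indistinguishable from non-irritants at the 2 h reading
#' but fully declared by 42 h.
#'
#' Non-irritant (`ghs_label = "NC"`) archetypes must have `grade <= 0.2`;
#' irritant (`"CAT2"`) archetypes must have `grade >= 0.5`.
#'
#' @param casrn Chemical identifier (CAS registry number as text).
#' @param ghs_label `"NC"`, `"CAT2"`, or `NA` for controls.
#' @param grade Damage intensity in \[0, 1\].
#' @param lag_h Onset delay in hours (>= 0).
#' @param rate_per_h First-order damage rate (> 0).
#' @param role `"test"`, `"negative_control"` or `"positive_control"`.
#' @return A one-row data frame of class `"chemical_archetype"`.
#' @export
chemical_archetype <- function(casrn, ghs_label, grade, lag_h = 0,
                               rate_per_h = 0.5, role = "test") {
  stopifnot(grade >= 0, grade <= 1, lag_h >= 0, rate_per_h > 0)
  role <- match.arg(role, c("test", "negative_control", "positive_control"))
  if (role == "test") {
    if (identical(ghs_label, "NC") && grade > 0.2) {
      stop("a No Category archetype must have grade <= 0.2", call. = FALSE)
    }
    if (identical(ghs_label, "CAT2") && grade < 0.5) {
      stop("a Category 2 archetype must have grade >= 0.5", call. = FALSE)
    }
    if (!ghs_label %in% c("NC", "CAT2")) {
      stop("`ghs_label` must be \"NC\" or \"CAT2\" for test chemicals",
           call. = FALSE)
    }
  }
  structure(data.frame(chemical_casrn = as.character(casrn),
                       role = role, ghs_label = as.character(ghs_label),
                       grade = grade, lag_h = lag_h,
                       rate_per_h = rate_per_h,
                       stringsAsFactors = FALSE),
            class = c("chemical_archetype", "data.frame"))
}

#' Damage level of an archetype at a given time
#'
#' @param archetype One-row archetype data frame (see [chemical_archetype()]).
#' @param time_h Hours since end of exposure (>= 0), vectorized.
#' @return Damage fraction(s) in \[0, 1\].
#' @export
damage_level <- function(archetype, time_h) {
  stopifnot(all(time_h >= 0))
  archetype$grade *
    (1 - exp(-archetype$rate_per_h * pmax(0, time_h - archetype$lag_h)))
}

#' Perturb circuit parameters by chemical damage
#'
#' Irritation is modelled as barrier disruption acting on the
#' stratum-corneum block only: at damage level \eqn{d}, its resistance drops
#' to \eqn{R_{sc}(1 - 0.95 d)} and its capacitance rises to
#' \eqn{C_{sc}(1 + k_c d)}. All other elements are unchanged, so irritants
#' raise the apparent capacitance of the tissue, most visibly around the
#' stratum-corneum relaxation frequency.
#'
#' @param base A [circuit_params()] object (pre-exposure tissue).
#' @param archetype A [chemical_archetype()] row.
#' @param time_h Hours since end of exposure (>= 0).
#' @param k_c Capacitance gain at full damage (default 30).
#' @param damage Optional precomputed damage level overriding
#'   `damage_level(archetype, time_h)`.
#' @return A [circuit_params()] object.
#' @export
apply_chemical_effect <- function(base, archetype, time_h, k_c = 30,
                                  damage = NULL) {
  stopifnot(inherits(base, "circuit_params"))
  d <- if (is.null(damage)) damage_level(archetype, time_h) else damage
  stopifnot(length(d) == 1L, d >= 0, d <= 1)
  out <- base
  out$r_sc <- base$r_sc * (1 - 0.95 * d)
  out$c_sc <- base$c_sc * (1 + k_c * d)
  out
}
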