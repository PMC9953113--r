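#' Default chemical archetypes of the synthetic study
#'
#' The 20 reference chemicals for skin-irritation method validation (10 GHS
#' No Category, 10 Category 2) plus PBS as negative control and 5% SDS as
#' positive control. Damage grades, onset lags and rates are fixed package
#' defaults chosen once so that, pushed through the default circuit, the
#' simulated normalized capacitance at the analysis frequency spans the
#' ranges observed on real RhE tissue (non-irritants roughly 0.8--6,
#' irritants roughly 8--35) and so that two irritants (CASRN 629-19-6 and
#' 7340-90-1) are delayed responders: silent at 2 h, declared by 24--42 h.
#'
#' @return Data frame with one row per condition: `chemical_casrn`, `role`,
#'   `ghs_label`, `grade`, `lag_h`, `rate_per_h`.
#' @export
default_archetypes <- function() {
  a <- function(...) chemical_archetype(...)
  out <- rbind(
    a("PBS", NA_character_, 0.000, 0, 0.5, role = "negative_control"),
    a("SDS-5pct", NA_character_, 1.000, 0, 2.0, role = "positive_control"),
    # GHS No Category
    a("6940-78-9", "NC", 0.200, 0.0, 0.08),
    a("84-66-2", "NC", 0.020, 0.0, 0.50),
    a("86-87-3", "NC", 0.030, 0.0, 0.50),
    a("7493-74-5", "NC", 0.050, 0.0, 0.30),
    a("67-63-0", "NC", 0.160, 0.0, 1.50),
    a("3446-89-7", "NC", 0.195, 2.5, 0.15),
    a("112-61-8", "NC", 0.010, 0.0, 0.50),
    a("5870-93-9", "NC", 0.015, 0.0, 0.50),
    a("6259-76-3", "NC", 0.005, 0.0, 0.50),
    a("104-55-2", "NC", 0.200, 0.0, 0.05),
    # GHS Category 2
    a("112-30-1", "CAT2", 1.000, 0.0, 0.12),
    a("103-95-7", "CAT2", 0.720, 0.0, 0.15),
    a("111-25-1", "CAT2", 0.550, 0.0, 0.25),
    a("86604-75-3", "CAT2", 1.000, 0.0, 2.00),
    a("629-19-6", "CAT2", 0.500, 4.0, 0.10), # delayed responder
    a("1310-58-3", "CAT2", 1.000, 0.0, 2.00),
    a("7340-90-1", "CAT2", 0.680, 8.0, 0.10), # delayed responder
    a("5271-27-2", "CAT2", 0.700, 0.0, 1.50),
    a("111-71-7", "CAT2", 1.000, 0.0, 2.00),
    a("127-18-4", "CAT2", 0.950, 0.0, 2.00))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Design of a synthetic EIS irritation study
#'
#' Bundles everything [generate_study()] needs: the chemical archetypes, the
#' run/replicate structure, measurement times, the frequency grid, the
#' baseline circuit, and the variability knobs.
#'
#' Variability has four independent sources, each off when set to 0:
#' multiplicative lognormal measurement noise on |Z| per frequency point
#' (`noise_sd_log`), lognormal inter-tissue spread of the baseline circuit
#' elements (`tissue_cv`), lognormal tissue-level spread of chemical
#' susceptibility (`grade_cv`, multiplies the damage grade), and a run-level
#' susceptibility multiplier (`run_cv`, modelling batch effects). Run- and
#' tissue-level components are exposed separately because their split cannot
#' be identified from published summary tables.
#'
#' @param archetypes Archetype table, default [default_archetypes()].
#' @param n_runs,n_replicates Experimental structure (default 3 x 3).
#' @param times_h Measurement times in hours, must include 0 (baseline).
#' @param grid Frequency grid in Hz, default [canonical_grid()].
#' @param base_params Baseline [circuit_params()].
#' @param noise_sd_log SD of log measurement noise on |Z| (default 0.05).
#' @param tissue_cv SD of log inter-tissue baseline variability (default 0.10).
#' @param grade_cv SD of log tissue susceptibility (default 0.20).
#' @param run_cv SD of log run-level susceptibility (default 0.05).
#' @param drift_per_h Exponential decay rate of tissue capacitance during
#'   incubation (default 0.005 / h), common to all tissues; reproduces the
#'   slight sub-unity drift of untreated controls over 42 h.
#' @param k_c Capacitance gain at full damage (default 30).
#' @param seed Master integer seed; all randomness derives from it.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(archetypes = default_archetypes(),
                         n_runs = 3, n_replicates = 3,
                         times_h = c(0, 2, 24, 42),
                         grid = canonical_grid(),
                         base_params = default_circuit_params(),
                         noise_sd_log = 0.05, tissue_cv = 0.10,
                         grade_cv = 0.20, run_cv = 0.05,
                         drift_per_h = 0.005, k_c = 30, seed = 1L) {
  stopifnot(n_runs >= 1, n_replicates >= 1, 0 %in% times_h,
            noise_sd_log >= 0, tissue_cv >= 0, grade_cv >= 0, run_cv >= 0,
            drift_per_h >= 0, k_c >= 0)
  check_grid(grid)
  structure(list(archetypes = archetypes, n_runs = as.integer(n_runs),
                 n_replicates = as.integer(n_replicates),
                 times_h = sort(unique(times_h)), grid = grid,
                 base_params = base_params, noise_sd_log = noise_sd_log,
                 tissue_cv = tissue_cv, grade_cv = grade_cv, run_cv = run_cv,
                 drift_per_h = drift_per_h, k_c = k_c,
                 seed = as.integer(seed)),
            class = "study_design")
}

# Deterministic 31-bit hash of a string; used to derive independent RNG
# substreams per tissue/run so adding conditions never reshuffles existing
# tissues.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

substream_seed <- function(master, label) {
  as.integer((as.numeric(master) + stable_hash(label)) %% 2147483647)
}

#' Generate a complete synthetic EIS irritation study
#'
#' Simulates one impedance sweep per tissue and time point from the
#' two-compartment circuit: per-tissue baseline parameters are drawn around
#' `base_params`, chemical damage perturbs the stratum-corneum block
#' according to the archetype time course, a common incubation drift shrinks
#' tissue capacitance slowly over time, and multiplicative lognormal noise
#' is applied to |Z| with phase preserved. Output is fully reproducible from
#' the design seed; each tissue and run uses its own deterministic RNG
#' substream.
#'
#' @param design A [study_design()].
#' @return An object of class `"eis_study"`: a list with `spectra` (long
#'   data frame: `tissue_id`, `chemical_casrn`, `run`, `replicate`,
#'   `time_h`, `frequency_hz`, `z_real_ohm`, `z_imag_ohm`), `metadata`
#'   (archetype table) and `design`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  arch <- design$archetypes
  grid <- design$grid
  times <- design$times_h
  nf <- length(grid)
  nt <- length(times)

  run_mult <- vapply(seq_len(design$n_runs), function(r) {
    if (design$run_cv == 0) return(1)
    set.seed(substream_seed(design$seed, paste0("run:", r)))
    stats::rlnorm(1, 0, design$run_cv)
  }, numeric(1))

  blocks <- vector("list", nrow(arch) * design$n_runs * design$n_replicates)
  b <- 0L
  for (i in seq_len(nrow(arch))) {
    archetype <- arch[i, ]
    for (run in seq_len(design$n_runs)) {
      for (rep in seq_len(design$n_replicates)) {
        tid <- sprintf("%s_run%d_rep%d", archetype$chemical_casrn, run, rep)
        set.seed(substream_seed(design$seed, tid))
        pm <- if (design$tissue_cv == 0) rep(1, 5) else
          stats::rlnorm(5, 0, design$tissue_cv)
        gm <- if (design$grade_cv == 0) 1 else
          stats::rlnorm(1, 0, design$grade_cv)
        eps <- if (design$noise_sd_log == 0) numeric(nt * nf) else
          stats::rnorm(nt * nf, 0, design$noise_sd_log)
        bp <- design$base_params
        bp$r_series <- bp$r_series * pm[1L]
        bp$r_sc <- bp$r_sc * pm[2L]
        bp$c_sc <- bp$c_sc * pm[3L]
        bp$r_ve <- bp$r_ve * pm[4L]
        bp$c_ve <- bp$c_ve * pm[5L]
        d_eff <- min(1, archetype$grade * gm * run_mult[run])
        z <- complex(real = numeric(nt * nf))
        for (k in seq_len(nt)) {
          t <- times[k]
          d <- d_eff *
            (1 - exp(-archetype$rate_per_h * max(0, t - archetype$lag_h)))
          p <- apply_chemical_effect(bp, archetype, t, k_c = design$k_c,
                                     damage = d)
          drift <- exp(-design$drift_per_h * t)
          p$c_sc <- p$c_sc * drift
          p$c_ve <- p$c_ve * drift
          z[(k - 1L) * nf + seq_len(nf)] <- circuit_impedance(p, grid)
        }
        z <- z * exp(eps) # multiplicative noise on |Z|, phase preserved
        b <- b + 1L
        blocks[[b]] <- data.frame(
          tissue_id = tid,
          chemical_casrn = archetype$chemical_casrn,
          run = run, replicate = rep,
          time_h = rep(times, each = nf),
          frequency_hz = rep(grid, nt),
          z_real_ohm = Re(z), z_imag_ohm = Im(z),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(spectra = do.call(rbind, blocks), metadata = arch,
                 design = design),
            class = "eis_study")
}

#' Write a synthetic study to CSV
#'
#' Writes `spectra.csv` (long impedance table) and `metadata.csv` (archetype
#' table with GHS labels) into `dir`. Output is byte-identical for identical
#' studies.
#'
#' @param study An [generate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "eis_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             metadata = file.path(dir, "metadata.csv"))
  utils::write.csv(study$spectra, paths[["spectra"]], row.names = FALSE)
  utils::write.csv(study$metadata, paths[["metadata"]], row.names = FALSE)
  invisible(paths)
}

#' Read study CSV tables
#'
#' @param path Path to a spectra or metadata CSV written by [write_study()]
#'   (or hand-prepared in the same dialect; `#` lines are comments).
#' @return A data frame.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  out <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(out) == 0L) stop(sprintf("empty input file: %s", path),
                            call. = FALSE)
  out
}
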