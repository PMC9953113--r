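#' Pipeline configuration
#'
#' Collects every input and tunable of a full pipeline run. Inputs may be
#' file paths (CSV) or in-memory data frames. Exactly one of `spectra` (raw
#' impedance sweeps, normalized internally) or `scores` (pre-computed
#' per-run irritancy scores with truth labels: columns `chemical_casrn`,
#' `run`, `score`, `truth`) must be supplied.
#'
#' @param spectra Long impedance table or path (see [normalize_study()]).
#' @param metadata Chemical metadata (`chemical_casrn`, `role`,
#'   `ghs_label`) or path; required with `spectra`.
#' @param scores Per-run labelled scores table or path (bypasses spectra).
#' @param qc_teer,qc_controls Optional QC tables or paths (see
#'   [apply_qc()]).
#' @param frequency `"auto"` (peak response of the positive control at the
#'   latest time) or a frequency in Hz, mapped to the nearest measured grid
#'   point.
#' @param time_h Evaluation time (2, 24 or 42; default 42).
#' @param cutoff `"auto"` (midpoint of the accuracy-optimal interval) or a
#'   positive number.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Optional integer recorded in the run log.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(spectra = NULL, metadata = NULL, scores = NULL,
                            qc_teer = NULL, qc_controls = NULL,
                            frequency = "auto", time_h = 42,
                            cutoff = "auto", out_dir = NULL, seed = NULL) {
  stopifnot(time_h %in% c(2, 24, 42))
  if (is.null(spectra) == is.null(scores)) {
    stop("supply exactly one of `spectra` or `scores`", call. = FALSE)
  }
  if (!is.null(spectra) && is.null(metadata)) {
    stop("`metadata` is required with `spectra`", call. = FALSE)
  }
  if (is.numeric(cutoff) && cutoff <= 0) {
    stop("`cutoff` must be > 0 when overridden", call. = FALSE)
  }
  structure(list(spectra = spectra, metadata = metadata, scores = scores,
                 qc_teer = qc_teer, qc_controls = qc_controls,
                 frequency = frequency, time_h = time_h, cutoff = cutoff,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields are passed through to [pipeline_config()]; table fields
#' (`spectra`, `metadata`, `scores`, `qc_teer`, `qc_controls`) must be file
#' paths, resolved relative to the YAML file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  pipeline_config(
    spectra = resolve(cfg$spectra), metadata = resolve(cfg$metadata),
    scores = resolve(cfg$scores), qc_teer = resolve(cfg$qc_teer),
    qc_controls = resolve(cfg$qc_controls),
    frequency = cfg$frequency %||% "auto",
    time_h = cfg$time_h %||% 42,
    cutoff = cfg$cutoff %||% "auto",
    out_dir = cfg$out_dir, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_table <- function(x) {
  if (is.null(x) || is.data.frame(x)) x else read_spectra_csv(x)
}

#' Run the full irritation-prediction pipeline
#'
#' Executes QC filtering, capacitance normalization, analysis-frequency
#' selection, scoring, classification, ROC/cut-off analysis and
#' within-laboratory reproducibility, and optionally writes all artifact
#' tables plus a run log to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"rheis_result"`: a list with `qualified`,
#'   `report` (a [performance_report()]; `NULL` when QC left no data),
#'   `frequency_hz`, `time_h`, `cutoff`, `cutoff_interval`,
#'   `chemical_calls`, `run_calls`, `wlr`, `roc`, and `qc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$scores)) {
    runs <- load_table(config$scores)
    need <- c("chemical_casrn", "run", "score", "truth")
    if (!all(need %in% names(runs))) {
      stop("scores table needs columns chemical_casrn, run, score, truth",
           call. = FALSE)
    }
    qc <- NULL
    frequency_hz <- if (is.numeric(config$frequency)) config$frequency
      else NA_real_
  } else {
    spectra <- load_table(config$spectra)
    metadata <- load_table(config$metadata)
    qc <- apply_qc(spectra, qc_teer = load_table(config$qc_teer),
                   qc_controls = load_table(config$qc_controls))
    if (nrow(qc$spectra) == 0L) {
      res <- structure(list(qualified = FALSE, report = NULL, qc = qc,
                            config = config),
                       class = "rheis_result")
      write_artifacts(res, config)
      return(res)
    }
    normalized <- normalize_study(qc$spectra)
    frequency_hz <- if (identical(config$frequency, "auto")) {
      select_analysis_frequency(normalized, metadata)
    } else {
      nearest_grid_frequency(config$frequency,
                             sort(unique(normalized$frequency_hz)))
    }
    ts <- tissue_scores(normalized, frequency_hz, config$time_h)
    runs <- label_scores(run_scores(ts), metadata)
  }

  chems <- chemical_scores(runs)
  chems <- chems[, c("chemical_casrn", "score", "sd", "n_runs")]
  truth <- runs$truth[match(chems$chemical_casrn, runs$chemical_casrn)]
  chems$truth <- truth
  chems <- chems[!is.na(chems$truth), ]

  opt <- optimal_cutoff(chems)
  cutoff <- if (identical(config$cutoff, "auto")) {
    if (is.finite(opt$lo) && is.finite(opt$hi)) (opt$lo + opt$hi) / 2
    else opt$hi
  } else {
    config$cutoff
  }

  report <- confusion_metrics(chems, cutoff)
  report$auc <- auc(chems)
  chems$call <- classify_capacitance(chems$score, cutoff)
  runs$call <- classify_capacitance(runs$score, cutoff)
  wlr <- within_lab_reproducibility(runs)
  report$wlr_percent <- wlr$percent

  res <- structure(list(qualified = TRUE, report = report,
                        frequency_hz = frequency_hz,
                        time_h = config$time_h, cutoff = cutoff,
                        cutoff_interval = opt,
                        chemical_calls = chems, run_calls = runs,
                        wlr = wlr, roc = roc_curve(chems), qc = qc,
                        config = config),
                   class = "rheis_result")
  write_artifacts(res, config)
  res
}

#' @export
print.rheis_result <- function(x, ...) {
  if (!x$qualified) {
    cat("Pipeline run NOT qualified: QC left no usable data\n")
    return(invisible(x))
  }
  cat(sprintf("EIS irritation prediction at %.4g Hz, %g h, cutoff %.3g\n",
              x$frequency_hz, x$time_h, x$cutoff))
  cat(sprintf("  accuracy-optimal cutoff interval: (%.3g, %.3g]\n",
              x$cutoff_interval$lo, x$cutoff_interval$hi))
  print(x$report)
  if (length(x$wlr$discordant) > 0L) {
    cat(sprintf("  discordant chemicals: %s\n",
                paste(x$wlr$discordant, collapse = ", ")))
  }
  invisible(x)
}

write_artifacts <- function(res, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  lines <- c(sprintf("rheis version: %s",
                     as.character(utils::packageVersion("rheis"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("seed: %s", config$seed %||% "none"),
             sprintf("config hash: %d",
                     stable_hash(paste(deparse(unclass(config)[
                       c("frequency", "time_h", "cutoff", "seed")]),
                       collapse = ""))),
             sprintf("qualified: %s", res$qualified))
  if (res$qualified) {
    w(res$chemical_calls, "chemical_calls.csv")
    w(res$run_calls, "run_calls.csv")
    w(res$roc, "roc.csv")
    rep <- res$report
    w(data.frame(metric = c("tp", "fp", "tn", "fn", "sensitivity",
                            "specificity", "accuracy", "auc",
                            "wlr_percent", "oecd_compliant"),
                 value = c(rep$tp, rep$fp, rep$tn, rep$fn, rep$sensitivity,
                           rep$specificity, rep$accuracy, rep$auc,
                           rep$wlr_percent, as.numeric(rep$oecd_compliant))),
      "report.csv")
    lines <- c(lines,
               sprintf("frequency_hz: %.6g", res$frequency_hz),
               sprintf("time_h: %g", res$time_h),
               sprintf("cutoff: %.6g", res$cutoff))
  }
  writeLines(lines, file.path(dir, "run_log.txt"))
  invisible(NULL)
}

#' Write the packaged miniature fixtures
#'
#' Generates a deterministic miniature synthetic study (4 chemicals, 2 runs,
#' 2 replicates, full time course) and copies the bundled reference result
#' tables next to it, so downstream tooling can be exercised on a small,
#' fully reproducible dataset.
#'
#' @param dir Output directory.
#' @param seed Integer seed of the miniature study.
#' @return Invisibly, a named character vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  arch <- default_archetypes()
  keep <- c("PBS", "SDS-5pct", "84-66-2", "67-63-0", "112-30-1", "629-19-6")
  mini <- study_design(archetypes = arch[arch$chemical_casrn %in% keep, ],
                       n_runs = 2, n_replicates = 2, seed = seed)
  paths <- write_study(generate_study(mini), dir)
  for (f in c("reference_capacitance_means.csv",
              "reference_capacitance_runs.csv",
              "reference_chemicals.csv")) {
    src <- system.file("extdata", f, package = "rheis", mustWork = TRUE)
    file.copy(src, file.path(dir, f), overwrite = TRUE)
    paths[[f]] <- file.path(dir, f)
  }
  invisible(paths)
}
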