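#' Per-tissue irritancy scores at the analysis frequency
#'
#' Extracts, for each tissue, the normalized capacitance at one frequency
#' and one evaluation time: the scalar score the classifier operates on.
#'
#' @param normalized Output of [normalize_study()].
#' @param frequency_hz Analysis frequency (must be a grid frequency present
#'   in the table).
#' @param time_h Evaluation time present in the table.
#' @return Data frame: `chemical_casrn`, `run`, `replicate`, `tissue_id`,
#'   `score`.
#' @export
tissue_scores <- function(normalized, frequency_hz, time_h) {
  sub <- normalized[normalized$time_h == time_h &
                      normalized$frequency_hz == frequency_hz, ]
  if (nrow(sub) == 0L) {
    stop(sprintf("no normalized data at %g Hz / %g h", frequency_hz, time_h),
         call. = FALSE)
  }
  out <- sub[, c("chemical_casrn", "run", "replicate", "tissue_id")]
  out$score <- sub$norm_capacitance
  rownames(out) <- NULL
  out[order(out$chemical_casrn, out$run, out$replicate), ]
}

#' Per-run scores: mean over a run's replicate tissues
#'
#' The classification unit of the pipeline: each chemical x run combination
#' is summarized by the mean score of its replicate tissues.
#'
#' @param tissue_scores Output of [tissue_scores()].
#' @return Data frame: `chemical_casrn`, `run`, `score` (replicate mean),
#'   `sd`, `n`.
#' @export
run_scores <- function(tissue_scores) {
  key <- interaction(tissue_scores$chemical_casrn, tissue_scores$run,
                     drop = TRUE)
  parts <- split(tissue_scores, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    ag <- aggregate_scores(p$score)
    data.frame(chemical_casrn = p$chemical_casrn[1L], run = p$run[1L],
               score = ag$mean, sd = ag$sd, n = ag$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chemical_casrn, out$run), ]
}

#' Per-chemical scores: mean of run means
#'
#' The overall score of a chemical is the mean of its run means (with the
#' between-run sample SD), mirroring how replicate tables feed the final
#' classification.
#'
#' @param run_scores Output of [run_scores()].
#' @return Data frame: `chemical_casrn`, `score` (mean of run means), `sd`,
#'   `n_runs`.
#' @export
chemical_scores <- function(run_scores) {
  parts <- split(run_scores, run_scores$chemical_casrn)
  out <- do.call(rbind, lapply(parts, function(p) {
    ag <- aggregate_scores(p$score)
    data.frame(chemical_casrn = p$chemical_casrn[1L], score = ag$mean,
               sd = ag$sd, n_runs = ag$n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chemical_casrn), ]
}

#' Attach GHS truth labels to chemical or run scores
#'
#' @param scores Data frame with a `chemical_casrn` column.
#' @param metadata Data frame with `chemical_casrn`, `ghs_label`, and
#'   optionally `role`; control rows (`role != "test"`) are dropped.
#' @return `scores` restricted to test chemicals, with a `truth` column.
#' @export
label_scores <- function(scores, metadata) {
  if (!all(c("chemical_casrn", "ghs_label") %in% names(metadata))) {
    stop("`metadata` needs columns chemical_casrn and ghs_label",
         call. = FALSE)
  }
  meta <- metadata
  if ("role" %in% names(meta)) meta <- meta[meta$role == "test", ]
  m <- match(scores$chemical_casrn, meta$chemical_casrn)
  out <- scores[!is.na(m), , drop = FALSE]
  out$truth <- meta$ghs_label[m[!is.na(m)]]
  rownames(out) <- NULL
  out
}
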