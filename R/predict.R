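#' Mean and sample standard deviation of replicate scores
#'
#' Aggregation used throughout reporting: arithmetic mean and sample SD
#' (n - 1 denominator).
#'
#' @param values Numeric vector (n >= 1; SD requires n >= 2 and is `NA`
#'   otherwise).
#' @return List with `mean`, `sd`, `n`.
#' @export
#' @examples
#' aggregate_scores(c(36.08, 25.07, 22.97)) # 28.04 +/- 7.04
aggregate_scores <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Define a prediction model
#'
#' A prediction model is a frequency, an evaluation time, and a decision
#' rule: for capacitance, a chemical is called an irritant iff its
#' normalized capacitance score is greater than or equal to the cut-off
#' (boundary counts as irritant); for MTT, iff relative viability is
#' strictly below 50%.
#'
#' @param frequency_hz Analysis frequency in Hz (capacitance rule).
#' @param time_h Evaluation time, one of 2, 24, 42.
#' @param cutoff Irritancy cut-off (> 0), capacitance rule only.
#' @param rule `"capacitance"` or `"mtt"`.
#' @return An object of class `"prediction_model"`.
#' @export
prediction_model <- function(frequency_hz = NA_real_, time_h = 42,
                             cutoff = NA_real_,
                             rule = c("capacitance", "mtt")) {
  rule <- match.arg(rule)
  stopifnot(time_h %in% c(2, 24, 42))
  if (rule == "capacitance" && (!is.na(cutoff) && cutoff <= 0)) {
    stop("`cutoff` must be > 0", call. = FALSE)
  }
  structure(list(frequency_hz = frequency_hz, time_h = time_h,
                 cutoff = cutoff, rule = rule),
            class = "prediction_model")
}

#' Classify normalized-capacitance scores
#'
#' @param score Numeric vector of normalized capacitance values.
#' @param model A capacitance-rule [prediction_model()], or a bare numeric
#'   cut-off.
#' @return Character vector, `"irritant"` or `"non-irritant"`; a score equal
#'   to the cut-off is an irritant.
#' @export
classify_capacitance <- function(score, model) {
  cutoff <- if (inherits(model, "prediction_model")) {
    if (model$rule != "capacitance") {
      stop("`model` must use the capacitance rule", call. = FALSE)
    }
    model$cutoff
  } else {
    model
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  ifelse(score >= cutoff, "irritant", "non-irritant")
}

#' Classify MTT relative viability
#'
#' Standard in vitro rule: irritant iff relative viability is strictly
#' below 50%.
#'
#' @param viability_percent Relative viability in percent (>= 0).
#' @return Character vector, `"irritant"` or `"non-irritant"`.
#' @export
classify_mtt <- function(viability_percent) {
  stopifnot(all(viability_percent >= 0))
  ifelse(viability_percent < 50, "irritant", "non-irritant")
}

check_labeled_scores <- function(scores, both_classes = TRUE) {
  if (!is.data.frame(scores) || nrow(scores) == 0L ||
      !all(c("score", "truth") %in% names(scores))) {
    stop("`scores` must be a non-empty data frame with columns score, truth",
         call. = FALSE)
  }
  if (!all(scores$truth %in% c("NC", "CAT2"))) {
    stop("`truth` must be \"NC\" or \"CAT2\"", call. = FALSE)
  }
  if (any(!is.finite(scores$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (both_classes && length(unique(scores$truth)) < 2L) {
    stop("both classes (NC and CAT2) must be present", call. = FALSE)
  }
  invisible(scores)
}

#' Confusion-matrix performance of a prediction model
#'
#' Scores labelled with in vivo GHS truth are classified with the model rule
#' and summarized as counts, sensitivity, specificity and accuracy (in
#' percent, Category 2 is the positive class), plus the OECD TG 439
#' compliance flag (sensitivity >= 80, specificity >= 70, accuracy >= 75).
#' If one class is absent the corresponding rate is `NA` (undefined), never
#' 0.
#'
#' @param scores Data frame with columns `score` and `truth`
#'   (`"NC"`/`"CAT2"`); typically one row per chemical.
#' @param model A capacitance [prediction_model()] or bare cut-off.
#' @return A [performance_report()] object.
#' @export
confusion_metrics <- function(scores, model) {
  check_labeled_scores(scores, both_classes = FALSE)
  call <- classify_capacitance(scores$score, model)
  pos <- scores$truth == "CAT2"
  performance_report(tp = sum(pos & call == "irritant"),
                     fp = sum(!pos & call == "irritant"),
                     tn = sum(!pos & call == "non-irritant"),
                     fn = sum(pos & call == "non-irritant"),
                     chemicals = if ("chemical_casrn" %in% names(scores))
                       sort(unique(scores$chemical_casrn)) else NULL)
}

#' Assemble a performance report
#'
#' @param tp,fp,tn,fn Confusion counts (Category 2 positive).
#' @param auc Optional area under the ROC curve.
#' @param wlr_percent Optional within-laboratory reproducibility in percent.
#' @param chemicals Optional sorted chemical identifiers the report covers.
#' @return An object of class `"performance_report"` with percent-scale
#'   `sensitivity`, `specificity`, `accuracy` and logical `oecd_compliant`.
#' @export
performance_report <- function(tp, fp, tn, fn, auc = NA_real_,
                               wlr_percent = NA_real_, chemicals = NULL) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  compliant <- !is.na(sens) && !is.na(spec) &&
    sens >= 80 && spec >= 70 && acc >= 75
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 auc = auc, oecd_compliant = compliant,
                 wlr_percent = wlr_percent, chemicals = chemicals),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Irritation prediction performance (CAT2 positive)\n")
  cat(sprintf("  counts: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn,
              x$fn))
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %.1f%%\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity), x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  if (!is.na(x$wlr_percent)) {
    cat(sprintf("  within-lab reproducibility %.1f%%\n", x$wlr_percent))
  }
  cat(sprintf("  OECD TG 439 compliant: %s\n",
              ifelse(x$oecd_compliant, "yes", "no")))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", x)

#' Empirical ROC curve of labelled scores
#'
#' One operating point per distinct score value (cut-off rule: irritant iff
#' score >= cut-off) plus the two degenerate endpoints (`Inf`: nothing
#' called irritant; `-Inf`: everything irritant). Sensitivity is
#' non-increasing as the cut-off increases.
#'
#' @param scores Data frame with `score` and `truth`; both classes required.
#' @return Data frame with columns `cutoff`, `sensitivity`,
#'   `one_minus_specificity` (proportions in \[0, 1\]), ordered by
#'   decreasing cut-off.
#' @export
roc_curve <- function(scores) {
  check_labeled_scores(scores)
  pos <- scores$truth == "CAT2"
  np <- sum(pos)
  nn <- sum(!pos)
  cuts <- c(Inf, sort(unique(scores$score), decreasing = TRUE), -Inf)
  sens <- vapply(cuts, function(c) sum(pos & scores$score >= c) / np,
                 numeric(1))
  fpr <- vapply(cuts, function(c) sum(!pos & scores$score >= c) / nn,
                numeric(1))
  data.frame(cutoff = cuts, sensitivity = sens,
             one_minus_specificity = fpr)
}

#' Area under the ROC curve by Mann-Whitney pair counting
#'
#' Computed directly as the mean over all (CAT2, NC) pairs of 1 if the
#' irritant scores higher, 0.5 on ties, 0 otherwise. Identical (to numerical
#' precision) to the trapezoidal area under [roc_curve()], and invariant
#' under strictly increasing transforms of the scores.
#'
#' @param scores Data frame with `score` and `truth`; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores) {
  check_labeled_scores(scores)
  sp <- scores$score[scores$truth == "CAT2"]
  sn <- scores$score[scores$truth == "NC"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Accuracy-optimal cut-off interval
#'
#' Sweeps candidate cut-offs (the distinct observed scores plus midpoints
#' between consecutive sorted scores) under the rule "irritant iff score >=
#' cut-off" and returns the full half-open interval `(lo, hi]` of cut-offs
#' achieving maximum accuracy. Because accuracy is piecewise constant
#' between observed scores, the interval endpoints are observed scores
#' (clamped to the observed score range when the optimal region is
#' unbounded). The lower endpoint `lo` is reported as the representative
#' value.
#'
#' @param scores Data frame with `score` and `truth`; both classes required.
#' @return List with `lo`, `hi`, `accuracy` (percent), `representative`
#'   (= `lo`) and `intervals`, a data frame of all maximal optimal
#'   intervals.
#' @export
optimal_cutoff <- function(scores) {
  check_labeled_scores(scores)
  s <- sort(unique(scores$score))
  # one candidate inside each half-open constancy interval (s[i], s[i+1]],
  # plus the unbounded intervals below min and above max
  cand <- c(s[1L] - 1, s[-1L], if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  cand <- sort(unique(cand))
  acc <- vapply(cand, function(c) {
    call <- scores$score >= c
    mean((scores$truth == "CAT2") == call) * 100
  }, numeric(1))
  best <- max(acc)
  opt <- abs(acc - best) < 1e-9
  # map optimal candidates back to constancy intervals over observed scores
  lower_bound <- function(c) { # open lower endpoint of the interval holding c
    below <- s[s < c]
    if (length(below) == 0L) -Inf else max(below)
  }
  upper_bound <- function(c) { # closed upper endpoint
    above <- s[s >= c]
    if (length(above) == 0L) Inf else min(above)
  }
  lo_all <- vapply(cand[opt], lower_bound, numeric(1))
  hi_all <- vapply(cand[opt], upper_bound, numeric(1))
  iv <- unique(data.frame(lo = lo_all, hi = hi_all))
  iv <- iv[order(iv$lo), , drop = FALSE]
  # merge adjacent intervals (shared endpoint) into maximal ones
  merged <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      if (iv$lo[i] <= merged$hi[nrow(merged)]) {
        merged$hi[nrow(merged)] <- max(merged$hi[nrow(merged)], iv$hi[i])
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
  }
  merged$lo[!is.finite(merged$lo)] <- min(s)
  merged$hi[!is.finite(merged$hi)] <- max(s)
  rownames(merged) <- NULL
  list(lo = merged$lo[1L], hi = merged$hi[1L], accuracy = best,
       representative = merged$lo[1L], intervals = merged)
}

#' Within-laboratory reproducibility of classification calls
#'
#' A chemical is concordant iff all of its runs yield the identical call.
#'
#' @param calls Data frame with columns `chemical_casrn`, `run`, `call`;
#'   every chemical must have the same number of runs (>= 2).
#' @return List with `percent` (100 x concordant / total), `concordant`,
#'   `total`, and `discordant` (chemical identifiers with split calls).
#' @export
within_lab_reproducibility <- function(calls) {
  need <- c("chemical_casrn", "run", "call")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    stop("`calls` needs columns chemical_casrn, run, call", call. = FALSE)
  }
  n_runs <- table(calls$chemical_casrn)
  if (length(unique(as.integer(n_runs))) != 1L || any(n_runs < 2L)) {
    bad <- names(n_runs)[n_runs != max(n_runs) | n_runs < 2L]
    stop(errorCondition(
      sprintf("chemical %s does not have the common number of runs",
              bad[1L]),
      class = "rheis_missing_runs"))
  }
  conc <- tapply(calls$call, calls$chemical_casrn,
                 function(x) length(unique(x)) == 1L)
  list(percent = 100 * sum(conc) / length(conc),
       concordant = sum(conc), total = length(conc),
       discordant = sort(names(conc)[!conc]))
}

#' Side-by-side comparison of two prediction methods
#'
#' Tabulates sensitivity, specificity, accuracy and compliance for an
#' EIS-based and an MTT-based report computed on the same chemical set,
#' with deltas (EIS minus MTT). No winner is declared programmatically.
#'
#' @param eis_report,mtt_report [performance_report()] objects.
#' @return Data frame with columns `metric`, `eis`, `mtt`, `delta`.
#' @export
compare_methods <- function(eis_report, mtt_report) {
  for (r in list(eis_report, mtt_report)) {
    if (!inherits(r, "performance_report")) {
      stop("both arguments must be performance_report objects", call. = FALSE)
    }
    if (anyNA(c(r$sensitivity, r$specificity, r$accuracy))) {
      stop(errorCondition("report is missing a metric",
                          class = "rheis_incomplete_report"))
    }
  }
  if (!is.null(eis_report$chemicals) && !is.null(mtt_report$chemicals) &&
      !identical(eis_report$chemicals, mtt_report$chemicals)) {
    stop(errorCondition(
      "reports were computed on different chemical sets",
      class = "rheis_chemical_mismatch"))
  }
  metrics <- c("sensitivity", "specificity", "accuracy")
  out <- data.frame(
    metric = c(metrics, "oecd_compliant"),
    eis = c(vapply(metrics, function(m) eis_report[[m]], numeric(1)),
            as.numeric(eis_report$oecd_compliant)),
    mtt = c(vapply(metrics, function(m) mtt_report[[m]], numeric(1)),
            as.numeric(mtt_report$oecd_compliant)))
  out$delta <- out$eis - out$mtt
  rownames(out) <- NULL
  out
}
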