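# Small builders shared across test files.

labeled <- function(cat2, nc) {
  data.frame(score = c(cat2, nc),
             truth = rep(c("CAT2", "NC"), c(length(cat2), length(nc))))
}

# Labelled per-chemical mean scores from the bundled reference results at
# one time point.
reference_mean_scores <- function(time_h) {
  m <- reference_capacitance_means()
  m <- m[m$time_h == time_h & m$role == "test", ]
  data.frame(chemical_casrn = m$chemical_casrn, score = m$mean,
             truth = m$ghs_label)
}

# Independent trapezoidal ROC-area oracle (no package code beyond the
# curve's defining rule; recomputes sens/fpr directly from scores).
trapezoid_auc <- function(scores) {
  pos <- scores$truth == "CAT2"
  cuts <- c(Inf, sort(unique(scores$score), decreasing = TRUE), -Inf)
  sens <- vapply(cuts, function(c) mean(scores$score[pos] >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(scores$score[!pos] >= c), numeric(1))
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

# Deterministic study design: every stochastic component off.
noise_free_design <- function(...) {
  study_design(noise_sd_log = 0, tissue_cv = 0, grade_cv = 0, run_cv = 0,
               ...)
}
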