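test_that("aggregation reports mean and sample SD", {
  a <- aggregate_scores(c(36.08, 25.07, 22.97))
  expect_equal(round(a$mean, 2), 28.04)
  expect_equal(round(a$sd, 2), 7.04)
  b <- aggregate_scores(c(19.89, 24.39, 16.35))
  expect_equal(round(b$mean, 2), 20.21)
  expect_equal(round(b$sd, 2), 4.03)
  expect_equal(aggregate_scores(c(5, 5, 5))[c("mean", "sd")],
               list(mean = 5, sd = 0))
  expect_true(is.na(aggregate_scores(3)$sd))
  expect_error(aggregate_scores(numeric(0)), "non-empty")
})

test_that("classification rules and their boundary conventions", {
  m <- prediction_model(frequency_hz = 10^4.25, time_h = 42, cutoff = 7.5)
  expect_equal(classify_capacitance(c(33.29, 5.79, 7.5), m),
               c("irritant", "non-irritant", "irritant"))
  expect_equal(classify_mtt(c(49.9, 50, 100)),
               c("irritant", "non-irritant", "non-irritant"))
  expect_error(prediction_model(cutoff = -1), "cutoff")
  expect_error(classify_capacitance(1, prediction_model(rule = "mtt")),
               "capacitance rule")
})

test_that("confusion metrics define CAT2 as positive and flag compliance", {
  r <- confusion_metrics(labeled(cat2 = c(10, 9, 2), nc = c(1, 8, 3)), 7.5)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(2, 1, 2, 1))
  expect_equal(r$sensitivity, 100 * 2 / 3)
  expect_equal(r$specificity, 100 * 2 / 3)
  expect_equal(r$accuracy, 100 * 4 / 6)
  expect_false(r$oecd_compliant) # specificity 66.7 < 70

  # a missing class leaves the corresponding rate undefined, never 0
  only_nc <- data.frame(score = c(1, 2), truth = c("NC", "NC"))
  r2 <- confusion_metrics(only_nc, 7.5)
  expect_true(is.na(r2$sensitivity))
  expect_equal(r2$specificity, 100)
  expect_false(r2$oecd_compliant)
})

test_that("ROC curve has one vertex per distinct score plus endpoints", {
  sc <- labeled(cat2 = 10, nc = 1)
  rc <- roc_curve(sc)
  expect_equal(nrow(rc), 4) # 2 scores + 2 endpoints
  expect_true(any(rc$cutoff == 10 & rc$sensitivity == 1 &
                    rc$one_minus_specificity == 0))
  expect_equal(rc$sensitivity[rc$cutoff == Inf], 0)
  expect_equal(rc$sensitivity[rc$cutoff == -Inf], 1)

  # all-identical scores collapse to the diagonal endpoints
  flat <- roc_curve(labeled(cat2 = c(3, 3), nc = c(3, 3)))
  expect_equal(flat$sensitivity, flat$one_minus_specificity)

  # sensitivity is non-increasing in the cut-off
  set.seed(1)
  for (i in 1:20) {
    sc <- labeled(cat2 = rnorm(7, 1), nc = rnorm(9))
    rc <- roc_curve(sc)
    expect_true(all(diff(rc$sensitivity) >= 0)) # rows ordered by falling cutoff
    expect_true(all(diff(rc$one_minus_specificity) >= 0))
  }
  expect_error(roc_curve(data.frame(score = 1, truth = "NC")),
               "both classes")
})

test_that("pair-counting AUC equals the trapezoidal ROC area", {
  expect_equal(auc(labeled(cat2 = c(5, 6), nc = c(1, 2))), 1)
  expect_equal(auc(labeled(cat2 = c(1, 2, 3), nc = c(1, 2, 3))), 0.5)

  set.seed(7)
  for (i in 1:300) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    sc <- labeled(cat2 = round(rnorm(n1, 0.5), sample(0:2, 1)),
                  nc = round(rnorm(n0), sample(0:2, 1)))
    expect_equal(auc(sc), trapezoid_auc(sc), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(3)
  for (i in 1:25) {
    sc <- labeled(cat2 = rnorm(6, 1), nc = rnorm(6))
    a0 <- auc(sc)
    for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
      tr <- sc; tr$score <- f(sc$score)
      expect_equal(auc(tr), a0)
    }
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    sc <- labeled(cat2 = round(rnorm(8, 0.8), 1), nc = round(rnorm(8), 1))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = sc$truth, predictor = sc$score, levels = c("NC", "CAT2"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc(sc), ref)
  }
})

test_that("optimal cut-off returns the full best-accuracy interval", {
  sep <- optimal_cutoff(labeled(cat2 = c(3, 4), nc = c(1, 2)))
  expect_equal(sep$lo, 2)
  expect_equal(sep$hi, 3)
  expect_equal(sep$accuracy, 100)
  expect_equal(sep$representative, sep$lo)

  overlap <- optimal_cutoff(labeled(cat2 = c(1, 2, 3), nc = c(1, 2, 3)))
  expect_equal(overlap$accuracy, 50)
  expect_lte(overlap$lo, 1)
  expect_gte(overlap$hi, 3)
})

test_that("no candidate cut-off beats the optimal interval", {
  set.seed(5)
  for (i in 1:30) {
    sc <- labeled(cat2 = round(rnorm(5, 1), 1), nc = round(rnorm(5), 1))
    opt <- optimal_cutoff(sc)
    cands <- c(sc$score, sc$score - 0.05, sc$score + 0.05)
    accs <- vapply(cands, function(c) {
      100 * mean((sc$truth == "CAT2") == (sc$score >= c))
    }, numeric(1))
    expect_gte(opt$accuracy + 1e-9, max(accs))
    # interior points of the reported interval achieve the optimum
    mid <- (opt$lo + opt$hi) / 2
    expect_equal(100 * mean((sc$truth == "CAT2") == (sc$score >= mid)),
                 opt$accuracy)
  }
})

test_that("lowering the cut-off trades specificity for sensitivity", {
  set.seed(9)
  sc <- labeled(cat2 = rnorm(10, 6), nc = rnorm(10, 5))
  cuts <- sort(c(sc$score, sc$score + 0.01), decreasing = TRUE)
  sens <- spec <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    r <- confusion_metrics(sc, cuts[k])
    sens[k] <- r$sensitivity; spec[k] <- r$specificity
  }
  expect_true(all(diff(sens) >= 0)) # cut-off falling: sensitivity rises
  expect_true(all(diff(spec) <= 0))
})

test_that("within-lab reproducibility counts fully concordant chemicals", {
  calls <- data.frame(chemical_casrn = rep(c("a", "b"), each = 3),
                      run = rep(1:3, 2),
                      call = c("irritant", "irritant", "irritant",
                               "non-irritant", "non-irritant", "irritant"))
  w <- within_lab_reproducibility(calls)
  expect_equal(w$percent, 50)
  expect_equal(w$discordant, "b")

  all_same <- calls; all_same$call <- "irritant"
  expect_equal(within_lab_reproducibility(all_same)$percent, 100)

  split1 <- data.frame(chemical_casrn = "a", run = 1:2,
                       call = c("irritant", "non-irritant"))
  expect_equal(within_lab_reproducibility(split1)$percent, 0)

  # invariant under run relabelling
  relab <- calls; relab$run <- rep(c(2, 3, 1), 2)
  expect_equal(within_lab_reproducibility(relab), w)

  expect_error(within_lab_reproducibility(calls[-1, ]),
               class = "rheis_missing_runs")
})

test_that("method comparison tabulates deltas without declaring a winner", {
  eis <- performance_report(tp = 10, fp = 0, tn = 10, fn = 0)
  mtt <- performance_report(tp = 9, fp = 3, tn = 7, fn = 1)
  cmp <- compare_methods(eis, mtt)
  expect_equal(cmp$delta[match(c("sensitivity", "specificity", "accuracy"),
                               cmp$metric)], c(10, 30, 20))
  expect_equal(compare_methods(eis, eis)$delta, rep(0, 4))

  incomplete <- performance_report(tp = 0, fp = 1, tn = 1, fn = 0)
  expect_error(compare_methods(eis, incomplete),
               class = "rheis_incomplete_report")
  eis2 <- performance_report(tp = 1, fp = 0, tn = 1, fn = 0,
                             chemicals = c("a", "b"))
  mtt2 <- performance_report(tp = 1, fp = 0, tn = 1, fn = 0,
                             chemicals = c("a", "c"))
  expect_error(compare_methods(eis2, mtt2),
               class = "rheis_chemical_mismatch")
})
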