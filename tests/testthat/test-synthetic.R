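test_that("circuit impedance has the correct low/high frequency limits", {
  p <- default_circuit_params()
  z_lo <- circuit_impedance(p, 1e-6)
  expect_equal(Re(z_lo), p$r_series + p$r_sc + p$r_ve, tolerance = 1e-3)
  expect_equal(Im(z_lo), 0, tolerance = 1)
  z_hi <- circuit_impedance(p, 1e14)
  expect_equal(Re(z_hi), p$r_series, tolerance = 1e-3)
})

test_that("chemical effect perturbs only the stratum-corneum block", {
  base <- default_circuit_params()
  nc <- chemical_archetype("x", "NC", grade = 0)
  for (t in c(0, 2, 24, 42)) {
    expect_identical(apply_chemical_effect(base, nc, t), base)
  }

  lagged <- chemical_archetype("y", "CAT2", grade = 0.8, lag_h = 4,
                               rate_per_h = 0.3)
  expect_identical(apply_chemical_effect(base, lagged, 3), base)
  expect_equal(damage_level(lagged, 4), 0)
  expect_gt(damage_level(lagged, 5), 0)

  # saturation: d = 1 with k_c = 30 gives c' = 31 c and r' = 0.05 r
  sat <- apply_chemical_effect(base, lagged, 42, k_c = 30, damage = 1)
  expect_equal(sat$c_sc, 31 * base$c_sc)
  expect_equal(sat$r_sc, 0.05 * base$r_sc)
  expect_equal(sat$r_ve, base$r_ve)
  expect_equal(sat$c_ve, base$c_ve)
})

test_that("archetype invariants are enforced", {
  expect_error(chemical_archetype("x", "NC", grade = 0.3), "0.2")
  expect_error(chemical_archetype("x", "CAT2", grade = 0.3), "0.5")
  arch <- default_archetypes()
  expect_equal(nrow(arch), 22)
  expect_equal(sum(arch$ghs_label == "NC", na.rm = TRUE), 10)
  expect_equal(sum(arch$ghs_label == "CAT2", na.rm = TRUE), 10)
  delayed <- arch[arch$chemical_casrn %in% c("629-19-6", "7340-90-1"), ]
  expect_true(all(delayed$lag_h > 2))
})

test_that("generated studies have the full design grid and are reproducible", {
  d <- study_design(seed = 11)
  st <- generate_study(d)
  expect_equal(nrow(st$spectra), 22 * 9 * 4 * 25)
  expect_identical(st$spectra, generate_study(d)$spectra)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  mini <- study_design(archetypes = default_archetypes()[1:4, ],
                       n_runs = 2, n_replicates = 2, seed = 3)
  write_study(generate_study(mini), dir1)
  write_study(generate_study(mini), dir2)
  expect_identical(readLines(file.path(dir1, "spectra.csv")),
                   readLines(file.path(dir2, "spectra.csv")))

  # per-tissue substreams: adding chemicals must not reshuffle existing ones
  a <- default_archetypes()
  small <- generate_study(study_design(archetypes = a[1:3, ], seed = 5))
  full <- generate_study(study_design(archetypes = a, seed = 5))
  pick <- a$chemical_casrn[3]
  x1 <- small$spectra[small$spectra$chemical_casrn == pick, ]
  x2 <- full$spectra[full$spectra$chemical_casrn == pick, ]
  rownames(x1) <- rownames(x2) <- NULL
  expect_identical(x1, x2)
})

test_that("without noise or drift an undamaged tissue normalizes to 1", {
  d <- noise_free_design(archetypes = default_archetypes()[1, , drop = FALSE],
                         n_runs = 1, n_replicates = 1, drift_per_h = 0)
  nm <- normalize_study(generate_study(d)$spectra)
  expect_true(all(nm$norm_capacitance == 1))
})

test_that("normalized capacitance at the analysis frequency rises with grade", {
  grades <- seq(0.05, 1, by = 0.05)
  arch <- do.call(rbind, lapply(seq_along(grades), function(i) {
    chemical_archetype(sprintf("g%02d", i), NA_character_, grades[i],
                       lag_h = 0, rate_per_h = 2, role = "positive_control")
  }))
  d <- noise_free_design(archetypes = arch, n_runs = 1, n_replicates = 1)
  nm <- normalize_study(generate_study(d)$spectra)
  f <- nearest_grid_frequency(17000)
  sc <- tissue_scores(nm, f, 42)
  sc <- sc[match(sprintf("g%02d", seq_along(grades)), sc$chemical_casrn), ]
  expect_true(all(diff(sc$score) > 0))
})

test_that("positive-control spectrum peaks at the 17.8 kHz grid point", {
  d <- noise_free_design()
  st <- generate_study(d)
  nm <- normalize_study(st$spectra)
  pc <- nm[nm$chemical_casrn == "SDS-5pct" & nm$time_h == 42, ]
  f_peak <- peak_response_frequency(pc)
  grid <- canonical_grid()
  i <- which(grid == f_peak)
  expect_true(i > 1 && i < length(grid)) # interior maximum
  expect_lte(abs(i - which.min(abs(log10(grid) - 4.25))), 1)
})

test_that("delayed responders cross the cut-off between 2 h and 42 h", {
  d <- noise_free_design()
  nm <- normalize_study(generate_study(d)$spectra)
  f <- nearest_grid_frequency(17000)
  for (casrn in c("629-19-6", "7340-90-1")) {
    s2 <- chemical_scores(run_scores(tissue_scores(nm, f, 2)))
    s42 <- chemical_scores(run_scores(tissue_scores(nm, f, 42)))
    expect_lt(s2$score[s2$chemical_casrn == casrn], 1.5)
    expect_gt(s42$score[s42$chemical_casrn == casrn], 7.5)
  }
})
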