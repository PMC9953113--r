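test_that("apparent capacitance follows C = 1/(2 pi f |Z''|)", {
  # identity case: f = 1/(2 pi), |Z''| = 1 -> C = 1 F
  sp <- impedance_spectrum("t", 0, c(1 / (2 * pi), 1000),
                           z_real = c(0, 0), z_imag = c(-1, -159.155))
  cs <- capacitance_from_impedance(sp)
  expect_equal(cs$capacitance_f[1], 1)
  expect_equal(cs$capacitance_f[2], 1e-6, tolerance = 1e-6)
  expect_false(attr(cs, "normalized"))

  # sign convention of Z'' must not matter
  expect_equal(apparent_capacitance(10, 5), apparent_capacitance(10, -5))
})

test_that("capacitance of a simulated circuit matches complex arithmetic", {
  # series R + one R||C block, alpha = 1, at omega * tau = 1
  p <- circuit_params(r_series = 100, r_sc = 1000, c_sc = 1e-7,
                      cpe_alpha_sc = 1, r_ve = 0, c_ve = 1, cpe_alpha_ve = 1)
  f <- 1 / (2 * pi * 1000 * 1e-7)
  z <- circuit_impedance(p, f)
  # oracle: direct complex arithmetic on Z = Rs + Rt / (1 + j w Rt Ct)
  z_oracle <- 100 + 1000 / (1 + 2i * pi * f * 1000 * 1e-7)
  expect_equal(z, z_oracle)
  expect_equal(z, complex(real = 600, imaginary = -500))
  expect_equal(apparent_capacitance(f, Im(z)), 2e-7)
})

test_that("a zero reactance point raises a degenerate-spectrum error", {
  expect_error(apparent_capacitance(c(10, 100), c(-5, 0)),
               class = "rheis_degenerate_spectrum")
  expect_error(apparent_capacitance(c(10, 100), c(-5, 0)), "100")
})

test_that("capacitance is scale-consistent in the reactance", {
  set.seed(42)
  for (i in 1:20) {
    f <- sort(runif(8, 1, 1e6))
    z <- -runif(8, 1, 1e4)
    s <- runif(1, 0.01, 100)
    expect_equal(apparent_capacitance(f, s * z),
                 apparent_capacitance(f, z) / s)
  }
})

test_that("normalization against the tissue's own baseline", {
  grid <- c(10, 100, 1000)
  base <- impedance_spectrum("t1", 0, grid, rep(5, 3), c(-100, -50, -10))
  later <- impedance_spectrum("t1", 42, grid, rep(5, 3), c(-50, -25, -5))
  ser <- tissue_series(list(base, later))

  # identical sweep normalizes to exactly 1 everywhere
  self <- tissue_series(list(
    base, impedance_spectrum("t1", 2, grid, rep(5, 3), c(-100, -50, -10))))
  expect_true(all(normalize_capacitance(self, 2)$norm_capacitance == 1))

  # halved |Z''| doubles the capacitance ratio
  nz <- normalize_capacitance(ser, 42)
  expect_equal(nz$norm_capacitance, rep(2, 3))
  expect_true(attr(nz, "normalized"))
})

test_that("structural errors: missing baseline, mismatched grids", {
  grid <- c(10, 100, 1000)
  s42 <- impedance_spectrum("t1", 42, grid, rep(5, 3), c(-50, -25, -5))
  expect_error(tissue_series(list(s42)), class = "rheis_missing_baseline")
  s0 <- impedance_spectrum("t1", 0, c(10, 100, 2000), rep(5, 3),
                           c(-100, -50, -10))
  expect_error(tissue_series(list(s0, s42)), class = "rheis_grid_mismatch")

  df <- data.frame(tissue_id = "t1", chemical_casrn = "x", run = 1,
                   replicate = 1, time_h = 42, frequency_hz = grid,
                   z_real_ohm = 5, z_imag_ohm = c(-50, -25, -5))
  expect_error(normalize_study(df), class = "rheis_missing_baseline")
})

test_that("peak response frequency maximizes the mean, ties to lower f", {
  grid <- c(10, 100, 1000)
  one <- data.frame(frequency_hz = grid, norm_capacitance = c(1, 3, 1))
  expect_equal(peak_response_frequency(one), 100)
  two <- rbind(one,
               data.frame(frequency_hz = grid, norm_capacitance = c(1, 4, 1)))
  expect_equal(peak_response_frequency(two), 100)
  flat <- data.frame(frequency_hz = grid, norm_capacitance = rep(1, 3))
  expect_equal(peak_response_frequency(flat), 10)
  # invariant under a common positive rescaling
  scaled <- two
  scaled$norm_capacitance <- scaled$norm_capacitance * 17.3
  expect_equal(peak_response_frequency(scaled), peak_response_frequency(two))
  expect_error(peak_response_frequency(one[0, ]), "non-empty")
})

test_that("nearest grid frequency works on the log scale", {
  grid <- canonical_grid()
  expect_length(grid, 25)
  expect_equal(range(grid), c(1, 1e6))
  # "17 kHz" resolves to 10^4.25 (enumerated: closest log distance)
  oracle <- grid[which.min(abs(log10(grid) - log10(17000)))]
  expect_equal(nearest_grid_frequency(17000), oracle)
  expect_equal(oracle, 10^4.25)
  expect_equal(nearest_grid_frequency(grid[7]), grid[7])
  expect_equal(nearest_grid_frequency(1), 1)
  expect_error(nearest_grid_frequency(-3), "> 0")
})

test_that("single-block apparent capacitance decreases to the membrane C", {
  # closed form for series R + R||C (alpha = 1):
  # C_app(w) = C + 1/(w^2 R^2 C), strictly decreasing, -> C as f -> Inf
  R <- 1000; C <- 1e-7
  p <- circuit_params(r_series = 100, r_sc = R, c_sc = C, cpe_alpha_sc = 1,
                      r_ve = 0, c_ve = 1, cpe_alpha_ve = 1)
  f <- canonical_grid()
  capp <- apparent_capacitance(f, Im(circuit_impedance(p, f)))
  w <- 2 * pi * f
  expect_equal(capp, C + 1 / (w^2 * R^2 * C))
  expect_true(all(diff(capp) < 0))
  expect_equal(apparent_capacitance(1e9, Im(circuit_impedance(p, 1e9))),
               C, tolerance = 1e-6)
})
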