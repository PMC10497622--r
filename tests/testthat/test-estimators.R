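test_that("chord rates are p/t and demand t > 0", {
  t50 <- time_to_product(kp_unit, 0.35, 0.175)
  r <- chord_rate(measurements(0.35, t50, 0.175))
  expect_equal(r$v_hat, 0.175 / t50)
  expect_equal(r$v_hat, 0.20159, tolerance = 1e-4)
  t60 <- time_to_product(kp_unit, 0.35, 0.21)
  expect_equal(chord_rate(measurements(0.35, t60, 0.21))$v_hat, 0.18645,
               tolerance = 1e-4)
  expect_equal(chord_rate(data.frame(s0 = 1, t = 2, p = 0))$v_hat, 0)
  expect_error(chord_rate(data.frame(s0 = 1, t = 0, p = 0)), "t = 0")
})

test_that("regression rates recover exact lines and match endpoint chords", {
  t <- 1:5
  r <- regression_rates(t, 0.3 * t)
  expect_equal(r$v1, 0.3, tolerance = 1e-12)
  expect_equal(r$v2, 0.3, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  # two points: ordinary slope is the chord between them
  r2 <- regression_rates(c(1, 2), c(0.4, 0.7))
  expect_equal(r2$v2, 0.3, tolerance = 1e-12)
  expect_error(regression_rates(c(2, 2), c(0.1, 0.2)), "singular")
  # early window of a progress curve: v1 within 5% of the true initial rate
  tt <- seq(0.001, 1, length.out = 50) * time_to_product(kp_unit, 0.7, 0.07)
  pp <- product_at_time(kp_unit, 0.7, tt)
  expect_equal(regression_rates(tt, pp)$v1, initial_rate(kp_unit, 0.7),
               tolerance = 0.05)
})

test_that("both rate fits recover exact hyperbolic data", {
  g <- default_s0_grid()
  v <- initial_rate(kp_unit, g)
  hw <- fit_hanes_woolf(g, v)
  hyp <- fit_hyperbolic(g, v)
  expect_equal(c(hw$V, hw$Km), c(1, 1), tolerance = 1e-9)
  expect_equal(c(hyp$V, hyp$Km), c(1, 1), tolerance = 1e-6)
  expect_error(fit_hanes_woolf(c(1, 2), c(0.5, 0.6)), ">= 3 distinct")
  expect_error(fit_hanes_woolf(c(1, 2, 3), c(0.5, -1, 0.6)), "positive")
})

test_that("apparent parameters from chord rates reproduce the reference bias values", {
  # 3-significant-digit rate rounding emulates the hand-computed tables
  fits <- lapply(c(0.1, 0.5, 0.7), function(f)
    fit_hanes_woolf(chord_rate(ct_dataset(f)$measurements, round_signif = 3)))
  expect_equal(fits[[1]]$V, 1.017, tolerance = 0.005)
  expect_equal(fits[[1]]$Km, 1.074, tolerance = 0.005)
  expect_equal(fits[[2]]$V, 1.124, tolerance = 0.005)
  expect_equal(fits[[2]]$Km, 1.562, tolerance = 0.005)
  expect_equal(fits[[3]]$V, 1.268, tolerance = 0.005)
  expect_equal(fits[[3]]$Km, 2.210, tolerance = 0.005)
  hyp <- fit_hyperbolic(chord_rate(ct_dataset(0.7)$measurements,
                                   round_signif = 3))
  expect_equal(hyp$V, 1.233, tolerance = 0.005)
  expect_equal(hyp$Km, 2.097, tolerance = 0.01)
})

test_that("hyperbolic and Hanes-Woolf stay within 5% of each other up to 70% conversion", {
  for (f in c(0.1, 0.4, 0.7)) {
    r <- chord_rate(ct_dataset(f)$measurements)
    hw <- fit_hanes_woolf(r)
    hyp <- fit_hyperbolic(r)
    expect_equal(hyp$V / hw$V, 1, tolerance = 0.05)
    expect_equal(hyp$Km / hw$Km, 1, tolerance = 0.05)
  }
})

test_that("integrated-equation regression recovers the truth on any noiseless design", {
  kp2 <- kinetic_parameters(V = 3.2, Km = 0.8)
  for (strategy in c("constant_time", "constant_conversion")) {
    for (f in c(0.1, 0.4, 0.7)) {
      d <- simulate_design(design_spec(strategy, default_s0_grid(), f, kp2))
      fit <- fit_integrated(d$measurements)
      expect_equal(fit$V, kp2$V, tolerance = 1e-3)
      expect_equal(fit$Km, kp2$Km, tolerance = 1e-3)
    }
  }
  # two exact points determine the line exactly
  m2 <- ct_dataset(0.5)$measurements[c(1, 7), ]
  fit2 <- fit_integrated(m2)
  expect_equal(c(fit2$V, fit2$Km), c(1, 1), tolerance = 1e-9)
})

test_that("integrated fit flags inconsistent data and p = 0 degeneracy", {
  # rates that rise with depletion cannot come from the irreversible model
  m <- data.frame(s0 = c(1, 1, 1), t = c(1, 2, 3), p = c(0.1, 0.35, 0.7))
  expect_error(fit_integrated(m), "non-negative slope")
  d <- ct_dataset(0.3)$measurements
  d$p[1] <- 0
  expect_warning(fit <- fit_integrated(d), "p = 0")
  expect_equal(fit$V, 1, tolerance = 1e-6)
})

test_that("single-point specificity matches the reference underestimation", {
  m10 <- measurements(0.35, time_to_product(kp_unit, 0.35, 0.035), 0.035)
  m60 <- measurements(0.35, time_to_product(kp_unit, 0.35, 0.21), 0.21)
  expect_equal(single_point_specificity(m10, params = kp_unit)$correction,
               0.71, tolerance = 0.005)
  expect_equal(single_point_specificity(m60, params = kp_unit)$correction,
               0.53, tolerance = 0.01)
  # underestimation worsens monotonically with conversion
  fr <- seq(0.05, 0.9, by = 0.05)
  corr <- vapply(fr, function(f) {
    m <- measurements(0.35, time_to_product(kp_unit, 0.35, f * 0.35), f * 0.35)
    single_point_specificity(m, params = kp_unit)$correction
  }, numeric(1))
  expect_true(all(diff(corr) < 0))
  expect_true(all(corr < 1))
})

test_that("bias table reproduces reference rows and its ordering laws", {
  bt <- bias_table(seq(0.1, 0.7, by = 0.1), round_signif = 3)
  row3 <- bt[abs(bt$f - 0.3) < 1e-9, ]
  expect_equal(row3$Km_app, 1.258, tolerance = 0.005)
  expect_equal(row3$ratio, 0.840, tolerance = 0.005)
  expect_equal(bt[abs(bt$f - 0.6) < 1e-9, ]$V_app, 1.182, tolerance = 0.005)
  # bias grows with conversion; Km is always inflated more than V
  expect_true(all(diff(bt$V_app) > 0))
  expect_true(all(diff(bt$Km_app) > 0))
  expect_true(all(diff(bt$ratio) < 0))
  expect_true(all(bt$V_app >= 1 - 1e-9))
  expect_true(all(bt$Km_app >= bt$V_app))
  # vanishing conversion: no bias
  bt0 <- bias_table(1e-6)
  expect_equal(c(bt0$V_app, bt0$Km_app), c(1, 1), tolerance = 1e-3)
})

test_that("noiseless bias is larger below Km than above Km at matched f", {
  below <- fit_hanes_woolf(chord_rate(
    ct_dataset(0.5, grid = below_km_grid())$measurements))
  above <- fit_hanes_woolf(chord_rate(
    ct_dataset(0.5, grid = above_km_grid())$measurements))
  expect_gt(below$V, above$V)
  expect_gt(below$Km, above$Km)
  expect_gt(below$V, 1)
  expect_gt(above$Km, 1)
})

test_that("bias-map inversion recovers the generating parameters", {
  sp70 <- design_spec("constant_time", target_fraction = 0.7)
  cor70 <- correct_apparent(1.268, 2.210, sp70)
  expect_equal(cor70$V, 1, tolerance = 0.01)
  expect_equal(cor70$Km, 1, tolerance = 0.02)
  sp10 <- design_spec("constant_time", target_fraction = 0.1)
  cor10 <- correct_apparent(1.017, 1.074, sp10)
  expect_equal(cor10$V, 1, tolerance = 0.01)
  expect_equal(cor10$Km, 1, tolerance = 0.02)
  # self-consistency away from unit parameters and on another grid
  kp2 <- kinetic_parameters(V = 0.6, Km = 35)
  sp <- design_spec("constant_time", default_s0_grid(scale = 29), 0.55, kp2)
  app <- fit_hanes_woolf(chord_rate(simulate_design(sp)$measurements))
  rec <- correct_apparent(app$V, app$Km, sp)
  expect_equal(rec$V, kp2$V, tolerance = 1e-4)
  expect_equal(rec$Km, kp2$Km, tolerance = 1e-4)
  # near-zero conversion the map is the identity
  sp0 <- design_spec("constant_time", target_fraction = 1e-4)
  rec0 <- correct_apparent(1.25, 2.5, sp0)
  expect_equal(rec0$V, 1.25, tolerance = 1e-3)
  expect_equal(rec0$Km, 2.5, tolerance = 1e-3)
})

test_that("consistency diagnostic compares observed and simulated inflation", {
  d <- ct_dataset(0.5)
  hw <- fit_hanes_woolf(chord_rate(d$measurements))
  int <- fit_integrated(d$measurements)
  diag <- consistency_diagnostic(hw, int, d$design)
  expect_equal(diag$ratio_Km, 1.566, tolerance = 0.005)
  expect_equal(diag$expected_ratio_Km, diag$ratio_Km, tolerance = 1e-6)
  expect_true(diag$consistent)
  # apparent parameters below the integrated ones flag a violation
  fake_hmm <- hw; fake_hmm$V <- 0.6 * int$V; fake_hmm$Km <- 0.5 * int$Km
  expect_false(consistency_diagnostic(fake_hmm, int, d$design)$consistent)
})
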