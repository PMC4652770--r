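test_that("paired fraction obeys mass action and is half at the analytic Tm", {
  dH <- -50; dS <- -140; C_T <- 200e-6
  for (mol in c("heteroduplex", "self-associating", "unimolecular")) {
    TmK <- oracle_tm_K(dH, dS, C_T, self = (mol == "self-associating"))
    if (mol == "unimolecular") TmK <- dH / (dS / 1000)
    expect_equal(fraction_duplex(TmK, dH, dS, C_T, mol), 0.5, tolerance = 1e-12)
  }
  # closed-form quadratic vs bisection on the mass-action relation
  f_pkg <- fraction_duplex(330, dH, dS, C_T, "heteroduplex")
  expect_equal(f_pkg, oracle_fraction_het(330, dH, dS, C_T), tolerance = 1e-10)
  Ka <- exp(-(dH - 330 * dS / 1000) / (RKCAL * 330))
  f_bis <- bisect_root(function(f) Ka * (1 - f)^2 * C_T / 2 - f, 0, 1)
  expect_equal(f_pkg, f_bis, tolerance = 1e-10)
  # limits and monotonicity
  expect_gt(fraction_duplex(273.15, dH, dS, C_T), 0.99)
  Ts <- seq(280, 360, by = 2)
  expect_true(all(diff(fraction_duplex(Ts, dH, dS, C_T)) < 0))
  cts <- c(5e-6, 2e-5, 1e-4, 5e-4)
  expect_true(all(diff(fraction_duplex(330, dH, dS, cts)) > 0))
  expect_error(fraction_duplex(330, dH, dS, molecularity = "heteroduplex"),
               "C_T")
})

test_that("simulated melts are reproducible and hit the analytic midpoint", {
  flat <- simulate_melt(-55, -150, 200e-6,
                        baselines = list(lower = c(0.7, 0), upper = c(0.7, 0)))
  expect_equal(diff(range(flat$signal)), 0)
  a <- simulate_melt(-55, -150, 200e-6, noise_sd = 0.003, seed = 9)
  b <- simulate_melt(-55, -150, 200e-6, noise_sd = 0.003, seed = 9)
  expect_identical(a$signal, b$signal)
  # noise-free midpoint (signal halfway between baselines) at analytic Tm
  cv <- simulate_melt(-55, -150, 200e-6,
                      baselines = list(lower = c(0.6, 0), upper = c(0.9, 0)),
                      temperature_C = seq(4, 89, by = 0.01))
  TmC <- oracle_tm_K(-55, -150, 200e-6) - 273.15
  mid_idx <- which.min(abs(cv$signal - 0.75))
  expect_lt(abs(cv$temperature_C[mid_idx] - TmC), 0.011)
})

test_that("two-state fit inverts the simulator across the parameter grid", {
  for (dH in c(-80, -55, -30)) {
    for (TmC in c(30, 55, 75)) {
      dS <- 1000 * (dH / (TmC + 273.15) + RKCAL * log(4 / 200e-6))
      cv <- simulate_melt(dH, dS, 200e-6)
      fit <- fit_melt(cv)
      expect_false(fit$no_tm)
      expect_lt(abs(fit$Tm_C - attr(cv, "truth")$Tm_C), 0.05)
      expect_lt(abs(fit$dH - dH) / abs(dH), 0.01)
    }
  }
})

test_that("featureless curves are flagged instead of yielding a Tm", {
  tc <- seq(4, 89, by = 0.5)
  flat <- melt_curve(tc, 0.6 + 0.0004 * tc, C_T = 200e-6)
  expect_true(fit_melt(flat)$no_tm)
})

test_that("Tm scatter under 1 % signal noise stays below 0.3 degrees", {
  tms <- vapply(1:100, function(s) {
    cv <- simulate_melt(-55, -150, 200e-6, noise_sd = 0.0025, seed = s)
    fit_melt(cv)$Tm_C
  }, 0)
  expect_lt(stats::sd(tms), 0.3)
})

test_that("van 't Hoff ladders invert exactly and molecularities differ by R ln4", {
  gs <- gen_melt_series(-55, -150)
  vh <- vant_hoff(gs$truth$Tm_C, gs$truth$ladder)
  expect_equal(vh$dH, -55, tolerance = 1e-6)
  expect_equal(vh$dS, -150, tolerance = 1e-6)
  expect_equal(vh$r_squared, 1, tolerance = 1e-9)
  expect_equal(vh$dG[["298.15"]], -55 - 298.15 * (-150) / 1000,
               tolerance = 1e-6)
  # same data under the self-associating convention: identical slope,
  # intercept offset by slope * log(4)
  vh_self <- vant_hoff(gs$truth$Tm_C, gs$truth$ladder, "self-associating")
  expect_equal(vh_self$slope, vh$slope, tolerance = 1e-12)
  # ln(C_T) = ln(C_T/4) + ln 4, so the intercept drops by slope * ln 4,
  # i.e. the two conventions differ by exactly R * ln(4) / dH
  expect_equal(vh_self$intercept - vh$intercept, -vh$slope * log(4),
               tolerance = 1e-12)
  expect_error(vant_hoff(c(50, 51), c(1e-4, 1e-4)), "concentrations")
  expect_error(vant_hoff(c(50, 51, 52), c(1e-4, 1.2e-4, 2e-4)), "4-fold")
})

test_that("van 't Hoff enthalpy bias under Tm noise stays below 5 %", {
  gs <- gen_melt_series(-55, -150)
  dhs <- vapply(1:100, function(s) {
    set.seed(s)
    tms <- gs$truth$Tm_C + rnorm(length(gs$truth$Tm_C), 0, 0.2)
    vant_hoff(tms, gs$truth$ladder)$dH
  }, 0)
  expect_lt(abs(mean(dhs) - (-55)) / 55, 0.05)
})

test_that("overlay diagnostic separates intra- from intermolecular melts", {
  ladder <- c(200, 100, 50, 25, 12.5, 6.75) * 1e-6
  # intermolecular: genuine bimolecular concentration dependence
  inter <- gen_melt_series(-55, -150, ladder)$curves
  res <- overlay_diagnostic(inter)
  expect_equal(res$classification, "intermolecular")
  expect_true(all(res$midpoint_shifts_C < 0))  # dilution lowers the midpoint
  # intramolecular: same unimolecular curve at every concentration
  uni <- lapply(ladder, function(ct) {
    cv <- simulate_melt(-40, -40 / 328.15 * 1000, NA, "unimolecular")
    attr(cv, "C_T") <- ct
    cv
  })
  expect_equal(overlay_diagnostic(uni)$classification, "intramolecular")
  # affine rescaling of the raw signals must not change the call
  inter_scaled <- lapply(inter, function(cv) {
    cv$signal <- 3.7 * cv$signal - 1.2
    cv
  })
  expect_equal(overlay_diagnostic(inter_scaled)$classification, "intermolecular")
  # pure noise: indeterminate
  set.seed(1)
  tc <- seq(4, 89, by = 0.5)
  noise <- lapply(ladder[1:3], function(ct)
    melt_curve(tc, rnorm(length(tc), 0.7, 0.01), C_T = ct))
  expect_equal(overlay_diagnostic(noise)$classification, "indeterminate")
})
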