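make_exp <- function(cell = 10e-6, syringe = 100e-6, n = 25, vol = 2) {
  titration_experiment(cell_conc = cell, syringe_conc = syringe,
                       injection_volumes_uL = rep(vol, n))
}

test_that("simulated heats vanish without enthalpy and after saturation", {
  exp <- make_exp()
  sim0 <- simulate_titration(exp, single_site_model(1e-7, dH = 0))
  expect_equal(sim0$heats, rep(0, 25))
  # tight binder: post-saturation injections release essentially no heat
  sim <- simulate_titration(exp, single_site_model(1e-10, dH = -50))
  expect_lt(abs(sim$heats[25]), abs(sim$heats[1]) * 1e-3)
})

test_that("heats integrate to the enthalpy balance from oracle speciation", {
  exp <- make_exp()
  model <- single_site_model(Kd = 1e-7, dH = -50)
  sim <- simulate_titration(exp, model)
  # independent path: bisection speciation + perfusion bookkeeping
  d <- exp$injection_volumes_uL / exp$cell_volume_uL
  totT <- 0; totC <- exp$cell_conc; ab_prev <- 0
  V0 <- exp$cell_volume_uL * 1e-6
  q_oracle <- numeric(25)
  for (i in 1:25) {
    totT_new <- totT * exp(-d[i]) + exp$syringe_conc * (1 - exp(-d[i]))
    totC_new <- totC * exp(-d[i])
    ab <- oracle_two_strand_AB(totT_new, totC_new, 1 / model$Kd)
    dV <- exp$injection_volumes_uL[i] * 1e-6
    q_oracle[i] <- model$dH * (V0 * (ab - ab_prev) + dV * (ab + ab_prev) / 2) * 1e9
    totT <- totT_new; totC <- totC_new; ab_prev <- ab
  }
  expect_close(sim$heats, q_oracle, 1e-6 * max(abs(q_oracle)))
  # negligible-dilution limit: total heat equals V * dH * (final complex)
  tiny <- titration_experiment(cell_conc = 10e-6, syringe_conc = 2000e-6,
                               injection_volumes_uL = rep(0.05, 30))
  simt <- simulate_titration(tiny, model)
  sp <- attr(simt, "speciation")$species
  expect_equal(sum(simt$heats),
               unname(V0 * model$dH * sp[nrow(sp), "duplex"] * 1e9),
               tolerance = 2e-2)
})

test_that("simulation is seed-deterministic and discretization-stable", {
  exp <- make_exp()
  m <- single_site_model(1e-7, -50)
  s1 <- simulate_titration(exp, m, noise_sd = 0.2, seed = 11)
  s2 <- simulate_titration(exp, m, noise_sd = 0.2, seed = 11)
  expect_identical(s1$heats, s2$heats)
  # halving injection volumes changes the cumulative heat by < 0.1 %
  half <- make_exp(n = 50, vol = 1)
  expect_equal(sum(simulate_titration(half, m)$heats),
               sum(simulate_titration(exp, m)$heats),
               tolerance = 1e-3)
})

test_that("single-site fit recovers generating parameters and is a fixed point", {
  g <- gen_itc(single_site_model(Kd = 100e-9, dH = -50, n = 1), seed = 3)
  f <- fit_single_site(g$experiment)
  expect_equal(f$Kd, 100e-9, tolerance = 1e-6)
  expect_equal(f$dH, -50, tolerance = 1e-6)
  expect_equal(f$n, 1, tolerance = 1e-6)
  # refitting data simulated from the fitted parameters reproduces them
  g2 <- gen_itc(single_site_model(f$Kd, f$dH, f$n), seed = 3)
  f2 <- fit_single_site(g2$experiment)
  expect_equal(f2$Kd, f$Kd, tolerance = 1e-6)
  expect_equal(f2$dH, f$dH, tolerance = 1e-6)
})

test_that("all-zero heats yield a flagged, unidentifiable fit", {
  exp <- make_exp()
  exp$heats <- rep(0, 25)
  f <- fit_single_site(exp)
  expect_equal(f$dH, 0)
  expect_true("kd-unidentifiable" %in% f$flags)
})

test_that("competition fit reduces to single-site at L = 0 and round-trips", {
  g <- gen_itc(single_site_model(Kd = 100e-9, dH = -50, n = 1), seed = 5)
  fss <- fit_single_site(g$experiment)
  fc <- fit_competition(g$experiment, L = 0, dH_dimer = 0)
  expect_equal(1 / fc$model$K, fss$Kd, tolerance = 1e-6)
  expect_equal(fc$model$dH_duplex, fss$dH, tolerance = 1e-6)

  m <- competition_model(K = 1e6, L = 1.54e5, dH_duplex = -60, dH_dimer = -67.6)
  g2 <- gen_itc(m, seed = 6)
  f2 <- fit_competition(g2$experiment, L = m$L, dH_dimer = m$dH_dimer)
  expect_equal(f2$model$K, m$K, tolerance = 1e-4)
  expect_equal(f2$model$dH_duplex, m$dH_duplex, tolerance = 1e-4)
})

test_that("closed-form corrections match their definitions and invert exactly", {
  expect_equal(kobs_correction(1e6, 0, 1e-5), 1e6)
  expect_equal(kobs_correction(1e6, 1.538e5, 4.30e-6), 1e6 / 2.32268,
               tolerance = 1e-5)
  expect_equal(dh_obs_correction(-60, -67.6, 0, 1e-5), -60)
  # 2L[Uc] = 1.323 -> f = 0.5695
  L <- 1.323 / (2 * 4.30e-6)
  expect_equal(dh_obs_correction(-60, -67.6, L, 4.30e-6), -21.5,
               tolerance = 2e-3)
  # inversion identity across a parameter grid
  for (t in c(0.1, 0.5, 1, 2, 5)) {
    L <- t / (2 * 4.30e-6)
    dobs <- dh_obs_correction(-60, -67.6, L, 4.30e-6)
    expect_equal(dh_duplex_from_observed(dobs, -67.6, L, 4.30e-6), -60)
  }
})

test_that("correcting observed parameters recovers the generating state", {
  # construct an observed fit directly from the closed forms, then invert
  K <- 4.3e6; L <- 1.54e5; dH <- -55; dH_dimer <- -67.6
  x0 <- free_monomer(10e-6, L)
  obs <- structure(list(Kd = 1 / kobs_correction(K, L, x0),
                        dH = dh_obs_correction(dH, dH_dimer, L, x0),
                        n = 1, baseline = 0, residual_rms = 0,
                        ci = NULL, flags = character()),
                   class = "single_site_fit")
  st <- correct_observed(obs, L, dH_dimer, x0)
  expect_equal(1 / st$Kd, K, tolerance = 1e-12)
  expect_equal(st$dH, dH, tolerance = 1e-12)
  expect_equal(st$TdS, st$dH - st$dG)
  # L = 0 leaves the observed values untouched
  st0 <- correct_observed(obs, 0, dH_dimer, x0)
  expect_equal(st0$Kd, obs$Kd)
  expect_equal(st0$dH, obs$dH)
})

test_that("free monomer concentration solves the dimer mass balance", {
  expect_equal(free_monomer(1e-5, 0), 1e-5)
  x <- free_monomer(1e-5, 1 / 6.5e-6)
  expect_equal(2 * (1 / 6.5e-6) * x^2 + x, 1e-5, tolerance = 1e-12)
  expect_equal(x, 4.302953e-6, tolerance = 1e-6)
})

test_that("fitting competition data with the single-site model attenuates K", {
  # moderate dimer strength, saturating titration: the apparent constant
  # sits between the fully corrected closed form and the true K
  K <- 1e6; L <- 1.538e5
  m <- competition_model(K, L, dH_duplex = -60, dH_dimer = -67.6)
  g <- gen_itc(m, cell_conc = 10e-6, syringe_conc = 100e-6, seed = 2)
  f <- fit_single_site(g$experiment)
  x0 <- free_monomer(10e-6, L)
  expect_gt(1 / f$Kd, kobs_correction(K, L, x0) * 0.8)
  expect_lt(1 / f$Kd, K * 1.25)
  # and the fitted enthalpy is less exothermic than the duplex enthalpy
  expect_gt(f$dH, m$dH_duplex)
})
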