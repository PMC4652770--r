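#' Periodic double-well free-energy landscape
#'
#' A smooth 360-degree-periodic landscape with two Gaussian-like (von
#' Mises shaped) wells, mimicking the two glycosidic-torsion modes of a
#' pyrimidine nucleoside (anti near -160 degrees, a second minimum near
#' +50 degrees) separated by a barrier. Well 1 has depth `barrier`, well 2
#' is shallower by `delta`, both measured from the inter-well plateau.
#'
#' @param min1,min2 well positions, degrees. Defaults -160 and 50.
#' @param barrier depth of well 1 below the plateau, kcal mol^-1. Default 3.
#' @param delta how much shallower well 2 is, kcal mol^-1. Default 1.
#' @param width angular width parameter of the wells (dimensionless, larger
#'   means narrower). Default 6.
#' @return function mapping angle (degrees, vectorized) to free energy
#'   (kcal mol^-1).
#' @export
double_well_landscape <- function(min1 = -160, min2 = 50,
                                  barrier = 3, delta = 1, width = 6) {
  force(min1); force(min2); force(barrier); force(delta); force(width)
  function(angle) {
    w1 <- exp(width * (cos((angle - min1) * pi / 180) - 1))
    w2 <- exp(width * (cos((angle - min2) * pi / 180) - 1))
    -barrier * w1 - (barrier - delta) * w2 + barrier
  }
}

# seeded Metropolis chain over a periodic 1-D energy function (kcal/mol)
.metropolis_angles <- function(energy_fn, n, T, seed, init = 0,
                               proposal_sd = 25, burn_in = 1000) {
  set.seed(seed)
  RT <- .RK * T
  total <- n + burn_in
  prop <- stats::rnorm(total, 0, proposal_sd)
  u <- stats::runif(total)
  out <- numeric(total)
  x <- init
  ex <- energy_fn(x)
  accepted <- 0L
  for (i in seq_len(total)) {
    y <- wrap_angle(x + prop[i])
    ey <- energy_fn(y)
    if (u[i] < exp((ex - ey) / RT)) { x <- y; ex <- ey; accepted <- accepted + 1L }
    out[i] <- x
  }
  list(angles = out[(burn_in + 1):total], acceptance = accepted / total)
}

#' Generate a synthetic ITC titration with known truth
#'
#' Produces a paper-scale titration (170 uL cell, ~10 uM titrand, 20-30
#' injections of ~2 uL from a ~10-fold more concentrated syringe) under
#' either the single-site or the homodimer-competition model, with seeded
#' Gaussian heat noise. The generating parameters travel with the output.
#'
#' @param model a [single_site_model()] or [competition_model()].
#' @param cell_conc,syringe_conc concentrations, M.
#' @param n_injections number of injections. Default 25.
#' @param injection_uL per-injection volume, uL. Default 2.
#' @param cell_volume_uL cell volume, uL. Default 170.
#' @param noise_sd Gaussian heat noise, ucal. Default 0.
#' @param T temperature, K.
#' @param seed integer seed.
#' @return list with `experiment` (a `titration_experiment` with heats) and
#'   `truth` (model, noise, seed).
#' @export
gen_itc <- function(model, cell_conc = 10e-6, syringe_conc = 100e-6,
                    n_injections = 25, injection_uL = 2,
                    cell_volume_uL = 170, noise_sd = 0, T = .TREF, seed = 1) {
  exp <- titration_experiment(cell_conc = cell_conc,
                              syringe_conc = syringe_conc,
                              injection_volumes_uL = rep(injection_uL, n_injections),
                              cell_volume_uL = cell_volume_uL, T = T)
  exp <- simulate_titration(exp, model, noise_sd = noise_sd, seed = seed)
  list(experiment = exp,
       truth = list(model = model, noise_sd = noise_sd, seed = seed))
}

#' Generate a melting-curve concentration ladder with known truth
#'
#' Curves over 4-89 degrees C with sloped linear baselines and seeded
#' Gaussian noise, across the standard dilution ladder
#' 200 to 6.75 uM.
#'
#' @param dH,dS transition enthalpy (kcal mol^-1) and entropy
#'   (cal mol^-1 K^-1).
#' @param ladder total strand concentrations, M.
#' @param molecularity transition molecularity tag.
#' @param baselines baseline list as in [simulate_melt()].
#' @param noise_sd Gaussian signal noise. Default 0.
#' @param seed integer seed (per-curve seeds are derived from it).
#' @param temperature_C temperature grid.
#' @return list with `curves` (list of [melt_curve()]) and `truth`
#'   (parameters plus the analytic `Tm_C` per concentration).
#' @export
gen_melt_series <- function(dH, dS,
                            ladder = c(200, 100, 50, 25, 12.5, 6.75) * 1e-6,
                            molecularity = "heteroduplex",
                            baselines = list(lower = c(0.60, 5e-4),
                                             upper = c(0.85, 8e-4)),
                            noise_sd = 0, seed = 1,
                            temperature_C = seq(4, 89, by = 0.5)) {
  molecularity <- .match_molecularity(molecularity)
  curves <- lapply(seq_along(ladder), function(i)
    simulate_melt(dH, dS, ladder[i], molecularity, baselines,
                  noise_sd = noise_sd, seed = seed + i - 1,
                  temperature_C = temperature_C))
  tm <- vapply(ladder, function(ct) .tm_of(dH, dS, ct, molecularity), 0) - 273.15
  list(curves = curves,
       truth = list(dH = dH, dS = dS, ladder = ladder, Tm_C = tm,
                    molecularity = molecularity, noise_sd = noise_sd,
                    seed = seed))
}

#' Generate noisy vicinal couplings from a two-state pucker mixture
#'
#' @param x_N true North fraction, strictly inside (0, 1).
#' @param P_N,P_S,nu_max geometry, as in [karplus_forward()].
#' @param noise_sd Gaussian coupling noise, Hz. Default 0.
#' @param seed integer seed.
#' @return list with `J` (named couplings, Hz) and `truth`.
#' @export
gen_couplings <- function(x_N, P_N = 18, P_S = 162, nu_max = 38,
                          noise_sd = 0, seed = 1) {
  stopifnot(x_N > 0, x_N < 1)
  J <- karplus_forward(x_N, P_N, P_S, nu_max)
  if (noise_sd > 0) {
    set.seed(seed)
    J <- J + stats::rnorm(length(J), 0, noise_sd)
  }
  list(J = J, truth = list(x_N = x_N, P_N = P_N, P_S = P_S,
                           nu_max = nu_max, noise_sd = noise_sd, seed = seed))
}

#' Sample an unbiased dihedral-angle series from a periodic landscape
#'
#' Seeded Metropolis sampling of the Boltzmann distribution
#' `p(angle) proportional to exp(-G(angle)/RT)` on the circle, with burn-in
#' discarded. The acceptance rate is reported in the metadata.
#'
#' @param landscape function angle (degrees) -> free energy (kcal mol^-1),
#'   360-periodic; see [double_well_landscape()].
#' @param n number of retained samples.
#' @param T temperature, K.
#' @param seed integer seed.
#' @param init chain start, degrees. Default 0.
#' @param proposal_sd Gaussian proposal width, degrees. Default 25.
#' @param burn_in discarded initial steps. Default 1000.
#' @return list with `angles` (degrees, wrapped to (-180, 180]) and `truth`
#'   (including `acceptance`).
#' @export
gen_angle_series <- function(landscape, n = 1e4, T = .TREF, seed = 1,
                             init = 0, proposal_sd = 25, burn_in = 1000) {
  stopifnot(is.function(landscape), n >= 1)
  mc <- .metropolis_angles(landscape, n, T, seed, init, proposal_sd, burn_in)
  list(angles = mc$angles,
       truth = list(T = T, seed = seed, n = n, burn_in = burn_in,
                    proposal_sd = proposal_sd, acceptance = mc$acceptance))
}

#' Generate umbrella-sampling windows over a periodic landscape
#'
#' For each restraint center, runs a seeded Metropolis chain on
#' `landscape + bias` (the same `0.5 * k * d^2` minimum-image bias used by
#' [wham_solve()]) starting at the window center, discarding burn-in. The
#' default setup — centers every 10 degrees around the full circle with
#' `k = 0.007` kcal mol^-1 deg^-2 — is the standard dihedral umbrella
#' protocol for nucleoside torsions.
#'
#' @param landscape periodic free-energy function, degrees -> kcal mol^-1.
#' @param centers restraint centers, degrees. Default `seq(0, 350, 10)`.
#' @param k force constant, kcal mol^-1 deg^-2. Default 0.007.
#' @param n_per_window retained samples per window. Default 1e4.
#' @param T temperature, K.
#' @param seed integer seed (per-window seeds are derived from it).
#' @param proposal_sd,burn_in Metropolis settings.
#' @return list with `windows` (list of [umbrella_window()]) and `truth`
#'   (including per-window acceptance rates).
#' @export
gen_umbrella <- function(landscape, centers = seq(0, 350, by = 10),
                         k = 0.007, n_per_window = 1e4, T = .TREF, seed = 1,
                         proposal_sd = 15, burn_in = 500) {
  stopifnot(is.function(landscape))
  acc <- numeric(length(centers))
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    biased <- function(a) landscape(a) + bias_energy(a, centers[i], k = k)
    mc <- .metropolis_angles(biased, n_per_window, T, seed + i - 1,
                             init = centers[i], proposal_sd = proposal_sd,
                             burn_in = burn_in)
    windows[[i]] <- umbrella_window(centers[i], k, mc$angles, T)
    acc[i] <- mc$acceptance
  }
  list(windows = windows,
       truth = list(centers = centers, k = k, T = T, seed = seed,
                    n_per_window = n_per_window, acceptance = acc))
}
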