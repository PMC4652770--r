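test_that("forward Karplus mixing is linear and orders North/South couplings", {
  jn <- karplus_forward(1)
  js <- karplus_forward(0)
  expect_equal(karplus_forward(0.5), 0.5 * (jn + js))
  # canonical North: small J(H1'H2'), large J(H3'H4'); South reversed
  expect_lt(jn[["J_H1p_H2p"]], js[["J_H1p_H2p"]])
  expect_gt(jn[["J_H3p_H4p"]], js[["J_H3p_H4p"]])
  expect_lt(jn[["J_H1p_H2p"]], jn[["J_H3p_H4p"]])
})

test_that("two-state inversion recovers populations with and without noise", {
  for (x in seq(0.1, 0.9, by = 0.1)) {
    J <- karplus_forward(x)
    expect_lt(abs(fit_two_state(J)$x_N - x), 1e-3)
  }
  expect_equal(fit_two_state(karplus_forward(0))$x_N, 0)
  expect_equal(fit_two_state(karplus_forward(1))$x_N, 1)
  # 0.2 Hz Gaussian noise: recovered within 0.05 (median over replicates)
  errs <- vapply(1:100, function(s) {
    g <- gen_couplings(0.8, noise_sd = 0.2, seed = s)
    abs(fit_two_state(pmin(pmax(g$J, 0), 12))$x_N - 0.8)
  }, 0)
  expect_lt(stats::median(errs), 0.05)
  # full mode refines geometry too
  full <- fit_two_state(karplus_forward(0.7), mode = "full")
  expect_lt(abs(full$x_N - 0.7), 0.02)
})

test_that("population free energies reproduce published values and antisymmetry", {
  expect_equal(round(population_to_dG(0.80), 2), -0.82)
  expect_equal(population_to_dG(0.5), 0)
  expect_equal(round(population_to_dG(0.54), 1), -0.1)
  expect_equal(population_to_dG(0.54), -0.095, tolerance = 1e-2)
  xs <- seq(0.05, 0.95, by = 0.05)
  expect_close(population_to_dG(xs), -population_to_dG(1 - xs), 1e-12)
  expect_error(population_to_dG(1), "strictly inside")
  expect_error(population_to_dG(0), "strictly inside")
})

test_that("pseudorotation phase is recovered from rings built on the full wheel", {
  for (P in seq(0, 342, by = 18)) {
    ph <- phase_from_coords(ring_from_pucker(P, 38))
    err <- abs(((ph$P - P + 180) %% 360) - 180)
    expect_lt(err, 2)
    expect_lt(abs(ph$nu_max - 38), 1)
  }
  # planar pentagon: phase undefined
  ang <- 2 * pi * (0:4) / 5
  flat <- cbind(cos(ang), sin(ang), 0)
  expect_error(phase_from_coords(flat), "planar")
  # z-negation flips every endocyclic torsion, advancing the phase by 180
  rg <- ring_from_pucker(18, 38)
  rgm <- rg; rgm[, 3] <- -rgm[, 3]
  expect_equal(phase_from_coords(rgm)$P,
               (phase_from_coords(rg)$P + 180) %% 360, tolerance = 1e-6)
})

test_that("glycosidic torsion matches its construction and an independent formula", {
  p1 <- c(0, 0, 0); p2 <- c(1.5, 0, 0); p3 <- c(2.1, 1.35, 0)
  p4 <- atom_with_dihedral(p1, p2, p3, -160)
  expect_equal(chi_from_coords(p1, p2, p3, p4), -160, tolerance = 1e-6)
  # rotating the base atom a full turn about the glycosidic bond axis
  # returns the same torsion (Rodrigues rotation, theta = 2 pi)
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  rodrigues <- function(v, k, th)
    v * cos(th) + c(k[2]*v[3]-k[3]*v[2], k[3]*v[1]-k[1]*v[3], k[1]*v[2]-k[2]*v[1]) *
      sin(th) + k * sum(k * v) * (1 - cos(th))
  p4_rot <- p3 + rodrigues(p4 - p3, axis, 2 * pi)
  expect_equal(chi_from_coords(p1, p2, p3, p4_rot),
               chi_from_coords(p1, p2, p3, p4), tolerance = 1e-9)
  expect_error(chi_from_coords(p1, p2, 2 * p2 - p1, 3 * p2 - 2 * p1),
               "collinear")
  set.seed(21)
  for (i in 1:1000) {
    pts <- matrix(rnorm(12), 4, 3)
    ref <- tryCatch(oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (!is.na(ref))
      expect_equal(chi_from_coords(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                   ref, tolerance = 1e-6)
  }
})

test_that("trajectory basin populations match the analytic Boltzmann ratio", {
  expect_equal(trajectory_populations(rep(18, 2000))$fractions[["North"]], 1)
  # two-state landscape with a 0.9 kcal/mol gap at 298 K; a modest barrier
  # and wide proposals keep the chain mixing between the wells
  lw <- double_well_landscape(min1 = 18, min2 = 180, barrier = 1.5, delta = 0.9)
  g <- gen_angle_series(lw, n = 1e5, seed = 13, proposal_sd = 40)
  pops <- trajectory_populations(g$angles)$fractions
  # analytic basin probabilities by numerical quadrature over each window
  grid <- seq(0.05, 359.95, by = 0.1)
  w <- exp(-lw(grid) / (RKCAL * 298.15))
  inN <- ((grid - (-30)) %% 360) <= 120
  pN <- sum(w[inN]) / sum(w)
  expect_lt(abs(pops[["North"]] - pN), 0.02)
  # population pair 0.92 / 0.71 implies a basin gap near 0.9 kcal/mol
  gap <- population_to_dG(0.92) - population_to_dG(0.71)
  expect_equal(round(abs(gap), 1), 0.9)
})

test_that("histogram free-energy profiles recover flatness, gaps and rotation", {
  set.seed(31)
  flat <- fes_from_histogram(runif(1e6, 0, 360))
  expect_lt(max(flat$free_energy, na.rm = TRUE), 0.05)
  # 92:8 two-state occupancy: gap of -RT log(92/8), printed as 1.43
  angles <- c(rep(18, 9200), rep(180, 800))
  fes <- fes_from_histogram(angles)
  gap <- fes$free_energy[fes$angle == 182.5] - fes$free_energy[fes$angle == 17.5]
  expect_equal(gap, -1.9872e-3 * 298.15 * log(800 / 9200), tolerance = 1e-9)
  expect_lt(abs(gap - 1.43), 0.05)
  # rotation of the angular origin by whole bins permutes, not changes, G
  set.seed(32)
  s <- runif(5e4, 0, 360)
  f1 <- fes_from_histogram(s, bin_width = 10)
  f2 <- fes_from_histogram((s + 40) %% 360, bin_width = 10)
  expect_equal(sort(f1$free_energy), sort(f2$free_energy), tolerance = 1e-12)
})

test_that("ring pucker and chi are read from PDB atom records", {
  rg <- ring_from_pucker(18, 38)
  # append base atoms N1 (bonded to C1') and C2 defining chi = -160
  O4p <- rg[1, ]; C1p <- rg[2, ]
  off <- c(0.4, -0.8, 1.1)                      # any non-collinear direction
  N1 <- C1p + 1.47 * off / sqrt(sum(off^2))
  C2 <- atom_with_dihedral(O4p, C1p, N1, -160, bond = 1.38, angle = 118)
  atoms <- rbind(rg, N1, C2)
  names_pdb <- c("O4'", "C1'", "C2'", "C3'", "C4'", "N1", "C2")
  pdb_path <- tempfile(fileext = ".pdb")
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    sprintf("ATOM  %5d %-4s   U A   1    %8.3f%8.3f%8.3f  1.00  0.00",
            i, names_pdb[i], atoms[i, 1], atoms[i, 2], atoms[i, 3]), "")
  writeLines(c(lines, "END"), pdb_path)
  res <- pucker_from_pdb(pdb_path)
  expect_lt(abs(res$P - 18), 2)
  expect_equal(res$chi, -160, tolerance = 1e-3)
})
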