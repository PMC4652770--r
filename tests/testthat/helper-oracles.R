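# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: plain bisection for speciation, an
# acos/sign formula for dihedrals, and direct algebra for mass-action
# fractions.

RKCAL <- 1.9872e-3   # kcal/mol/K, restated here independently of the package

bisect_root <- function(f, lo, hi, tol = 1e-15, maxit = 400) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if ((hi - lo) < tol) break
  }
  (lo + hi) / 2
}

# [AB] for simple 1:1 binding by bisection on the untransformed equation
oracle_two_strand_AB <- function(totA, totB, K) {
  if (K == 0 || totA == 0 || totB == 0) return(0)
  f <- function(ab) K * (totA - ab) * (totB - ab) - ab
  bisect_root(f, 0, min(totA, totB), tol = 1e-18 + 1e-13 * min(totA, totB))
}

# free [Uc] for the duplex/homodimer competition by bisection on the
# reduced mass balance
oracle_competition_freeUc <- function(totU, totUc, K, L) {
  if (totUc == 0) return(0)
  g <- function(x) x + 2 * L * x^2 + K * x * totU / (1 + K * x) - totUc
  bisect_root(g, 0, totUc, tol = 1e-18 + 1e-13 * totUc)
}

# dihedral via the acos formula with an explicit sign from the triple
# product (independent of the package's atan2 route)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# place a 4th atom so that the dihedral p1-p2-p3-p4 equals `target` degrees
# (z-matrix style construction; bond length 1.5, bond angle 109.5)
atom_with_dihedral <- function(p1, p2, p3, target, bond = 1.5, angle = 109.5) {
  b2 <- (p3 - p2); b2 <- b2 / sqrt(sum(b2^2))
  b1 <- (p2 - p1)
  n <- b1 - sum(b1 * b2) * b2
  n <- n / sqrt(sum(n^2))
  m <- c(b2[2]*n[3]-b2[3]*n[2], b2[3]*n[1]-b2[1]*n[3], b2[1]*n[2]-b2[2]*n[1])
  th <- angle * pi / 180; ph <- target * pi / 180
  p3 + bond * (-cos(th) * b2 + sin(th) * (cos(ph) * (-n) - sin(ph) * m))
}

# analytic paired fraction for the heteroduplex mass action, quadratic form
oracle_fraction_het <- function(T, dH, dS_cal, C_T) {
  Ka <- exp(-(dH - T * dS_cal / 1000) / (RKCAL * T))
  a <- Ka * C_T / 2
  ((2 * a + 1) - sqrt((2 * a + 1)^2 - 4 * a^2)) / (2 * a)
}

# analytic melting temperature (K) of the van 't Hoff line
oracle_tm_K <- function(dH, dS_cal, C_T, self = FALSE) {
  ka <- if (self) 1 / C_T else 4 / C_T
  dH / (dS_cal / 1000 - RKCAL * log(ka))
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |diff| = %.3g (tol %.3g)",
                              max(abs(actual - expected)), tol))
}
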