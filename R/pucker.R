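#' Wrap angles to a half-open 360-degree interval
#'
#' @param x angles, degrees.
#' @param lower lower edge of the target interval; the result lies in
#'   `(lower, lower + 360]`. Default -180.
#' @return wrapped angles, degrees.
#' @export
wrap_angle <- function(x, lower = -180) {
  lower + 360 - (lower + 360 - x) %% 360
}

# minimum-image difference a - b on the circle, in (-180, 180]
.ang_diff <- function(a, b) wrap_angle(a - b)

#' Default generalized Karplus parameter table for ribose protons
#'
#' Parameters of the electronegativity-corrected Karplus relation
#' `J(phi) = P1 cos^2(phi) + P2 cos(phi) + P3 +
#'   sum_i lambda_i (P4 + P5 cos^2(xi_i phi + P6 |lambda_i|))`
#' together with, for each vicinal ribose proton pair, the linear relation
#' `phi = A + B * nu` between the proton-proton torsion and the relevant
#' endocyclic ring torsion, and the substituent electronegativity terms
#' (`lambda`, orientation signs `xi`). The table is a plain list so an
#' alternative parameterization can be passed to [karplus_forward()] and
#' [fit_two_state()]; population round trips are independent of the
#' particular table as long as forward and inverse share it.
#'
#' @return a list with components `P` (numeric, P1..P6) and `pairs` (one
#'   entry per coupling with `A`, `B`, `nu_index`, `lambda`, `xi`).
#' @export
karplus_params <- function() {
  list(
    P = c(13.22, -0.99, 0, 0.87, -2.46, 19.9),
    pairs = list(
      J_H1p_H2p = list(A = 121.4, B = 1.03, nu_index = 1,
                       lambda = c(O4p = 1.27, N1 = 0.85, O2p = 1.26, C3p = 0.68),
                       xi = c(1, 1, -1, 1)),
      J_H2p_H3p = list(A = 2.4, B = 1.06, nu_index = 2,
                       lambda = c(O2p = 1.26, C1p = 0.68, O3p = 1.26, C4p = 0.68),
                       xi = c(1, 1, -1, -1)),
      J_H3p_H4p = list(A = -124.0, B = 1.09, nu_index = 3,
                       lambda = c(O3p = 1.26, C2p = 0.68, O4p = 1.27, C5p = 0.68),
                       xi = c(-1, 1, -1, 1))
    )
  )
}

# endocyclic torsion nu_j (degrees) of an ideal pseudorotating ring
.nu_of <- function(P, nu_max, j) nu_max * cos((P + 144 * (j - 2)) * pi / 180)

# generalized Karplus curve for one proton pair (phi in degrees)
.karplus_J <- function(phi, pair, P) {
  cphi <- cos(phi * pi / 180)
  P[1] * cphi^2 + P[2] * cphi + P[3] +
    sum(pair$lambda *
          (P[4] + P[5] * cos((pair$xi * phi + P[6] * abs(pair$lambda)) * pi / 180)^2))
}

# couplings (Hz) of a single pure geometry (P, nu_max)
.couplings_of_geometry <- function(P_deg, nu_max, params) {
  vapply(params$pairs, function(pair) {
    phi <- pair$A + pair$B * .nu_of(P_deg, nu_max, pair$nu_index)
    .karplus_J(phi, pair, params$P)
  }, 0)
}

#' Predicted vicinal ribose couplings for a two-state pucker mixture
#'
#' Observed couplings of a nucleoside exchanging rapidly between a North
#' (C3'-endo) and a South (C2'-endo) pucker are the population-weighted
#' average of the pure-state couplings:
#' `J_obs = x_N * J(North) + (1 - x_N) * J(South)`, each pure-state value
#' evaluated from the ring torsions `nu_j = nu_max * cos(P + 144 (j - 2))`
#' through the generalized electronegativity-corrected Karplus curve.
#'
#' @param x_N North-state fraction, in `[0, 1]`.
#' @param P_N,P_S pseudorotation phases of the North and South states,
#'   degrees. Defaults 18 and 162 (canonical C3'-endo / C2'-endo).
#' @param nu_max puckering amplitude, degrees. Default 38.
#' @param params Karplus table, see [karplus_params()].
#' @return named numeric vector of couplings (Hz):
#'   `J_H1p_H2p`, `J_H2p_H3p`, `J_H3p_H4p`.
#' @examples
#' karplus_forward(0.8)
#' @export
karplus_forward <- function(x_N, P_N = 18, P_S = 162, nu_max = 38,
                            params = karplus_params()) {
  stopifnot(x_N >= 0, x_N <= 1, nu_max >= 0)
  jn <- .couplings_of_geometry(P_N, nu_max, params)
  js <- .couplings_of_geometry(P_S, nu_max, params)
  x_N * jn + (1 - x_N) * js
}

#' Two-state North/South populations from observed couplings
#'
#' Weighted least-squares inversion of [karplus_forward()]. In the default
#' `"population"` mode only `x_N` is fitted with the two geometries held at
#' canonical values; `"full"` mode additionally fits `P_N`, `P_S` and
#' `nu_max` within canonical windows. A residual RMS above
#' `poor_fit_threshold` raises a `poor-two-state-fit` flag.
#'
#' @param J named numeric vector of observed couplings (Hz), names as in
#'   [karplus_forward()] output.
#' @param weights per-coupling weights (e.g. inverse variances).
#' @param mode `"population"` or `"full"`.
#' @param P_N,P_S,nu_max geometry (starting values in `"full"` mode).
#' @param params Karplus table.
#' @param poor_fit_threshold residual RMS (Hz) above which the two-state
#'   description is flagged as poor. Default 0.5.
#' @return object of class `pucker_fit`: list with `x_N`, `P_N`, `P_S`,
#'   `nu_max`, `dG_NS` (free energy of N relative to S at 298.15 K,
#'   kcal mol^-1, `NA` at the endpoints), `residual_rms`, `flags`.
#' @export
fit_two_state <- function(J, weights = NULL, mode = c("population", "full"),
                          P_N = 18, P_S = 162, nu_max = 38,
                          params = karplus_params(),
                          poor_fit_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(J) == 3)
  nm <- names(karplus_params()$pairs)
  if (!is.null(names(J))) J <- J[nm]
  if (anyNA(J)) stop("J must supply all three couplings: ",
                     paste(nm, collapse = ", "))
  if (any(J < 0 | J > 12)) stop("couplings outside the physical 0-12 Hz range")
  w <- if (is.null(weights)) rep(1, 3) else weights
  if (mode == "population") {
    jn <- .couplings_of_geometry(P_N, nu_max, params)
    js <- .couplings_of_geometry(P_S, nu_max, params)
    # linear in x_N: closed-form weighted least squares, clamped to [0, 1]
    num <- sum(w * (jn - js) * (J - js))
    den <- sum(w * (jn - js)^2)
    x <- min(max(num / den, 0), 1)
    res <- J - (x * jn + (1 - x) * js)
  } else {
    obj <- function(p) {
      pred <- karplus_forward(p[1], p[2], p[3], p[4], params)
      sum(w * (J - pred)^2)
    }
    opt <- stats::optim(c(0.5, P_N, P_S, nu_max), obj, method = "L-BFGS-B",
                        lower = c(0, 0, 126, 30), upper = c(1, 36, 198, 46))
    x <- opt$par[1]; P_N <- opt$par[2]; P_S <- opt$par[3]; nu_max <- opt$par[4]
    res <- J - karplus_forward(x, P_N, P_S, nu_max, params)
  }
  rms <- sqrt(mean(res^2))
  flags <- if (rms > poor_fit_threshold) "poor-two-state-fit" else character()
  dG <- if (x > 0 && x < 1) population_to_dG(x) else NA_real_
  structure(list(x_N = x, P_N = P_N, P_S = P_S, nu_max = nu_max,
                 dG_NS = dG, residual_rms = rms, flags = flags),
            class = "pucker_fit")
}

#' Conformational free energy from a fractional population
#'
#' For a two-state equilibrium with fraction `x` in the state of interest,
#' `Keq = x / (1 - x)` and `dG = -R*T*log(Keq)`; negative when the state is
#' majority-populated.
#'
#' @param x fractional population, strictly inside `(0, 1)`.
#' @param T temperature, K. Default 298.15.
#' @return free energy of the state relative to its alternative,
#'   kcal mol^-1.
#' @examples
#' population_to_dG(0.80)   # approx -0.82
#' @export
population_to_dG <- function(x, T = .TREF) {
  stopifnot(is.numeric(x), T > 0)
  if (any(x <= 0 | x >= 1))
    stop("x must lie strictly inside (0, 1); a one-sided population has no finite dG")
  -.RK * T * log(x / (1 - x))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking along the central bond, a clockwise
#' rotation of the far bond relative to the near bond is positive. Result
#' in `(-180, 180]` degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return dihedral angle, degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) stop("degenerate geometry: zero central bond")
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("collinear geometry: dihedral undefined")
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# the five endocyclic torsions nu_0..nu_4 from ring coordinates ordered
# O4', C1', C2', C3', C4' (rows); nu_j is the torsion about the bond
# C(j)'-C(j+1)' in the standard numbering, nu_2 = C1'-C2'-C3'-C4'
.ring_torsions <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) == 5, ncol(coords) == 3)
  # atom order in `coords`: 1 = O4', 2 = C1', 3 = C2', 4 = C3', 5 = C4'
  idx <- list(nu0 = c(5, 1, 2, 3),   # C4'-O4'-C1'-C2'
              nu1 = c(1, 2, 3, 4),   # O4'-C1'-C2'-C3'
              nu2 = c(2, 3, 4, 5),   # C1'-C2'-C3'-C4'
              nu3 = c(3, 4, 5, 1),   # C2'-C3'-C4'-O4'
              nu4 = c(4, 5, 1, 2))   # C3'-C4'-O4'-C1'
  vapply(idx, function(i)
    dihedral_angle(coords[i[1], ], coords[i[2], ], coords[i[3], ], coords[i[4], ]), 0)
}

#' Pseudorotation phase and amplitude from ring coordinates
#'
#' Computes the five endocyclic torsions and the pseudorotation phase `P`
#' and amplitude `nu_max` in the standard (Altona-Sundaralingam) torsion
#' convention, in which pure C3'-endo sits at `P = 18` degrees and pure
#' C2'-endo at `P = 162` degrees; free-energy-landscape conventions that
#' place these minima near 30 and 180 degrees differ only by a small
#' constant offset within the same North/South windows.
#'
#' @param coords 5 x 3 numeric matrix of ring-atom coordinates, rows in the
#'   order O4', C1', C2', C3', C4'.
#' @return list with `P` (degrees, in `[0, 360)`), `nu_max` (degrees) and
#'   `nu` (the five torsions).
#' @export
phase_from_coords <- function(coords) {
  nu <- .ring_torsions(coords)
  # least-squares projection of the five torsions onto
  # nu_j = nu_max * cos(P + 144 (j - 2)); exactly the classical phase for an
  # ideal pseudorotation pattern, and well defined at P = 90/270 where the
  # textbook nu_2 / cos(P) amplitude formula is singular
  theta <- 144 * ((0:4) - 2) * pi / 180
  a <- (2 / 5) * sum(nu * cos(theta))
  b <- -(2 / 5) * sum(nu * sin(theta))
  nu_max <- sqrt(a^2 + b^2)
  if (nu_max < 1)
    stop("ring is essentially planar (amplitude < 1 degree): phase undefined")
  P <- (atan2(b, a) * 180 / pi) %% 360
  list(P = P, nu_max = nu_max, nu = nu)
}

#' Build ring coordinates with a prescribed pucker
#'
#' Constructs five ring-atom coordinates (order O4', C1', C2', C3', C4')
#' whose endocyclic torsions match the ideal pseudorotation pattern
#' `nu_j = nu_max * cos(P + 144 (j - 2))`. Atoms keep the in-plane
#' positions of a regular pentagon (1.45 Angstrom bonds); the five
#' out-of-plane displacements are solved by Gauss-Newton refinement against
#' the target torsions. Used to exercise [phase_from_coords()] over the
#' full phase wheel.
#'
#' @param P target pseudorotation phase, degrees.
#' @param nu_max target amplitude, degrees. Default 38.
#' @return 5 x 3 coordinate matrix.
#' @export
ring_from_pucker <- function(P, nu_max = 38) {
  r <- 1.45 / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  xy <- cbind(r * cos(ang), r * sin(ang))
  target <- .nu_of(P, nu_max, 0:4)
  tor_of_z <- function(z) .ring_torsions(cbind(xy, z))
  # The z-only torsion Jacobian is rank 2 (pucker amplitude and phase);
  # uniform z-shift and the two tilts are exact null directions, so all
  # steps use the Moore-Penrose pseudo-inverse.
  pinv_step <- function(Jm, f) {
    sv <- svd(Jm)
    keep <- sv$d > 1e-8 * sv$d[1]
    sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% f) / sv$d[keep])
  }
  num_jac <- function(z, f0) {
    h <- 1e-6
    Jm <- matrix(0, 5, 5)
    for (j in 1:5) {
      zp <- z; zp[j] <- zp[j] + h
      Jm[, j] <- (tor_of_z(zp) - f0) / h
    }
    Jm
  }
  z <- as.numeric(pinv_step(num_jac(numeric(5), numeric(5)), target))
  for (iter in 1:60) {
    tz <- tor_of_z(z)
    f <- tz - target
    step <- as.numeric(pinv_step(num_jac(z, tz), f))
    z <- z - pmin(pmax(step, -0.5), 0.5)
    if (max(abs(step)) < 1e-10) break
  }
  cbind(xy, z)
}

#' Glycosidic torsion angle from coordinates
#'
#' The chi angle O4'-C1'-N1-C2 (pyrimidine numbering) describing rotation
#' of the base about the glycosidic bond; `chi` near -160 degrees is the
#' anti orientation typical of structured RNA. For purines pass the
#' corresponding O4'-C1'-N9-C4 atoms.
#'
#' @param O4p,C1p,N1,C2 length-3 coordinate vectors.
#' @return signed torsion, degrees in `(-180, 180]`.
#' @export
chi_from_coords <- function(O4p, C1p, N1, C2) {
  dihedral_angle(O4p, C1p, N1, C2)
}

#' Default angular basins for pucker and glycosidic populations
#'
#' North/South pseudorotation windows and the two glycosidic modes (anti
#' near -160 degrees, plus near +50 degrees). Basin membership is decided
#' on the circle, so window edges may be given outside `[0, 360)`.
#'
#' @param which `"pucker"` or `"chi"`.
#' @return named list of `c(lower, upper)` windows, degrees.
#' @export
default_basins <- function(which = c("pucker", "chi")) {
  which <- match.arg(which)
  if (which == "pucker")
    list(North = c(-30, 90), South = c(90, 270))
  else
    list(anti = c(-240, -100), plus = c(-10, 110))  # anti centered on -160
}

# membership of angles (degrees) in a circular window (lo, hi], lo < hi in
# unwrapped coordinates (hi - lo <= 360)
.in_basin <- function(angles, window) {
  span <- window[2] - window[1]
  stopifnot(span > 0, span <= 360)
  d <- (angles - window[1]) %% 360
  d > 0 & d <= span
}

#' Fractional basin populations of an angle trajectory
#'
#' Assigns each sample of a dihedral-angle series to named circular basins
#' and returns occupancy fractions together with a histogram. Samples
#' falling outside every basin are counted, not silently dropped.
#'
#' @param angles angle samples, degrees (any wrap).
#' @param basins named list of `c(lower, upper)` circular windows; see
#'   [default_basins()].
#' @param bin_width histogram bin width, degrees. Default 5.
#' @return list with `fractions` (named), `counts`, `n_outside`,
#'   `histogram` (data.frame `angle`, `count`).
#' @export
trajectory_populations <- function(angles, basins = default_basins("pucker"),
                                   bin_width = 5) {
  stopifnot(length(angles) >= 1)
  counts <- vapply(basins, function(w) sum(.in_basin(angles, w)), 0L)
  h <- .angle_histogram(angles, bin_width)
  list(fractions = counts / length(angles), counts = counts,
       n_outside = length(angles) - sum(counts), histogram = h)
}

.angle_histogram <- function(angles, bin_width) {
  stopifnot(360 %% bin_width == 0)
  a <- angles %% 360
  breaks <- seq(0, 360, by = bin_width)
  idx <- pmin(floor(a / bin_width) + 1, length(breaks) - 1)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(angle = breaks[-length(breaks)] + bin_width / 2, count = counts)
}

#' Free-energy profile from an unbiased angle histogram
#'
#' Boltzmann inversion of the empirical bin probabilities,
#' `G(bin) = -R*T*log(p_hat(bin))`, shifted so the occupied minimum is
#' zero. Empty bins have no defined free energy and are `NA`.
#'
#' @param angles unbiased angle samples, degrees.
#' @param T temperature, K. Default 298.15.
#' @param bin_width bin width, degrees (must divide 360). Default 5.
#' @return object of class `fes_profile`: data.frame with `angle` (bin
#'   centers, degrees), `free_energy` (kcal mol^-1) and `count`.
#' @export
fes_from_histogram <- function(angles, T = .TREF, bin_width = 5) {
  stopifnot(length(angles) >= 1, T > 0)
  h <- .angle_histogram(angles, bin_width)
  p <- h$count / sum(h$count)
  G <- ifelse(p > 0, -.RK * T * log(p), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  out <- data.frame(angle = h$angle, free_energy = G, count = h$count)
  class(out) <- c("fes_profile", "data.frame")
  attr(out, "T") <- T
  out
}

#' Sugar pucker and glycosidic torsion from a PDB file
#'
#' Reads PDB-format atom records and evaluates the pseudorotation phase,
#' amplitude and glycosidic chi angle of one nucleoside residue. Both
#' prime (`O4'`) and star (`O4*`) atom-name dialects are recognized.
#'
#' @param path PDB file path.
#' @param resno residue number to analyze; default the first residue with a
#'   complete ribose ring.
#' @param chi_atoms base atoms defining chi; default pyrimidine
#'   `c("N1", "C2")`, pass `c("N9", "C4")` for purines.
#' @return list with `P`, `nu_max`, `chi` (degrees) and `resno`.
#' @export
pucker_from_pdb <- function(path, resno = NULL, chi_atoms = c("N1", "C2")) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  norm_name <- gsub("\\*", "'", trimws(at$elety))
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  if (is.null(resno)) {
    for (rn in unique(at$resno)) {
      if (all(ring %in% norm_name[at$resno == rn])) { resno <- rn; break }
    }
    if (is.null(resno)) stop("no residue with a complete ribose ring found")
  }
  sel <- at$resno == resno
  grab <- function(nm) {
    i <- which(sel & norm_name == nm)
    if (!length(i)) stop("atom ", nm, " missing in residue ", resno)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  coords <- do.call(rbind, lapply(ring, grab))
  ph <- phase_from_coords(coords)
  chi <- tryCatch(
    chi_from_coords(grab("O4'"), grab("C1'"), grab(chi_atoms[1]), grab(chi_atoms[2])),
    error = function(e) NA_real_)
  list(P = ph$P, nu_max = ph$nu_max, chi = chi, resno = resno)
}
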