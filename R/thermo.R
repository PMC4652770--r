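#' Gibbs free energy of binding from a dissociation constant
#'
#' Evaluates `dG = R*T*log(Kd)` (kcal mol^-1). For a dissociation constant
#' below 1 M this is negative, i.e. binding is favourable at standard state.
#'
#' @param kd dissociation constant, mol L^-1 (positive).
#' @param T temperature, K. Default 298.15.
#' @return free energy change, kcal mol^-1.
#' @examples
#' free_energy_from_kd(45.2e-9)   # approx -10.0
#' @export
free_energy_from_kd <- function(kd, T = .TREF) {
  stopifnot(is.numeric(kd), is.numeric(T))
  if (any(kd <= 0)) stop("kd must be positive")
  if (any(T <= 0)) stop("T must be positive")
  .RK * T * log(kd)
}

#' Dissociation constant from a free energy of binding
#'
#' Inverse of [free_energy_from_kd()].
#'
#' @param dG free energy change, kcal mol^-1.
#' @param T temperature, K.
#' @return dissociation constant, mol L^-1.
#' @export
kd_from_free_energy <- function(dG, T = .TREF) {
  if (any(T <= 0)) stop("T must be positive")
  exp(dG / (.RK * T))
}

#' Entropic term of binding from enthalpy and free energy
#'
#' `TdS = dH - dG`, the decomposition used to report calorimetric entropies
#' alongside enthalpies at a common temperature.
#'
#' @param dH enthalpy change, kcal mol^-1.
#' @param dG free energy change, kcal mol^-1.
#' @return the product T*dS, kcal mol^-1.
#' @examples
#' entropy_term(-47.7, -10.0)   # -37.7
#' @export
entropy_term <- function(dH, dG) {
  stopifnot(is.finite(dH), is.finite(dG))
  dH - dG
}

#' Bundle of thermodynamic state functions for one equilibrium
#'
#' Holds `dG`, `dH`, `TdS` (kcal mol^-1), `Kd` (M) and `T` (K) for a single
#' binding or conformational equilibrium, filling in whatever is derivable:
#' any two of `{dG, dH, TdS}` determine the third via `dG = dH - TdS`, and
#' `dG` and `Kd` determine each other via `dG = R*T*log(Kd)`. Inconsistent
#' over-specification (beyond 1e-9 kcal mol^-1) is an error.
#'
#' @param dG,dH,TdS state functions, kcal mol^-1 (any may be `NA`).
#' @param Kd dissociation constant, M (or `NA`).
#' @param T temperature, K.
#' @return an object of class `thermo_state`: a list with the five fields.
#' @examples
#' s <- thermo_state(Kd = 45.2e-9, dH = -47.7)
#' round(s$TdS, 1)
#' @export
thermo_state <- function(dG = NA_real_, dH = NA_real_, TdS = NA_real_,
                         Kd = NA_real_, T = .TREF) {
  stopifnot(is.numeric(T), T > 0)
  if (!is.na(Kd) && Kd <= 0) stop("Kd must be positive")
  dG_kd <- if (!is.na(Kd)) free_energy_from_kd(Kd, T) else NA_real_
  if (!is.na(dG) && !is.na(dG_kd) && abs(dG - dG_kd) > 1e-9)
    stop("dG and Kd are inconsistent: dG = ", dG, ", R*T*log(Kd) = ", dG_kd)
  if (is.na(dG)) dG <- dG_kd
  # complete the triangle dG = dH - TdS
  known <- !is.na(c(dG, dH, TdS))
  if (sum(known) == 3 && abs(dG - (dH - TdS)) > 1e-9)
    stop("dG, dH, TdS violate dG = dH - TdS")
  if (is.na(dG) && !is.na(dH) && !is.na(TdS)) dG <- dH - TdS
  if (is.na(dH) && !is.na(dG) && !is.na(TdS)) dH <- dG + TdS
  if (is.na(TdS) && !is.na(dG) && !is.na(dH)) TdS <- dH - dG
  if (is.na(Kd) && !is.na(dG)) Kd <- kd_from_free_energy(dG, T)
  structure(list(dG = dG, dH = dH, TdS = TdS, Kd = Kd, T = T),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf(
    "thermo_state @ %.2f K: dG = %.3f, dH = %.3f, TdS = %.3f kcal/mol, Kd = %.3g M\n",
    x$T, x$dG, x$dH, x$TdS, x$Kd))
  invisible(x)
}

#' Differential thermodynamics of a modified versus a native equilibrium
#'
#' Computes `ddX = X_modified - X_native` for `dG`, `dH` and the entropy.
#' The entropy difference is reported in cal mol^-1 K^-1
#' (`ddS = 1000 * (TdS_mod - TdS_nat) / T`), the unit conventional for
#' nucleic acid duplex comparisons; `ddG` and `ddH` stay in kcal mol^-1.
#'
#' @param modified,native `thermo_state` objects at the same temperature.
#' @return list with `ddG`, `ddH` (kcal mol^-1) and `ddS` (cal mol^-1 K^-1).
#' @examples
#' a <- thermo_state(Kd = 21.1e-9, dH = -45.5)
#' b <- thermo_state(Kd = 45.2e-9, dH = -47.7)
#' delta_delta(a, b)
#' @export
delta_delta <- function(modified, native) {
  stopifnot(inherits(modified, "thermo_state"), inherits(native, "thermo_state"))
  if (abs(modified$T - native$T) > 1e-9)
    stop("states must share a temperature (", modified$T, " vs ", native$T, ")")
  list(ddG = modified$dG - native$dG,
       ddH = modified$dH - native$dH,
       ddS = 1000 * (modified$TdS - native$TdS) / native$T)
}

#' Competition model for duplex formation against a homodimer
#'
#' Parameter container for the coupled equilibria
#' `1/2 [Uc:Uc] <-> [Uc] <-> [U:Uc]`: a target strand U binds its partner
#' Uc with association constant `K` while Uc also self-associates into a
#' homodimer with association constant `L = [Uc:Uc]/[Uc]^2`. Enthalpies are
#' per mole of complex formed.
#'
#' @param K duplex association constant, M^-1 (> 0).
#' @param L dimerization association constant, M^-1 (>= 0).
#' @param dH_duplex duplex formation enthalpy, kcal mol^-1.
#' @param dH_dimer homodimer formation enthalpy, kcal mol^-1.
#' @return object of class `competition_model`.
#' @export
competition_model <- function(K, L = 0, dH_duplex = 0, dH_dimer = 0) {
  stopifnot(is.finite(K), is.finite(L), is.finite(dH_duplex), is.finite(dH_dimer))
  if (K <= 0) stop("K must be positive")
  if (L < 0) stop("L must be non-negative")
  structure(list(K = K, L = L, dH_duplex = dH_duplex, dH_dimer = dH_dimer),
            class = "competition_model")
}

.speciation <- function(totals, free, complexes) {
  structure(list(totals = totals, free = free, complexes = complexes),
            class = "speciation_state")
}

#' Equilibrium speciation for simple 1:1 binding
#'
#' Solves `K = [AB]/([A][B])` with mass balances `totA = [A] + [AB]`,
#' `totB = [B] + [AB]`. The complex concentration is the physical root of
#' the quadratic, evaluated in a cancellation-safe form.
#'
#' @param totA,totB total strand concentrations, M.
#' @param K association constant, M^-1 (>= 0).
#' @return a `speciation_state`: lists `totals`, `free` (A, B) and
#'   `complexes` (AB), all in M.
#' @examples
#' solve_two_strand(1e-5, 1e-5, 1e7)$complexes$AB
#' @export
solve_two_strand <- function(totA, totB, K) {
  stopifnot(totA >= 0, totB >= 0, K >= 0)
  if (K == 0 || totA == 0 || totB == 0) {
    AB <- 0
  } else {
    # K*(totA-AB)*(totB-AB) = AB  ->  K*AB^2 - (1 + K*(totA+totB))*AB + K*totA*totB = 0
    b <- 1 + K * (totA + totB)
    disc <- b^2 - 4 * K^2 * totA * totB
    AB <- 2 * K * totA * totB / (b + sqrt(max(disc, 0)))  # smaller root, stable form
    AB <- min(AB, totA, totB)
  }
  .speciation(totals = list(A = totA, B = totB),
              free = list(A = totA - AB, B = totB - AB),
              complexes = list(AB = AB))
}

#' Equilibrium speciation under homodimer competition
#'
#' Simultaneously satisfies `K = [U:Uc]/([U][Uc])`,
#' `L = [Uc:Uc]/[Uc]^2` and the mass balances
#' `totU = [U] + [U:Uc]`, `totUc = [Uc] + 2[Uc:Uc] + [U:Uc]`.
#' Internally the system is reduced to one monotone scalar equation in the
#' free `[Uc]`, solved by safeguarded bisection/Newton (`uniroot`) to high
#' relative accuracy, so convergence is guaranteed for all valid inputs.
#'
#' @param totU,totUc total strand concentrations, M.
#' @param model a [competition_model()].
#' @return a `speciation_state` with `free` (U, Uc) and `complexes`
#'   (duplex `U.Uc`, dimer `Uc.Uc`), all in M.
#' @examples
#' m <- competition_model(K = 1e6, L = 1.54e5)
#' solve_competition(1e-5, 1e-5, m)
#' @export
solve_competition <- function(totU, totUc, model) {
  stopifnot(inherits(model, "competition_model"), totU >= 0, totUc >= 0)
  K <- model$K; L <- model$L
  if (totUc == 0) {
    return(.speciation(list(U = totU, Uc = 0),
                       list(U = totU, Uc = 0),
                       list(U.Uc = 0, Uc.Uc = 0)))
  }
  # with x = [Uc]: [U] = totU/(1+K*x); balance
  #   g(x) = x + 2*L*x^2 + K*x*totU/(1+K*x) - totUc = 0, monotone increasing
  g <- function(x) x + 2 * L * x^2 + K * x * totU / (1 + K * x) - totUc
  sol <- stats::uniroot(g, lower = 0, upper = totUc, tol = 1e-18,
                        maxiter = 2000, extendInt = "no")
  x <- sol$root
  # one Newton polish for relative accuracy near machine precision
  gp <- function(x) 1 + 4 * L * x + K * totU / (1 + K * x)^2
  for (i in 1:3) x <- max(x - g(x) / gp(x), 0)
  U <- totU / (1 + K * x)
  duplex <- K * U * x
  dimer <- L * x^2
  resU  <- if (totU > 0) abs(U + duplex - totU) / totU else 0
  resUc <- abs(x + 2 * dimer + duplex - totUc) / totUc
  if (max(resU, resUc) > 1e-8)
    stop(sprintf("competition solver failed to converge: residuals %.3g / %.3g",
                 resU, resUc))
  .speciation(list(U = totU, Uc = totUc),
              list(U = U, Uc = x),
              list(U.Uc = duplex, Uc.Uc = dimer))
}
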