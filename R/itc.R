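#' Single-site 1:1 binding model for ITC
#'
#' Parameter container for the standard single-site (Wiseman) isotherm:
#' titrant binds `n` equivalent sites on the cell species with dissociation
#' constant `Kd` and molar enthalpy `dH`.
#'
#' @param Kd dissociation constant, M (> 0).
#' @param dH binding enthalpy, kcal mol^-1.
#' @param n stoichiometry (sites per cell molecule, > 0).
#' @return object of class `single_site_model`.
#' @export
single_site_model <- function(Kd, dH, n = 1) {
  stopifnot(is.finite(Kd), Kd > 0, is.finite(dH), is.finite(n), n > 0)
  structure(list(Kd = Kd, dH = dH, n = n), class = "single_site_model")
}

#' Define an ITC titration experiment
#'
#' Describes a perfusion-cell titration: the syringe species is injected in
#' a series of small volumes into a fixed active cell volume; material
#' displaced by each injection leaves the cell at its pre-injection
#' composition. Defaults follow a small-volume calorimeter protocol
#' (170 uL cell, ~2 uL injections).
#'
#' @param cell_conc total concentration of the cell (titrand) species, M.
#' @param syringe_conc concentration of the titrant in the syringe, M.
#' @param injection_volumes_uL per-injection volumes, uL.
#' @param cell_volume_uL active cell volume, uL. Default 170.
#' @param T temperature, K.
#' @param heats optional per-injection heats, ucal (filled by
#'   [simulate_titration()] or read from file).
#' @return object of class `titration_experiment`.
#' @export
titration_experiment <- function(cell_conc, syringe_conc,
                                 injection_volumes_uL,
                                 cell_volume_uL = 170, T = .TREF,
                                 heats = NULL) {
  stopifnot(cell_conc >= 0, syringe_conc >= 0, cell_volume_uL > 0, T > 0,
            all(injection_volumes_uL > 0))
  if (!is.null(heats) && length(heats) != length(injection_volumes_uL))
    stop("heats must have one entry per injection")
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 injection_volumes_uL = as.numeric(injection_volumes_uL),
                 cell_volume_uL = cell_volume_uL, T = T, heats = heats),
            class = "titration_experiment")
}

# Per-injection total concentrations in the cell under the
# continuous-perfusion displacement convention: injected volume mixes in
# while an equal volume of instantaneous cell content overflows, giving the
# exact exponential update totX -> totX * exp(-dV/V0). The concentration
# path then depends only on cumulative injected volume, not on how it is
# discretized. Row i holds totals after injection i; the first row is the
# initial cell content.
.titration_totals <- function(exp) {
  d <- exp$injection_volumes_uL / exp$cell_volume_uL
  m <- length(d)
  totT <- numeric(m + 1)           # titrant (syringe species)
  totC <- numeric(m + 1)           # titrand (cell species)
  totC[1] <- exp$cell_conc
  for (i in seq_len(m)) {
    totT[i + 1] <- totT[i] * exp(-d[i]) + exp$syringe_conc * (1 - exp(-d[i]))
    totC[i + 1] <- totC[i] * exp(-d[i])
  }
  list(titrant = totT, titrand = totC, dfrac = d)
}

# Complex concentrations (M) for each row of totals, as a matrix with one
# column per enthalpy-carrying species.
.titration_species <- function(totT, totC, model) {
  if (inherits(model, "single_site_model")) {
    ab <- mapply(function(a, b)
      solve_two_strand(a, model$n * b, 1 / model$Kd)$complexes$AB, totT, totC)
    cbind(duplex = ab)
  } else if (inherits(model, "competition_model")) {
    sp <- mapply(function(a, b) {
      s <- solve_competition(a, b, model)
      c(s$complexes$U.Uc, s$complexes$Uc.Uc)
    }, totT, totC)
    cbind(duplex = sp[1, ], dimer = sp[2, ])
  } else stop("unknown binding model of class ", class(model)[1])
}

.model_dH <- function(model) {
  if (inherits(model, "single_site_model")) c(duplex = model$dH)
  else c(duplex = model$dH_duplex, dimer = model$dH_dimer)
}

#' Simulate integrated injection heats for a titration
#'
#' For each injection the cell totals are updated with the
#' continuous-perfusion displacement bookkeeping (overflow carries away cell
#' content at its instantaneous composition, so totals dilute by
#' `exp(-dV/V0)`), speciation is solved before and after, and the heat is
#' the enthalpy-weighted number of complex moles formed — the change within
#' the active volume plus the complex carried out with the overflow
#' (trapezoidal composition over the injection):
#' `q_i = sum_s dH_s * (V0 * ([s]_i - [s]_(i-1)) + dV_i * ([s]_i + [s]_(i-1))/2)`,
#' reported in ucal. The trapezoidal overflow term makes the cumulative heat
#' second-order insensitive to how the injected volume is discretized.
#' Optional Gaussian noise is seeded and reproducible.
#'
#' @param exp a [titration_experiment()].
#' @param model a [single_site_model()] or [competition_model()].
#' @param noise_sd Gaussian heat noise, ucal per injection. Default 0.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return the experiment with `heats` filled; the per-injection speciation
#'   is attached as attribute `"speciation"`.
#' @export
simulate_titration <- function(exp, model, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(exp, "titration_experiment"))
  tt <- .titration_totals(exp)
  sp <- .titration_species(tt$titrant, tt$titrand, model)
  dH <- .model_dH(model)
  V0 <- exp$cell_volume_uL * 1e-6                      # L
  m <- length(tt$dfrac)
  q <- numeric(m)
  for (i in seq_len(m)) {
    dV <- exp$injection_volumes_uL[i] * 1e-6           # L
    dmol <- V0 * (sp[i + 1, ] - sp[i, ]) + dV * (sp[i + 1, ] + sp[i, ]) / 2
    q[i] <- sum(dH[colnames(sp)] * dmol) * 1e9         # kcal -> ucal
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(m, 0, noise_sd)
  }
  exp$heats <- q
  attr(exp, "speciation") <- list(totals = tt, species = sp)
  exp
}

# residuals of a model parameterization against observed heats
.itc_residuals <- function(exp, model, baseline) {
  sim <- simulate_titration(exp, model, noise_sd = 0)
  exp$heats - (sim$heats + baseline)
}

.itc_ci <- function(fit_lm) {
  # half-widths from the local quadratic approximation at the optimum
  ci <- tryCatch({
    covm <- stats::vcov(fit_lm)
    1.96 * sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(fit_lm$par)))
  stats::setNames(ci, names(fit_lm$par))
}

#' Fit the single-site binding isotherm to ITC heats
#'
#' Least-squares fit of `(Kd, dH, n, baseline)` to the integrated injection
#' heats via multistart Levenberg-Marquardt (`Kd` is fitted on the log
#' scale). Confidence half-widths come from the local quadratic
#' approximation at the optimum. A flat isotherm (heat dynamic range below
#' three times the residual scatter) is flagged as unidentifiable rather
#' than failed.
#'
#' @param exp a `titration_experiment` with observed `heats`.
#' @param start optional named list of starting values
#'   (`Kd`, `dH`, `n`, `baseline`); defaults are heuristic.
#' @param n_starts number of multistart perturbations. Default 8.
#' @param seed seed for the multistart perturbations.
#' @param fix_n fix the stoichiometry at its starting value (default 1)
#'   instead of fitting it; appropriate when the binding stoichiometry is
#'   known and the isotherm is only partially developed.
#' @return object of class `single_site_fit`: list with `Kd`, `dH`, `n`,
#'   `baseline`, `residual_rms`, `ci` (on `log10(Kd)`, `dH`, `n`,
#'   `baseline`), `flags`, `fitted`, `residuals`.
#' @export
fit_single_site <- function(exp, start = NULL, n_starts = 8, seed = 1,
                            fix_n = FALSE) {
  stopifnot(inherits(exp, "titration_experiment"), !is.null(exp$heats))
  if (sum(abs(exp$heats) > 0) == 0) {
    return(structure(list(Kd = NA_real_, dH = 0, n = 1, baseline = 0,
                          residual_rms = 0, ci = NULL,
                          flags = "kd-unidentifiable",
                          fitted = exp$heats * 0, residuals = exp$heats * 0),
                     class = "single_site_fit"))
  }
  if (length(exp$heats) < 6) stop("need at least 6 injections to fit")
  tt <- .titration_totals(exp)
  # heuristic starts: dH from early heats at full binding, Kd near cell conc
  V0 <- exp$cell_volume_uL * 1e-6
  dmolT <- tt$titrant[2] - tt$titrant[1] * (1 - tt$dfrac[1])
  dH0 <- exp$heats[1] / (V0 * dmolT * 1e9)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -10
  s0 <- list(Kd = max(exp$cell_conc, 1e-9) / 10, dH = dH0, n = 1, baseline = 0)
  if (!is.null(start)) s0[names(start)] <- start

  resid_fn <- function(p) {
    n_val <- if (fix_n) s0$n else max(p[["n"]], 1e-6)
    model <- single_site_model(Kd = 10^p[["lKd"]], dH = p[["dH"]], n = n_val)
    .itc_residuals(exp, model, p[["baseline"]])
  }
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <-
    if (fix_n) c(lKd = log10(s0$Kd), dH = s0$dH, baseline = s0$baseline)
    else c(lKd = log10(s0$Kd), dH = s0$dH, n = s0$n, baseline = s0$baseline)
  for (j in seq_len(n_starts - 1)) {
    pert <- c(stats::runif(1, -1.5, 1.5), s0$dH * stats::runif(1, -0.4, 0.4),
              stats::runif(1, -0.4, 0.4), 0)
    starts[[j + 1]] <- starts[[1]] + if (fix_n) pert[-3] else pert
  }
  fits <- lapply(starts, function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("single-site fit failed from every start")
  dev <- vapply(fits, stats::deviance, 0)
  # lowest deviance; ties broken by proximity of log Kd to its start
  ord <- order(dev, vapply(fits, function(f)
    abs(f$par[["lKd"]] - starts[[1]][["lKd"]]), 0))
  best <- fits[[ord[1]]]
  p <- best$par
  res <- resid_fn(p)
  rms <- sqrt(mean(res^2))
  flags <- character()
  if (diff(range(exp$heats)) < 3 * max(rms, .Machine$double.eps))
    flags <- c(flags, "flat-isotherm-wide-ci")
  structure(list(Kd = 10^p[["lKd"]], dH = p[["dH"]],
                 n = if (fix_n) s0$n else p[["n"]],
                 baseline = p[["baseline"]], residual_rms = rms,
                 ci = .itc_ci(best), flags = flags,
                 fitted = exp$heats - res, residuals = res),
            class = "single_site_fit")
}

#' Fit the homodimer-competition isotherm to ITC heats
#'
#' Fits the duplex association constant `K` (log scale) and duplex enthalpy
#' under the coupled duplex/homodimer equilibria, with the dimerization
#' constant `L` and dimer enthalpy fixed from independent single-strand
#' melting analysis. Stoichiometry is fixed at 1:1, the assumption under
#' which the competition scheme is derived.
#'
#' @param exp a `titration_experiment` with observed `heats` (cell species
#'   is the self-associating strand).
#' @param L dimerization association constant, M^-1.
#' @param dH_dimer dimer formation enthalpy, kcal mol^-1.
#' @param start optional named list (`K`, `dH_duplex`, `baseline`).
#' @param n_starts,seed multistart settings as in [fit_single_site()].
#' @return object of class `competition_fit`: list with `model`
#'   (a [competition_model()]), `baseline`, `residual_rms`, `ci`, `flags`,
#'   `fitted`, `residuals`.
#' @export
fit_competition <- function(exp, L, dH_dimer, start = NULL,
                            n_starts = 8, seed = 1) {
  stopifnot(inherits(exp, "titration_experiment"), !is.null(exp$heats),
            L >= 0, is.finite(dH_dimer))
  if (length(exp$heats) < 6) stop("need at least 6 injections to fit")
  s0 <- list(K = 10 / max(exp$cell_conc, 1e-9), dH_duplex = -50, baseline = 0)
  if (!is.null(start)) s0[names(start)] <- start
  resid_fn <- function(p) {
    model <- competition_model(K = 10^p[["lK"]], L = L,
                               dH_duplex = p[["dH"]], dH_dimer = dH_dimer)
    .itc_residuals(exp, model, p[["baseline"]])
  }
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- c(lK = log10(s0$K), dH = s0$dH_duplex, baseline = s0$baseline)
  for (j in seq_len(n_starts - 1)) {
    starts[[j + 1]] <- starts[[1]] +
      c(stats::runif(1, -1.5, 1.5), stats::runif(1, -20, 20), 0)
  }
  fits <- lapply(starts, function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("competition fit failed from every start")
  dev <- vapply(fits, stats::deviance, 0)
  ord <- order(dev, vapply(fits, function(f)
    abs(f$par[["lK"]] - starts[[1]][["lK"]]), 0))
  best <- fits[[ord[1]]]
  p <- best$par
  res <- resid_fn(p)
  structure(list(model = competition_model(K = 10^p[["lK"]], L = L,
                                           dH_duplex = p[["dH"]],
                                           dH_dimer = dH_dimer),
                 baseline = p[["baseline"]],
                 residual_rms = sqrt(mean(res^2)),
                 ci = .itc_ci(best), flags = character(),
                 fitted = exp$heats - res, residuals = res),
            class = "competition_fit")
}

#' Observed association constant under homodimer competition
#'
#' Closed-form attenuation of the true duplex association constant by the
#' competing homodimer: `K_obs = K / (1 + 2*L*free_Uc)`, where `free_Uc` is
#' the free concentration of the self-associating strand.
#'
#' @param K true duplex association constant, M^-1.
#' @param L dimerization association constant, M^-1.
#' @param free_Uc free self-associating strand concentration, M.
#' @return observed association constant, M^-1.
#' @export
kobs_correction <- function(K, L, free_Uc) {
  stopifnot(K >= 0, L >= 0, free_Uc >= 0)
  K / (1 + 2 * L * free_Uc)
}

#' Observed enthalpy under homodimer competition
#'
#' Closed-form shift of the apparent binding enthalpy when each duplex
#' formed draws the partner strand out of its homodimer:
#' `dH_obs = dH_duplex - dH_dimer * f`, with
#' `f = 2*L*free_Uc / (1 + 2*L*free_Uc)` the fraction of newly bound strand
#' supplied by dimer dissociation. `free_Uc` is evaluated at the start of
#' the titration.
#'
#' @inheritParams kobs_correction
#' @param dH_duplex,dH_dimer formation enthalpies, kcal mol^-1.
#' @return observed enthalpy, kcal mol^-1.
#' @seealso [dh_duplex_from_observed()] for the inverse.
#' @export
dh_obs_correction <- function(dH_duplex, dH_dimer, L, free_Uc) {
  stopifnot(is.finite(dH_duplex), is.finite(dH_dimer), L >= 0, free_Uc >= 0)
  f <- 2 * L * free_Uc / (1 + 2 * L * free_Uc)
  dH_duplex - dH_dimer * f
}

#' Recover the true duplex enthalpy from an observed enthalpy
#'
#' Inverse of [dh_obs_correction()].
#'
#' @inheritParams dh_obs_correction
#' @param dH_obs observed (single-site-fitted) enthalpy, kcal mol^-1.
#' @return duplex formation enthalpy, kcal mol^-1.
#' @export
dh_duplex_from_observed <- function(dH_obs, dH_dimer, L, free_Uc) {
  f <- 2 * L * free_Uc / (1 + 2 * L * free_Uc)
  dH_obs + dH_dimer * f
}

#' Free concentration of a self-associating strand
#'
#' Free monomer concentration of a strand of total concentration `tot` with
#' dimerization constant `L` and no binding partner present; the positive
#' root of `2*L*x^2 + x - tot = 0`.
#'
#' @param tot total strand concentration, M.
#' @param L dimerization association constant, M^-1.
#' @return free monomer concentration, M.
#' @export
free_monomer <- function(tot, L) {
  stopifnot(tot >= 0, L >= 0)
  if (L == 0) return(tot)
  2 * tot / (1 + sqrt(1 + 8 * L * tot))   # stable form of the positive root
}

#' Correct single-site-fitted ITC parameters for homodimer competition
#'
#' Applies the inverse closed-form corrections to a single-site fit of data
#' affected by partner-strand homodimerization: the association constant is
#' rescaled by `(1 + 2*L*free_Uc)` and the enthalpy shifted by the dimer
#' dissociation contribution, then `dG` and `TdS` are recomputed.
#'
#' @param fit a `single_site_fit` (the observed parameters).
#' @param L dimerization association constant, M^-1.
#' @param dH_dimer dimer formation enthalpy, kcal mol^-1.
#' @param free_Uc free self-associating strand concentration at the start of
#'   the titration, M (see [free_monomer()]).
#' @param T temperature, K.
#' @return a [thermo_state()] holding the corrected `Kd`, `dH`, `dG`, `TdS`.
#' @export
correct_observed <- function(fit, L, dH_dimer, free_Uc, T = .TREF) {
  stopifnot(inherits(fit, "single_site_fit"))
  K_obs <- 1 / fit$Kd
  K <- K_obs * (1 + 2 * L * free_Uc)
  dH <- dh_duplex_from_observed(fit$dH, dH_dimer, L, free_Uc)
  thermo_state(Kd = 1 / K, dH = dH, T = T)
}
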