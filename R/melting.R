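.molecularities <- c("heteroduplex", "self-associating", "unimolecular")

.match_molecularity <- function(molecularity) {
  match.arg(molecularity, .molecularities)
}

# association constant at T (K) from dH (kcal/mol) and dS (cal/mol/K)
.ka_of_T <- function(T, dH, dS) exp(-(dH - T * dS / 1000) / (.RK * T))

#' Fraction of strands paired at a temperature
#'
#' Solves the two-state mass-action relation for the fraction `f` of
#' strands in the associated state given a transition enthalpy and entropy:
#' \describe{
#'   \item{heteroduplex}{`Ka = 2f / ((1-f)^2 * C_T)` (equimolar strands)}
#'   \item{self-associating}{`Ka = f / (2 (1-f)^2 * C_T)`}
#'   \item{unimolecular}{`Keq = f / (1-f)` (no `C_T` dependence)}
#' }
#' At the melting temperature defined by the van 't Hoff line, `f = 1/2`
#' (heteroduplex `Kd(Tm) = C_T/4`; self-associating `Kd(Tm) = C_T`).
#'
#' @param T temperature, K (vectorized).
#' @param dH transition enthalpy, kcal mol^-1 (negative for association).
#' @param dS transition entropy, cal mol^-1 K^-1.
#' @param C_T total strand concentration, M (required for bimolecular cases).
#' @param molecularity one of `"heteroduplex"`, `"self-associating"`,
#'   `"unimolecular"`.
#' @return fraction paired, in `[0, 1]`.
#' @export
fraction_duplex <- function(T, dH, dS, C_T = NA_real_,
                            molecularity = "heteroduplex") {
  molecularity <- .match_molecularity(molecularity)
  Ka <- .ka_of_T(T, dH, dS)
  if (molecularity == "unimolecular") return(Ka / (1 + Ka))
  if (any(!is.finite(C_T) | C_T <= 0)) stop("C_T > 0 required for bimolecular melts")
  a <- switch(molecularity,
              "heteroduplex" = Ka * C_T / 2,
              "self-associating" = 2 * Ka * C_T)
  # a*(1-f)^2 = f  ->  stable root in [0,1]
  2 * a / ((2 * a + 1) + sqrt(4 * a + 1))
}

# entropy (cal/mol/K) pinned so that f = 1/2 at Tm for the given molecularity
.ds_from_tm <- function(Tm_K, dH, C_T, molecularity) {
  ka_tm <- switch(molecularity,
                  "heteroduplex" = 4 / C_T,
                  "self-associating" = 1 / C_T,
                  "unimolecular" = 1)
  1000 * (dH / Tm_K + .RK * log(ka_tm))
}

# analytic melting temperature (K) of the van 't Hoff line
.tm_of <- function(dH, dS, C_T, molecularity) {
  ka_tm <- switch(molecularity,
                  "heteroduplex" = 4 / C_T,
                  "self-associating" = 1 / C_T,
                  "unimolecular" = 1)
  dH / (dS / 1000 - .RK * log(ka_tm))
}

#' Construct a melting curve object
#'
#' @param temperature_C temperatures, degrees C, strictly increasing.
#' @param signal absorbance or CD signal, arbitrary units.
#' @param C_T total strand concentration, M.
#' @param molecularity transition molecularity tag.
#' @return object of class `melt_curve`: a data.frame with attributes
#'   `C_T` and `molecularity`.
#' @export
melt_curve <- function(temperature_C, signal, C_T = NA_real_,
                       molecularity = "heteroduplex") {
  stopifnot(length(temperature_C) == length(signal))
  if (length(temperature_C) < 20) stop("a melt curve needs >= 20 points")
  if (any(diff(temperature_C) <= 0)) stop("temperatures must be strictly increasing")
  if (any(temperature_C < 0 | temperature_C > 100))
    stop("temperatures must lie in [0, 100] degrees C")
  out <- data.frame(temperature_C = temperature_C, signal = signal)
  attr(out, "C_T") <- C_T
  attr(out, "molecularity") <- .match_molecularity(molecularity)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Simulate a two-state melting curve with sloped baselines
#'
#' The signal interpolates between a folded (lower) and melted (upper)
#' linear baseline with the fraction single-stranded, reproducing the
#' hyperchromic rise of nucleic acid melts:
#' `signal(T) = lower(T) * f_folded + upper(T) * (1 - f_folded) + noise`.
#'
#' @param dH,dS transition enthalpy (kcal mol^-1) and entropy
#'   (cal mol^-1 K^-1).
#' @param C_T total strand concentration, M.
#' @param molecularity transition molecularity tag.
#' @param baselines list with `lower` and `upper`, each `c(intercept, slope)`
#'   in signal units and signal units per degree C.
#' @param noise_sd Gaussian signal noise sd. Default 0.
#' @param seed integer seed used when `noise_sd > 0`.
#' @param temperature_C temperature grid, degrees C.
#' @return a [melt_curve()]; the generating parameters are attached as
#'   attribute `"truth"`.
#' @export
simulate_melt <- function(dH, dS, C_T = NA_real_,
                          molecularity = "heteroduplex",
                          baselines = list(lower = c(0.60, 5e-4),
                                           upper = c(0.85, 8e-4)),
                          noise_sd = 0, seed = NULL,
                          temperature_C = seq(4, 89, by = 0.5)) {
  molecularity <- .match_molecularity(molecularity)
  TK <- temperature_C + 273.15
  f <- fraction_duplex(TK, dH, dS, C_T, molecularity)
  lower <- baselines$lower[1] + baselines$lower[2] * temperature_C
  upper <- baselines$upper[1] + baselines$upper[2] * temperature_C
  sig <- lower * f + upper * (1 - f)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  }
  out <- melt_curve(temperature_C, sig, C_T, molecularity)
  attr(out, "truth") <- list(dH = dH, dS = dS,
                             Tm_C = .tm_of(dH, dS, C_T, molecularity) - 273.15,
                             baselines = baselines, noise_sd = noise_sd)
  out
}

#' Fit a two-state model with double sloped baselines to a melting curve
#'
#' Nonlinear least squares over six parameters: `Tm`, the transition
#' enthalpy, and intercept/slope of both baselines, fitted jointly against
#' the raw curve (no pre-selected baseline windows). `Tm` is defined as the
#' temperature at which the paired fraction is 1/2 at the curve's own
#' `C_T`; the entropy is pinned to `Tm` through the mass-action relation of
#' the declared molecularity. Curves without a resolvable sigmoidal
#' transition (fitted transition amplitude below three times the residual
#' scatter, or `Tm` outside the scanned range) are flagged `no_tm` rather
#' than fitted blindly; residual structure such as premelting transitions
#' is reported through `residual_rms`, not masked.
#'
#' @param curve a [melt_curve()].
#' @return object of class `melt_fit`: list with `Tm_C`, `dH`, `dS`,
#'   `lower_baseline`, `upper_baseline` (each `c(intercept, slope)`),
#'   `residual_rms`, `no_tm`, `flags`, `fitted`.
#' @export
fit_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  Tc <- curve$temperature_C
  y <- curve$signal
  C_T <- attr(curve, "C_T")
  molecularity <- attr(curve, "molecularity")
  n <- length(Tc)
  lo_idx <- seq_len(max(4, floor(0.15 * n)))
  hi_idx <- seq(n - max(4, floor(0.15 * n)) + 1, n)
  cl <- stats::coef(stats::lm(y[lo_idx] ~ Tc[lo_idx]))
  cu <- stats::coef(stats::lm(y[hi_idx] ~ Tc[hi_idx]))
  # crude Tm start: steepest point of the smoothed curve
  dy <- diff(stats::filter(y, rep(1 / 5, 5), sides = 2)[c(-1, -n)])
  Tm0 <- Tc[which.max(abs(dy)) + 1]
  p0 <- c(Tm = Tm0, dH = -50, bl0 = cl[[1]], bl1 = cl[[2]],
          bu0 = cu[[1]], bu1 = cu[[2]])
  model_signal <- function(p) {
    dS <- .ds_from_tm(p[["Tm"]] + 273.15, p[["dH"]], C_T, molecularity)
    f <- fraction_duplex(Tc + 273.15, p[["dH"]], dS, C_T, molecularity)
    lower <- p[["bl0"]] + p[["bl1"]] * Tc
    upper <- p[["bu0"]] + p[["bu1"]] * Tc
    lower * f + upper * (1 - f)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) y - model_signal(p),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  no_tm <- FALSE
  flags <- character()
  if (is.null(fit)) {
    no_tm <- TRUE
    p <- p0
    res <- y - model_signal(p0)
  } else {
    p <- fit$par
    res <- y - model_signal(p)
    rms <- sqrt(mean(res^2))
    amp <- abs((p[["bu0"]] + p[["bu1"]] * p[["Tm"]]) -
               (p[["bl0"]] + p[["bl1"]] * p[["Tm"]]))
    if (amp < 3 * max(rms, .Machine$double.eps) ||
        p[["Tm"]] < min(Tc) || p[["Tm"]] > max(Tc))
      no_tm <- TRUE
    if ((p[["bl0"]] + p[["bl1"]] * p[["Tm"]]) >
        (p[["bu0"]] + p[["bu1"]] * p[["Tm"]]))
      flags <- c(flags, "inverted-baselines")
  }
  dS <- .ds_from_tm(p[["Tm"]] + 273.15, p[["dH"]], C_T, molecularity)
  structure(list(Tm_C = if (no_tm) NA_real_ else p[["Tm"]],
                 dH = if (no_tm) NA_real_ else p[["dH"]],
                 dS = if (no_tm) NA_real_ else dS,
                 lower_baseline = c(intercept = p[["bl0"]], slope = p[["bl1"]]),
                 upper_baseline = c(intercept = p[["bu0"]], slope = p[["bu1"]]),
                 residual_rms = sqrt(mean(res^2)),
                 no_tm = no_tm, flags = flags,
                 fitted = y - res),
            class = "melt_fit")
}

#' Concentration-series van 't Hoff analysis of melting temperatures
#'
#' Ordinary least squares of `1/Tm` (K^-1) on `ln(C_T/4)` — or `ln(C_T)`
#' for a self-associating strand — following
#' `1/Tm = (R/dH) * ln(C_T/4) + dS/dH`. The transition enthalpy is `R`
#' divided by the slope and the entropy is `dH * intercept`.
#'
#' @param Tm_C melting temperatures, degrees C.
#' @param C_T total strand concentrations, M (same length).
#' @param molecularity `"heteroduplex"` or `"self-associating"`.
#' @param T_report temperatures (K) at which `dG` is evaluated.
#' @return object of class `vant_hoff_result`: list with `dH`
#'   (kcal mol^-1), `dS` (cal mol^-1 K^-1), `dG` (named by temperature,
#'   kcal mol^-1), `slope`, `intercept`, `r_squared`, `flags`.
#' @export
vant_hoff <- function(Tm_C, C_T, molecularity = "heteroduplex",
                      T_report = c(`298.15` = 298.15, `310.15` = 310.15)) {
  molecularity <- match.arg(molecularity, .molecularities[1:2])
  stopifnot(length(Tm_C) == length(C_T))
  if (length(unique(C_T)) < 3)
    stop("van 't Hoff analysis needs >= 3 distinct concentrations")
  if (max(C_T) / min(C_T) < 4)
    stop("concentration ladder should span at least a 4-fold range")
  x <- if (molecularity == "heteroduplex") log(C_T / 4) else log(C_T)
  y <- 1 / (Tm_C + 273.15)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  flags <- character()
  if (abs(slope) < 1e-12) flags <- c(flags, "unstable-dH-near-zero-slope")
  dH <- .RK / slope                      # kcal/mol
  dS <- 1000 * dH * intercept            # cal/mol/K
  dG <- vapply(T_report, function(TT) dH - TT * dS / 1000, 0)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(dH = dH, dS = dS, dG = dG, slope = slope,
                 intercept = intercept,
                 r_squared = r2, flags = flags),
            class = "vant_hoff_result")
}

# temperature at which a normalized curve crosses `level`, by linear
# interpolation on a lightly smoothed curve. A transition must cross the
# level essentially once; curves that never reach it, or cross it
# repeatedly (no resolvable transition), give NA.
.crossing_temperature <- function(temperature_C, normalized, level) {
  k <- min(7, length(normalized) - (1 - length(normalized) %% 2))
  sm <- stats::filter(normalized, rep(1 / k, k), sides = 2)
  keep <- !is.na(sm)
  sm <- as.numeric(sm[keep]); tc <- temperature_C[keep]
  above <- sm >= level
  if (all(above) || !any(above)) return(NA_real_)
  up <- which(!above[-length(above)] & above[-1])
  down <- which(above[-length(above)] & !above[-1])
  if (length(up) + length(down) > 2) return(NA_real_)
  i <- up[1]
  if (is.na(i)) return(NA_real_)
  t0 <- tc[i]; t1 <- tc[i + 1]
  y0 <- sm[i]; y1 <- sm[i + 1]
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Classify a normalized melt overlay as intra- or intermolecular
#'
#' Normalizes each curve to `[0, 1]` and locates the temperature at
#' normalized signal 0.75 (the vertical midpoint marker of the transition).
#' If that temperature shifts monotonically with concentration beyond
#' `tolerance_C` the process is intermolecular; if the maximal pairwise
#' shift stays below tolerance the curves overlap and the process is
#' intramolecular; anything else (including curves never reaching the 0.75
#' level) is indeterminate. Classification is invariant to affine rescaling
#' of the raw signals.
#'
#' @param curves list of [melt_curve()] objects at distinct `C_T`.
#' @param tolerance_C shift tolerance, degrees C. Default 0.5.
#' @param level normalized-signal marker. Default 0.75.
#' @return list with `classification`, `midpoint_C` (per curve, ordered by
#'   decreasing `C_T`), `midpoint_shifts_C` (per concentration step) and
#'   `C_T`.
#' @export
overlay_diagnostic <- function(curves, tolerance_C = 0.5, level = 0.75) {
  stopifnot(length(curves) >= 2)
  C_T <- vapply(curves, function(cv) attr(cv, "C_T"), 0)
  ord <- order(C_T, decreasing = TRUE)
  mids <- vapply(curves[ord], function(cv) {
    rng <- range(cv$signal)
    if (diff(rng) == 0) return(NA_real_)
    .crossing_temperature(cv$temperature_C,
                          (cv$signal - rng[1]) / diff(rng), level)
  }, 0)
  shifts <- diff(mids)
  classification <-
    if (any(is.na(mids))) "indeterminate"
    else if (max(abs(shifts)) < tolerance_C) "intramolecular"
    else if (all(shifts < 0) || all(shifts > 0)) "intermolecular"
    else "indeterminate"
  list(classification = classification,
       midpoint_C = mids, midpoint_shifts_C = shifts, C_T = C_T[ord])
}
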