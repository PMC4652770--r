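#' Construct an umbrella-sampling window
#'
#' One harmonic-restraint window on a periodic dihedral coordinate: the
#' restraint energy is `0.5 * k * d^2` with `d` the minimum-image
#' difference from the window center.
#'
#' @param center restraint center, degrees.
#' @param k force constant, kcal mol^-1 deg^-2 (>= 0). Default 0.007, a
#'   typical dihedral umbrella strength at 10-degree window spacing.
#' @param samples sampled angles, degrees.
#' @param T temperature, K.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 0.007, samples, T = .TREF) {
  stopifnot(is.finite(center), k >= 0, T > 0, length(samples) >= 1)
  structure(list(center = wrap_angle(center, lower = 0) %% 360,
                 k = k, samples = as.numeric(samples), T = T),
            class = "umbrella_window")
}

#' Harmonic bias energy of an umbrella window
#'
#' `0.5 * k * d^2` where `d` is the minimum-image periodic difference
#' between the angle and the window center (`|d| <= 180` degrees), so a
#' window at 350 degrees biases 10 degrees through the wrap, not 340.
#'
#' @param angle angle(s), degrees.
#' @param window an [umbrella_window()], or a center in degrees when `k` is
#'   given explicitly.
#' @param k force constant, kcal mol^-1 deg^-2 (ignored when `window` is an
#'   `umbrella_window`).
#' @return bias energy, kcal mol^-1.
#' @examples
#' bias_energy(10, 350, k = 0.007)   # 1.4
#' @export
bias_energy <- function(angle, window, k = NULL) {
  if (inherits(window, "umbrella_window")) {
    center <- window$center; k <- window$k
  } else {
    center <- window
    if (is.null(k)) stop("k required when window is a plain center")
  }
  d <- .ang_diff(angle, center)
  0.5 * k * d^2
}

#' Periodic 1-D WHAM reconstruction of a free-energy profile
#'
#' Self-consistent solution of the standard WHAM equations on a periodic
#' angular grid: with per-window histogram counts `n_ib`, sample counts
#' `N_i` and bias energies `c_ib` evaluated at the bin centers,
#' `p_b = sum_i n_ib / sum_i N_i exp(-(c_ib - f_i)/RT)` and
#' `f_i = -RT log sum_b p_b exp(-c_ib/RT)` are iterated until the largest
#' change in any `f_i` falls below `tol`. The profile is anchored at zero
#' at its minimum and the `f_i` are reported relative to the first window.
#'
#' @param windows list of [umbrella_window()] objects at a common
#'   temperature, jointly covering the sampled range.
#' @param bin_width bin width, degrees (must divide 360). Default 2.
#' @param tol convergence tolerance on the window free energies,
#'   kcal mol^-1. Default 1e-8.
#' @param max_iter iteration cap. Default 1e5.
#' @return object of class `wham_solution`: list with `pmf` (an
#'   `fes_profile` data.frame: `angle`, `free_energy`, `count`),
#'   `window_free_energies`, `iterations`, `converged`, and
#'   `delta_history` (the per-iteration maximum change in the window free
#'   energies, the convergence diagnostic).
#' @export
wham_solve <- function(windows, bin_width = 2, tol = 1e-8, max_iter = 1e5) {
  stopifnot(length(windows) >= 1, 360 %% bin_width == 0)
  stopifnot(all(vapply(windows, inherits, TRUE, "umbrella_window")))
  Ts <- vapply(windows, `[[`, 0, "T")
  if (diff(range(Ts)) > 1e-9) stop("all windows must share a temperature")
  RT <- .RK * Ts[1]
  mids <- seq(bin_width / 2, 360 - bin_width / 2, by = bin_width)
  nb <- length(mids)
  nw <- length(windows)
  counts <- vapply(windows, function(w)
    .angle_histogram(w$samples, bin_width)$count, numeric(nb))   # nb x nw
  N <- colSums(counts)
  h <- rowSums(counts)
  # joint support must be one contiguous arc on the circle
  occ <- h > 0
  if (!all(occ)) {
    runs <- rle(occ[c(which.max(!occ):nb, seq_len(which.max(!occ) - 1))])
    if (sum(runs$values) > 1)
      stop("disconnected support: sampled regions are separated by empty bins")
  }
  bias <- vapply(windows, function(w) bias_energy(mids, w), numeric(nb))  # nb x nw
  expb <- exp(-bias / RT)
  f <- numeric(nw)
  iter <- 0L
  converged <- FALSE
  deltas <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- expb %*% (N * exp(f / RT))            # nb x 1
    p <- ifelse(h > 0, h / denom, 0)
    fn <- -RT * log(colSums(p * expb))
    fn <- fn - fn[1]
    deltas[iter] <- max(abs(fn - f))
    if (deltas[iter] < tol) { f <- fn; converged <- TRUE; break }
    f <- fn
  }
  denom <- expb %*% (N * exp(f / RT))
  p <- as.numeric(ifelse(h > 0, h / denom, 0))
  p <- p / sum(p)
  G <- ifelse(p > 0, -RT * log(p), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  pmf <- data.frame(angle = mids, free_energy = G, count = h)
  class(pmf) <- c("fes_profile", "data.frame")
  attr(pmf, "T") <- Ts[1]
  structure(list(pmf = pmf, window_free_energies = f,
                 iterations = iter, converged = converged,
                 delta_history = deltas),
            class = "wham_solution")
}
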