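---
title: "Coupled-equilibrium thermodynamics of 2-thiouridine RNA duplexes"
author: "thiotherm"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiotherm)
```

## The problem

2-thiouridine (s2U) — uridine with sulfur replacing the C2 carbonyl oxygen
— stabilizes U:A Watson–Crick pairs and destabilizes U:G wobbles, which
makes it valuable for both tRNA biology and nonenzymatic RNA copying.
Dissecting *why* it stabilizes a duplex requires pulling apart the free
energy of hybridization into its enthalpic and entropic parts, at the
duplex scale (calorimetry, optical melting) and at the nucleoside scale
(sugar-pucker populations from NMR couplings, torsion-angle landscapes
from simulation). `thiotherm` implements that entire analysis chain as
composable, tested functions:

* **core thermodynamics** — `thermo_state()`, `free_energy_from_kd()`,
  `entropy_term()`, `delta_delta()`, and exact speciation solvers for 1:1
  binding (`solve_two_strand()`) and binding coupled to a competing
  homodimer (`solve_competition()`);
* **ITC** — forward simulation (`simulate_titration()`) and
  Levenberg–Marquardt fitting (`fit_single_site()`, `fit_competition()`)
  of integrated injection heats, plus the closed-form corrections
  `kobs_correction()` / `dh_obs_correction()` and `correct_observed()`;
* **optical melting** — `simulate_melt()`, `fit_melt()` (two-state model
  with sloped double baselines), `vant_hoff()` (concentration-series
  analysis), `overlay_diagnostic()` (intra- vs intermolecular calls for
  single strands);
* **sugar pucker** — a generalized Karplus forward model
  (`karplus_forward()`) and its two-state inversion (`fit_two_state()`),
  pseudorotation phase from coordinates (`phase_from_coords()`,
  `pucker_from_pdb()`), glycosidic torsions (`chi_from_coords()`), basin
  populations and Boltzmann-inverted profiles
  (`trajectory_populations()`, `fes_from_histogram()`);
* **umbrella sampling** — periodic 1-D WHAM (`wham_solve()`);
* **synthetic data** — seeded generators (`gen_itc()`,
  `gen_melt_series()`, `gen_couplings()`, `gen_angle_series()`,
  `gen_umbrella()`) that produce every input the analysis consumes, so the
  full pipeline is testable without instrument data.

All energies are kcal mol^-1 internally; entropy differences are converted
to cal mol^-1 K^-1 only at reporting. The gas constant
(1.9872e-3 kcal mol^-1 K^-1) and reference temperature (298.15 K) live in
`thermo_constants()` and nowhere else.

## The coupled-equilibrium ITC model

A titration of strand U into a cell containing its partner Uc is
complicated when Uc self-associates. The package models the scheme

```
Uc + Uc  <-> Uc:Uc      (association constant L = [Uc:Uc]/[Uc]^2)
U  + Uc  <-> U:Uc       (association constant K)
```

`solve_competition()` reduces the two mass balances to one monotone scalar
equation in free `[Uc]` and solves it by safeguarded bisection with a
Newton polish, so convergence is guaranteed for all valid inputs
(residuals are checked to 1e-8 relative, conservation to 1e-10).

### Injection bookkeeping

`simulate_titration()` uses the continuous-perfusion displacement
convention: injected volume mixes in while an equal volume of cell content
overflows at its instantaneous composition, so every total concentration
dilutes by exactly `exp(-dV/V0)` per injection and the concentration path
depends only on cumulative injected volume. The heat of injection *i*
counts the complex moles formed — the change inside the active volume plus
the complex carried out with the overflow, the latter integrated with the
trapezoid rule. This makes the cumulative heat second-order insensitive to
how the injected volume is discretized (halving injection volumes moves
the total heat by well under 0.1 %). Heats are in ucal; the default cell
is 170 uL with ~2 uL injections, ~10 uM titrand and a ~10-fold stronger
syringe, the scale of small-volume calorimeters.

### The closed-form corrections and their regimes

Fitting homodimer-affected data with the plain single-site model yields an
*observed* constant and enthalpy. The package provides the standard
closed-form relations

* `K_obs = K / (1 + 2 L [Uc])`
* `dH_obs = dH_duplex - dH_dimer * 2 L [Uc] / (1 + 2 L [Uc])`

with `[Uc]` the free competing-strand concentration at the start of the
titration (`free_monomer()` computes it). Three facts about these
relations, established numerically during development and enforced by the
test suite, deserve emphasis because they are easy to get wrong:

1. **`K_obs` is a titration-start identity.** It is exactly the apparent
   association constant `[U:Uc] / ([U] * pool)` when the "site"
   concentration is the whole unbound Uc pool (monomer plus
   dimer-sequestered). The tests verify it against the brute-force
   speciation solver to well under 5 % across dimer loads
   `2L[Uc]` from 0.1 to 5.
2. **`dH_obs` is a complete-conversion statement**, and its
   `dH_dimer` enters *per mole of strand* transferred out of the dimer —
   half the per-dimer formation enthalpy, as the half-dimer notation
   `1/2 [Uc:Uc] <-> [Uc]` of the scheme implies. With that convention the
   total heat per duplex formed over a saturating simulated titration
   matches the closed form to better than 0.4 kcal mol^-1 across the same
   grid. The *marginal* (first-injection) dimer contribution is instead
   `2Lx/(1+4Lx)` per dimer; the two coincide only for weak dimerization.
3. **The corrections cannot be validated by a curve fit at pinned
   `[Uc]`.** The curvature of a binding isotherm *is* the depletion of the
   free pool: any titration in which free `[Uc]` moves by less than ~20 %
   carries essentially no information about `Kd`, and the single-site
   least-squares surface is degenerate there. In identifiable
   (saturating) titrations free `[Uc]` spans nearly its full range, and
   the fitted apparent constant falls between the fully corrected form
   (evaluated at the initial pool) and the true `K` — a bracket the tests
   assert. This is why `fit_competition()`, which fits the full coupled
   model with `L` and `dH_dimer` fixed from independent single-strand
   melts, is the preferred route to the true `K` and `dH_duplex`; the
   closed forms are for correcting already-published observed values,
   which is how `correct_observed()` uses them.

Applying the published corrected/observed free-energy pair and enthalpy
triple in reverse implies dimer loads `2L[Uc]` of about 3.9 and 4.4 —
internally consistent within 15 %, though both exceed what the stated
10 uM cell concentration supports (they match the free monomer of a
100 uM syringe pool instead). The package therefore treats the printed
corrected values as internally consistent rather than as absolute targets.

`fit_single_site()` fits `(Kd, dH, n, baseline)` (optionally with `n`
fixed) by multistart Levenberg–Marquardt on `log10(Kd)`; ties are broken
by deviance and then by proximity to the starting `log10(Kd)`. Confidence
half-widths come from the local quadratic approximation. A heat dynamic
range below three times the residual scatter raises a flat-isotherm flag;
all-zero heats short-circuit to a flagged, unidentifiable result. The
baseline is a single constant offset per experiment, appropriate when no
blank-injection data exist.

## Two-state melting with double baselines

`fraction_duplex()` solves the mass-action relation for the paired strand
fraction under three molecularities — heteroduplex
(`Ka = 2f/((1-f)^2 C_T)`, equimolar strands assumed), self-associating
(`Ka = f/(2(1-f)^2 C_T)`), and unimolecular — using the cancellation-safe
quadratic root. At the melting temperature defined by the van 't Hoff
line, `f = 1/2` (equivalently `Kd(Tm) = C_T/4`, or `C_T` for a
homodimer).

`fit_melt()` fits all six parameters (Tm, dH, two sloped baselines)
jointly against the raw curve; no baseline windows are pre-selected. The
entropy is pinned to Tm through the molecularity's mass-action relation,
so Tm is always "paired fraction one-half at this curve's C_T". Curves
whose fitted transition amplitude is under three times the residual
scatter, or whose Tm falls outside the scanned range, are flagged `no_tm`
— mirroring single-strand melts too shallow to yield a reliable melting
temperature. Premelting structure shows up in `residual_rms`; it is
reported, not masked.

`vant_hoff()` regresses `1/Tm` on `ln(C_T/4)` (or `ln(C_T)` for a
self-associating strand): `dH = R/slope`, `dS = dH * intercept`, and
`dG(T)` is reported at 25 and 37 degrees C by default (the analysis
temperature is a choice the user can override). The two molecularity
conventions shift the intercept by exactly `R ln(4) / dH`, which the
tests assert to machine precision. The ladder must span at least three
distinct concentrations over a 4-fold range; the default synthetic ladder
is 200, 100, 50, 25, 12.5, 6.75 uM over 4–89 degrees C.

`overlay_diagnostic()` normalizes each curve to [0, 1], locates the
temperature at normalized signal 0.75 on a lightly smoothed curve, and
calls the series intermolecular when that marker shifts monotonically
with concentration beyond tolerance (default 0.5 degrees C),
intramolecular when curves overlap within tolerance, and indeterminate
otherwise — including when a curve crosses the marker level repeatedly,
as pure noise does. The call is invariant to affine rescaling of the raw
signals.

## Sugar pucker

### Couplings

The three vicinal ribose couplings (J H1'-H2', H2'-H3', H3'-H4') of a
nucleoside exchanging between North (C3'-endo) and South (C2'-endo)
puckers average linearly over the two states. Pure-state couplings are
computed from the ring torsions `nu_j = nu_max cos(P + 144 (j-2))`
through pair-specific linear proton-torsion relations and a generalized
electronegativity-corrected Karplus curve
(`J = P1 cos^2 phi + P2 cos phi + P3 +
sum_i lambda_i (P4 + P5 cos^2(xi_i phi + P6 |lambda_i|))`).
The default parameter table (`karplus_params()`) uses the classical
curve constants (13.22, -0.99, 0, 0.87, -2.46, 19.9), substituent
electronegativities (ring O 1.27, OH 1.26, N 0.85, C 0.68) and
orientation signs chosen so that canonical North geometry gives a small
J(H1'H2') and a large J(H3'H4') with South reversed, the well-known
qualitative signature. The table is an explicit, swappable argument: any
self-consistent parameterization gives identical population round trips,
which is what the tests rely on — the exact constants of any particular
published variant are deliberately not hard-coded truth.

`fit_two_state()` inverts the forward model. The default
single-parameter mode is a closed-form weighted least-squares estimate of
the North fraction with the geometries held canonical
(P_N = 18, P_S = 162, nu_max = 38 degrees); `"full"` mode also fits the
geometries inside canonical windows. Residual RMS above 0.5 Hz flags a
poor two-state description. `population_to_dG()` converts fractions to
free energies via `-RT log(x/(1-x))` and refuses the endpoints, where the
free energy is unbounded.

### Coordinates and trajectories

`phase_from_coords()` computes the five endocyclic torsions and projects
them onto the ideal cosine pattern — exactly the classical phase and
amplitude for an ideal pseudorotation pattern, but well defined at
P = 90/270 where the textbook `nu_2/cos(P)` amplitude formula is
singular. The torsion convention places pure C3'-endo at P = 18 degrees
and C2'-endo at 162 degrees; landscape conventions that put these minima
near 30 and 180 degrees differ only by a small constant offset inside the
same North/South windows, so populations are insensitive to the choice.
Amplitudes under 1 degree (an essentially planar ring) are an error, not
a number. `ring_from_pucker()` builds coordinates for any target (P,
nu_max) by Gauss–Newton refinement of the out-of-plane displacements with
a pseudo-inverse (the z-only torsion Jacobian has rank 2 — amplitude and
phase — with translation and the two tilts as exact null directions);
the ring generator and the phase reader invert each other to ~1e-4
degrees over the full wheel. Dihedrals use the standard determinant
formula (identical to common trajectory tools); note that negating the
z-coordinates of a ring flips all five torsions and therefore advances
the phase by 180 degrees.

`trajectory_populations()` counts samples in named circular basins
(defaults: North (-30, 90], South (90, 270] for pucker; anti around -160
and plus around +50 degrees for the glycosidic angle) and reports
anything outside every basin rather than dropping it.
`fes_from_histogram()` Boltzmann-inverts an unbiased histogram with the
occupied minimum anchored at zero; empty bins are `NA`. All angular
arithmetic wraps on the circle.

## Umbrella sampling and WHAM

`wham_solve()` iterates the standard WHAM equations on a periodic grid
(default 2-degree bins, tolerance 1e-8 kcal mol^-1 on the window offsets,
at most 1e5 iterations), with the harmonic bias `0.5 k d^2` evaluated on
minimum-image differences so a window at 350 degrees biases 10 degrees
through the wrap. Windows at 0 and 360 degrees are the same window. The
default force constant, 0.007 kcal mol^-1 deg^-2 at 10-degree spacing, is
the standard dihedral umbrella protocol this analysis targets. Joint
support must be one contiguous arc; separated sampled regions are an
error because their relative offset is undetermined. The solution reports
the per-iteration convergence diagnostic, the window free energies
relative to the first window, and the PMF anchored at zero.

The synthetic route samples each window by seeded Metropolis on
landscape-plus-bias (`gen_umbrella()`), with the same bias convention as
the solver so tests are convention-consistent. On the reference
double-well landscape (wells at -160 and +50 degrees, 3 kcal mol^-1
barrier, 1 kcal mol^-1 asymmetry) 36 windows of 1e4 draws reconstruct the
landscape to under 0.1 kcal mol^-1 RMS over occupied bins.

## What the generators emulate — and what they do not

The generators reproduce the statistical *structure* the analysis assumes:
two-state binding isotherms and melting transitions, Gaussian
homoscedastic noise (no instrument noise model is published for these
data, so a single noise scale per experiment is the default; nothing in
the fitting depends on that choice), Boltzmann-distributed torsion
samples with realistic autocorrelation from the Metropolis kernel, and
paper-scale magnitudes (Kd tens of nM to uM, dH -45 to -65 kcal mol^-1,
170 uL cell, the 200 to 6.75 uM melt ladder). They do not emulate
baseline drift or power-trace integration artifacts in calorimetry,
premelting transitions or wavelength-resolved CD structure in melts,
multi-spin NMR effects beyond three averaged couplings, or force-field
error in torsion sampling. Passing tests therefore demonstrate that the
estimators invert the stated models correctly and stably at realistic
scales — not that those models exhaust real instrument data.

## Numerical choices

* Speciation: bracketed `uniroot` on monotone reductions plus a Newton
  polish; no seed sensitivity, residuals verified.
* Fits: `minpack.lm::nls.lm` with 8 seeded multistarts (Kd on the log
  scale); CIs from the quadratic approximation at the optimum.
* Tie-breaks: lowest deviance, then smallest `|log10 Kd - log10 Kd_start|`.
* Degenerate inputs fail loudly and specifically: non-positive Kd or
  temperatures, planar rings, collinear dihedrals, endpoints of
  population fractions, disconnected WHAM support, single-concentration
  van 't Hoff ladders.
* Tests run the full pipeline at reduced but honest sizes — 50–100 seeded
  replicates for recovery studies, 1e4 draws per umbrella window, 1e5–1e6
  samples for histogram flatness — sizes chosen so sampling error sits
  comfortably below the tolerances being asserted.

## Known limitations

* No activity-coefficient or salt-dependence corrections; the coupled
  scheme stops at two equilibria (no three-state competition).
* Heteroduplex melts assume equimolar strands (the `C_T/4` convention's
  derivation); unequal mixing ratios are out of scope.
* The overlay diagnostic is a classifier, not an estimator; weak
  intermolecular association below its shift tolerance will read as
  intramolecular.
* WHAM is 1-D and periodic only; no MBAR, no autocorrelation-time
  estimation (subsample externally if needed).
* The Karplus table is a package default, not a claim about any single
  published parameterization; absolute population accuracy inherits the
  table's accuracy, while population *differences* between similar
  nucleosides are robust.
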