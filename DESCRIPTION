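Package: thiotherm
Title: Thermodynamics of 2-Thiouridine-Enhanced RNA Hybridization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coupled-equilibrium analysis of RNA duplex formation in the
    presence of a competing single-strand homodimer, as arises when one
    strand of an isothermal titration calorimetry (ITC) experiment
    self-associates. Provides forward simulation and Levenberg-Marquardt
    fitting of single-site and homodimer-competition binding isotherms
    with closed-form corrections of the observed association constant and
    enthalpy; two-state optical melting-curve fitting with sloped double
    baselines and concentration-series van 't Hoff analysis for
    heteroduplex, self-associating and unimolecular transitions; ribose
    sugar-pucker analysis from vicinal proton couplings (generalized
    electronegativity-corrected Karplus equation), from ring coordinates
    (pseudorotation phase) and from dihedral-angle trajectories; and
    periodic weighted-histogram (WHAM) reconstruction of free-energy
    landscapes from umbrella-sampling windows. Seeded synthetic-data
    generators emulate every input so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
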