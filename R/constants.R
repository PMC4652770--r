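#' Physical constants used throughout the package
#'
#' All thermodynamic bookkeeping in the package uses the gas constant in
#' kcal mol^-1 K^-1 and a reference temperature of 298.15 K (25 degrees C).
#' Every module obtains `R` and `T_ref` from here; no other definition of
#' either exists in the package.
#'
#' @return A list with components
#'   \describe{
#'     \item{R_kcal}{gas constant, 1.9872e-3 kcal mol^-1 K^-1}
#'     \item{R_cal}{gas constant, 1.9872 cal mol^-1 K^-1}
#'     \item{T_ref}{reference temperature, 298.15 K}
#'   }
#' @examples
#' thermo_constants()$R_kcal
#' @export
thermo_constants <- function() {
  list(R_kcal = 1.9872e-3, R_cal = 1.9872, T_ref = 298.15)
}

.RK <- 1.9872e-3   # kcal mol^-1 K^-1
.RC <- 1.9872      # cal  mol^-1 K^-1
.TREF <- 298.15    # K
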