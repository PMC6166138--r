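#' Physical constants for the thermodynamic transport model
#'
#' Bundles the gas constant, the Faraday constant and the natural-log to
#' log10 prefactor used throughout the reversal-potential model. The
#' prefactor defaults to 2.3 (the rounding conventional in the
#' electrophysiology literature) rather than 2.303; both are supported so
#' either rounding of published slope predictions can be reproduced.
#'
#' @param gas_constant Gas constant R, J mol^-1 K^-1.
#' @param faraday Faraday constant F, C mol^-1.
#' @param ln10_factor Dimensionless prefactor converting natural-log
#'   thermodynamics to decade (log10) slopes.
#' @return An object of class `phys_constants`.
#' @examples
#' phys_constants()
#' phys_constants(ln10_factor = log(10)) # exact ln(10)
#' @export
phys_constants <- function(gas_constant = 8.314, faraday = 96485,
                           ln10_factor = 2.3) {
  for (nm in c("gas_constant", "faraday", "ln10_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm))
  }
  structure(list(gas_constant = gas_constant, faraday = faraday,
                 ln10_factor = ln10_factor),
            class = "phys_constants")
}

#' Transport-cycle stoichiometry
#'
#' Numbers of Na+, Cl- and substrate (glycine) molecules moved per transport
#' cycle. The substrate count is fixed at one per cycle; the net charge
#' translocated per cycle is always derived as `n_na - n_cl` (see
#' [net_charge()]), never stored.
#'
#' @param n_na Sodium ions coupled per cycle (>= 0).
#' @param n_cl Chloride ions coupled per cycle (>= 0).
#' @param n_gly Substrate molecules per cycle; must be 1.
#' @return An object of class `stoichiometry`.
#' @examples
#' stoichiometry(3, 1)          # GlyT2-like, net charge +2
#' net_charge(stoichiometry(2, 1)) # GlyT1-like, +1
#' @export
stoichiometry <- function(n_na, n_cl, n_gly = 1) {
  if (!is.numeric(n_na) || length(n_na) != 1L || n_na < 0)
    stop("'n_na' must be a single non-negative number")
  if (!is.numeric(n_cl) || length(n_cl) != 1L || n_cl < 0)
    stop("'n_cl' must be a single non-negative number")
  if (!identical(as.numeric(n_gly), 1))
    stop("'n_gly' is fixed at 1 substrate molecule per cycle")
  structure(list(n_na = as.numeric(n_na), n_cl = as.numeric(n_cl), n_gly = 1),
            class = "stoichiometry")
}

#' Net charge moved per transport cycle
#'
#' @param stoich A [stoichiometry()] object.
#' @return `n_na - n_cl` (elementary charges per cycle; the substrate is
#'   zwitterionic and carries no net charge).
#' @export
net_charge <- function(stoich) {
  stopifnot(inherits(stoich, "stoichiometry"))
  stoich$n_na - stoich$n_cl
}

#' Ionic and substrate conditions on both membrane faces
#'
#' External and internal Na+, Cl- and substrate concentrations plus bath
#' temperature. Only concentration ratios enter the thermodynamic model, so
#' the unit (mM throughout) cancels. Zero concentrations are rejected: the
#' model is logarithmic.
#'
#' The internal-side defaults (`na_i` 10 mM, `cl_i` 40 mM, `gly_i` 10 mM)
#' are assumptions representative of an injected oocyte, not measured
#' values; override them whenever intracellular composition is known.
#'
#' @param na_o,cl_o,gly_o External concentrations, mM (> 0).
#' @param na_i,cl_i,gly_i Internal concentrations, mM (> 0).
#' @param temperature_c Bath temperature, degrees C, in \[0, 45\]. 18 C is
#'   the usual oocyte recording temperature; use 37 for cell-uptake work.
#' @return An object of class `ion_conditions`.
#' @examples
#' ion_conditions(na_o = 100, cl_o = 100, gly_o = 1)
#' @export
ion_conditions <- function(na_o, cl_o, gly_o,
                           na_i = 10, cl_i = 40, gly_i = 10,
                           temperature_c = 18) {
  conc <- c(na_o = na_o, cl_o = cl_o, gly_o = gly_o,
            na_i = na_i, cl_i = cl_i, gly_i = gly_i)
  if (!all(is.finite(conc)) || any(conc <= 0))
    stop("all concentrations must be finite and strictly positive (mM); ",
         "the reversal-potential model is log-based")
  if (!is.finite(temperature_c) || temperature_c < 0 || temperature_c > 45)
    stop("'temperature_c' must lie in [0, 45] degrees C")
  structure(c(as.list(conc), list(temperature_c = temperature_c)),
            class = "ion_conditions")
}

#' Swap external and internal concentrations
#'
#' Utility that exchanges every external concentration with its internal
#' counterpart. The reversal potential is antisymmetric under this swap.
#'
#' @param cond An [ion_conditions()] object.
#' @return An `ion_conditions` object with the two faces exchanged.
#' @export
swap_sides <- function(cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  ion_conditions(na_o = cond$na_i, cl_o = cond$cl_i, gly_o = cond$gly_i,
                 na_i = cond$na_o, cl_i = cond$cl_o, gly_i = cond$gly_o,
                 temperature_c = cond$temperature_c)
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("Stoichiometry %gNa+ : %gCl- : %g substrate (net charge %+g per cycle)\n",
              x$n_na, x$n_cl, x$n_gly, net_charge(x)))
  invisible(x)
}

#' @export
print.ion_conditions <- function(x, ...) {
  cat(sprintf("Ion conditions at %.1f C (mM):\n", x$temperature_c))
  cat(sprintf("  external  Na+ %-7g Cl- %-7g substrate %g\n", x$na_o, x$cl_o, x$gly_o))
  cat(sprintf("  internal  Na+ %-7g Cl- %-7g substrate %g\n", x$na_i, x$cl_i, x$gly_i))
  invisible(x)
}

#' @export
print.phys_constants <- function(x, ...) {
  cat(sprintf("Physical constants: R = %g J/mol/K, F = %g C/mol, ln10 prefactor = %g\n",
              x$gas_constant, x$faraday, x$ln10_factor))
  invisible(x)
}
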