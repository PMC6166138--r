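#' Thermodynamic reversal potential of coupled transport
#'
#' Membrane potential at which an electrogenic cotransporter with the given
#' stoichiometry is at thermodynamic equilibrium, so net transporter current
#' is zero. For `n_na` Na+, `n_cl` Cl- and one substrate molecule per cycle
#' with net charge `z_t = n_na - n_cl`,
#'
#' \deqn{E_T = \frac{2.3\,R\,T}{z_T F}\,\log_{10}
#'   \frac{[Na]_o^{n_{Na}}\,[Cl]_o^{n_{Cl}}\,[S]_o}
#'        {[Na]_i^{n_{Na}}\,[Cl]_i^{n_{Cl}}\,[S]_i} \times 1000 \; [mV]}
#'
#' An electroneutral stoichiometry (`z_t == 0`) carries no current and has
#' no defined reversal potential.
#'
#' @param stoich A [stoichiometry()] object with nonzero net charge.
#' @param cond An [ion_conditions()] object (temperature taken from it).
#' @param consts Physical constants, see [phys_constants()].
#' @return Reversal potential in mV.
#' @examples
#' s <- stoichiometry(3, 1)
#' cond <- ion_conditions(na_o = 100, cl_o = 40, gly_o = 10,
#'                        na_i = 10, cl_i = 40, gly_i = 10)
#' reversal_potential(s, cond) # +86.5 mV: one decade of Na+, 3 Na+ over z=2
#' @export
reversal_potential <- function(stoich, cond, consts = phys_constants()) {
  stopifnot(inherits(stoich, "stoichiometry"), inherits(cond, "ion_conditions"),
            inherits(consts, "phys_constants"))
  z <- net_charge(stoich)
  if (z == 0)
    stop("electroneutral stoichiometry (net charge 0): reversal potential undefined")
  t_k <- cond$temperature_c + 273.15
  prefactor_mv <- consts$ln10_factor * consts$gas_constant * t_k /
    (z * consts$faraday) * 1000
  log_ratio <- stoich$n_na * log10(cond$na_o / cond$na_i) +
    stoich$n_cl * log10(cond$cl_o / cond$cl_i) +
    log10(cond$gly_o / cond$gly_i)
  prefactor_mv * log_ratio
}

#' Predicted reversal-potential shift per tenfold change in external Na+
#'
#' The slope of the reversal potential against log10 of the external sodium
#' concentration, `2.3 R T n_Na / (z_T F)` in mV per decade. This is the
#' diagnostic quantity for sodium coupling: at 18 C it is about 86.5
#' mV/decade for a 3Na:1Cl:1substrate cycle (net charge 2) and about 115.4
#' mV/decade for 2Na:1Cl:1substrate (net charge 1).
#'
#' @param stoich A [stoichiometry()] object with nonzero net charge.
#' @param temperature_c Temperature, degrees C.
#' @param consts Physical constants.
#' @return Slope in mV per decade of external Na+.
#' @examples
#' slope_per_decade(stoichiometry(3, 1), 18) # ~86.5
#' slope_per_decade(stoichiometry(2, 1), 18) # ~115.4
#' @export
slope_per_decade <- function(stoich, temperature_c = 18,
                             consts = phys_constants()) {
  stopifnot(inherits(stoich, "stoichiometry"), inherits(consts, "phys_constants"))
  z <- net_charge(stoich)
  if (z == 0)
    stop("electroneutral stoichiometry (net charge 0): slope undefined")
  t_k <- temperature_c + 273.15
  consts$ln10_factor * consts$gas_constant * t_k * stoich$n_na /
    (z * consts$faraday) * 1000
}

#' Infer the number of coupled sodium ions from a measured slope
#'
#' Pure inversion of [slope_per_decade()]: given a measured reversal-potential
#' slope (mV per decade of external Na+) and an assumed net charge per cycle,
#' returns the implied sodium coupling number
#' `n_Na = slope * z_T * F / (2.3 R T * 1000)`.
#'
#' @param slope Measured slope, mV per decade.
#' @param z_t Net charge per transport cycle (nonzero).
#' @param temperature_c Temperature, degrees C.
#' @param consts Physical constants.
#' @return Estimated number of coupled Na+ ions (dimensionless).
#' @examples
#' infer_n_na(86.49, z_t = 2, temperature_c = 18)  # ~2.99
#' infer_n_na(113.50, z_t = 1, temperature_c = 18) # ~1.97
#' @export
infer_n_na <- function(slope, z_t, temperature_c = 18,
                       consts = phys_constants()) {
  stopifnot(inherits(consts, "phys_constants"))
  if (!is.finite(slope)) stop("'slope' must be finite")
  if (!is.numeric(z_t) || length(z_t) != 1L || z_t == 0)
    stop("'z_t' must be a single nonzero number")
  t_k <- temperature_c + 273.15
  slope * z_t * consts$faraday /
    (consts$ln10_factor * consts$gas_constant * t_k * 1000)
}

#' Fit a reversal-potential series against log10 external Na+
#'
#' Ordinary least squares of measured reversal potentials on log10 of the
#' external sodium concentration. The fitted slope, in mV per decade, is
#' compared with [slope_per_decade()] predictions to infer stoichiometry.
#'
#' @param series A data frame with columns `na_o_mM` (> 0) and `e_rev_mV`;
#'   an `oocyte_id` column is allowed and ignored here (see
#'   [fit_reversal_per_oocyte()]).
#' @return An object of class `slope_fit`: `slope`, `intercept`, `slope_se`
#'   (all mV scale), `n_points`, `r_squared`.
#' @examples
#' s <- stoichiometry(3, 1)
#' na <- c(20, 40, 60, 80, 100)
#' er <- vapply(na, function(x) reversal_potential(
#'   s, ion_conditions(na_o = x, cl_o = 40, gly_o = 10)), numeric(1))
#' fit_reversal_series(data.frame(na_o_mM = na, e_rev_mV = er))
#' @export
fit_reversal_series <- function(series) {
  series <- as.data.frame(series)
  req <- c("na_o_mM", "e_rev_mV")
  missing_cols <- setdiff(req, names(series))
  if (length(missing_cols))
    stop("reversal series lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(series$na_o_mM)) || any(series$na_o_mM <= 0))
    stop("'na_o_mM' values must be finite and > 0")
  if (length(unique(series$na_o_mM)) < 2L)
    stop("need at least 2 distinct external Na+ concentrations to fit a slope")
  fit <- stats::lm(e_rev_mV ~ log10(na_o_mM), data = series)
  # noiseless model data fit exactly; lm's perfect-fit caveat is expected
  sm <- suppressWarnings(summary(fit))
  slope_se <- if (nrow(series) > 2L) sm$coefficients[2L, 2L] else 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = slope_se,
                 n_points = nrow(series),
                 r_squared = sm$r.squared),
            class = "slope_fit")
}

#' Per-oocyte reversal-series slopes and their mean
#'
#' Fits each oocyte's reversal-potential series separately by OLS against
#' log10 external Na+ and summarizes the slopes, mirroring how per-cell
#' slopes are averaged in voltage-clamp studies.
#'
#' @param series Data frame with columns `oocyte_id`, `na_o_mM`, `e_rev_mV`.
#' @return A list: `slopes` (named vector, one per oocyte), `mean_slope`,
#'   `se_mean` (standard error of the mean slope), `n_oocytes`.
#' @export
fit_reversal_per_oocyte <- function(series) {
  series <- as.data.frame(series)
  if (!"oocyte_id" %in% names(series))
    stop("reversal series lacks column(s): oocyte_id")
  fits <- lapply(split(series, series$oocyte_id), fit_reversal_series)
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  n <- length(slopes)
  list(slopes = slopes,
       mean_slope = mean(slopes),
       se_mean = if (n > 1L) stats::sd(slopes) / sqrt(n) else 0,
       n_oocytes = n)
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Reversal-potential slope: %.2f +/- %.2f mV per decade of [Na+]o\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept %.2f mV, n = %d points, R^2 = %.4f\n",
              x$intercept, x$n_points, x$r_squared))
  invisible(x)
}
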