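#' Construct a voltage-clamp current trace
#'
#' A uniformly sampled current recording at a fixed holding potential, with
#' the substrate-application window marked. Inward current is negative (the
#' electrophysiology convention).
#'
#' @param time_s Sample times in seconds; strictly increasing, uniform to
#'   within 1e-9 relative spacing.
#' @param current_nA Currents in nA, same length.
#' @param holding_mV Holding potential, mV.
#' @param window Length-2 numeric, substrate application window (start, end)
#'   in seconds; must lie inside the trace.
#' @param condition Optional free-form metadata list.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time_s, current_nA, holding_mV = -60,
                          window = range(time_s), condition = list()) {
  if (length(time_s) != length(current_nA))
    stop("'time_s' and 'current_nA' must have equal length")
  if (length(time_s) < 2L) stop("a trace needs at least 2 samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("'time_s' must be strictly increasing")
  if ((max(dt) - min(dt)) > 1e-9 * max(dt))
    stop("'time_s' must be a uniform grid (relative tolerance 1e-9)")
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("'window' must be (start, end) with start < end")
  if (window[1L] < time_s[1L] || window[2L] > time_s[length(time_s)])
    stop("application window lies outside the trace time span")
  structure(list(time_s = as.numeric(time_s),
                 current_nA = as.numeric(current_nA),
                 holding_mV = holding_mV,
                 window = as.numeric(window),
                 condition = condition),
            class = "current_trace")
}

#' Construct a steady-state current-voltage curve
#'
#' Mean steady-state currents over a voltage-step protocol (typically
#' -150 to +30 mV in 20-mV increments from a -60 mV holding potential),
#' averaged over oocytes. Stored sorted by ascending potential.
#'
#' @param potential_mV Step potentials, mV (distinct).
#' @param current_nA Mean currents, nA (inward negative).
#' @param sem_nA Standard errors of the mean, nA (>= 0).
#' @param n_oocytes Number of oocytes averaged.
#' @param condition Optional metadata list.
#' @return An object of class `iv_curve`.
#' @export
iv_curve <- function(potential_mV, current_nA, sem_nA = 0,
                     n_oocytes = NA_integer_, condition = list()) {
  if (length(potential_mV) != length(current_nA))
    stop("'potential_mV' and 'current_nA' must have equal length")
  if (length(potential_mV) < 2L) stop("an I/V curve needs at least 2 potentials")
  if (anyDuplicated(potential_mV)) stop("'potential_mV' values must be distinct")
  sem_nA <- rep_len(sem_nA, length(current_nA))
  if (any(sem_nA < 0)) stop("'sem_nA' must be >= 0")
  o <- order(potential_mV)
  structure(list(potential_mV = as.numeric(potential_mV)[o],
                 current_nA = as.numeric(current_nA)[o],
                 sem_nA = as.numeric(sem_nA)[o],
                 n_oocytes = n_oocytes, condition = condition),
            class = "iv_curve")
}

#' Substrate-evoked I/V curve by background subtraction
#'
#' Pointwise difference between the I/V curve recorded with substrate and
#' the background curve in the same medium without substrate; SEMs combine
#' in quadrature.
#'
#' @param with_substrate,without [iv_curve()] objects on identical
#'   potential grids.
#' @return The evoked `iv_curve`.
#' @export
evoked_iv <- function(with_substrate, without) {
  stopifnot(inherits(with_substrate, "iv_curve"), inherits(without, "iv_curve"))
  if (!isTRUE(all.equal(with_substrate$potential_mV, without$potential_mV)))
    stop("potential grids differ between the two I/V curves")
  iv_curve(with_substrate$potential_mV,
           with_substrate$current_nA - without$current_nA,
           sem_nA = sqrt(with_substrate$sem_nA^2 + without$sem_nA^2),
           n_oocytes = {
             ns <- c(with_substrate$n_oocytes, without$n_oocytes)
             if (all(is.na(ns))) NA_integer_ else min(ns, na.rm = TRUE)
           },
           condition = with_substrate$condition)
}

#' Normalize an I/V curve to its current at a reference potential
#'
#' Divides all currents (and SEMs) by the magnitude of the current at the
#' reference potential, so an inward current at the reference maps to -1.
#' Idempotent.
#'
#' @param iv An [iv_curve()].
#' @param reference_potential Reference potential, mV; must be on the grid
#'   and carry a nonzero current. Default -150 mV.
#' @return The normalized `iv_curve` (currents dimensionless).
#' @export
normalize_iv <- function(iv, reference_potential = -150) {
  stopifnot(inherits(iv, "iv_curve"))
  i <- which(abs(iv$potential_mV - reference_potential) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("reference potential %g mV is not on the I/V grid",
                 reference_potential))
  ref <- abs(iv$current_nA[i])
  if (ref == 0) stop("current at the reference potential is zero; cannot normalize")
  iv_curve(iv$potential_mV, iv$current_nA / ref, sem_nA = iv$sem_nA / ref,
           n_oocytes = iv$n_oocytes, condition = iv$condition)
}

#' Reversal potential from a discrete I/V curve
#'
#' Locates the single zero crossing of the curve and returns the potential
#' at which the current reverses, by linear interpolation between the
#' bracketing pair of points. Non-reversing curves (no sign change in the
#' tested range — the behavior of wild-type transporters under a strong
#' driving force) raise an error, as do curves crossing zero more than once.
#'
#' @param iv An [iv_curve()].
#' @return Reversal potential, mV.
#' @export
estimate_erev <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  v <- iv$potential_mV
  i <- iv$current_nA
  exact <- which(i == 0)
  sgn <- sign(i)
  cross <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
  n_cross <- length(exact) + length(cross)
  if (n_cross == 0L)
    stop("current does not reverse within the tested potential range")
  if (n_cross > 1L)
    stop("I/V curve crosses zero more than once; reversal potential ambiguous")
  if (length(exact)) return(v[exact])
  k <- cross
  v[k] + (v[k + 1L] - v[k]) * (0 - i[k]) / (i[k + 1L] - i[k])
}

#' Rectification degree of an I/V curve
#'
#' Ratio of the slope of the ordinary least-squares line through the `k`
#' most-negative-potential points to the slope through the `k`
#' most-positive-potential points. A value of 1 indicates a linear
#' (non-rectifying) curve; strongly inwardly rectifying transporter
#' currents give values well above 1.
#'
#' @param iv An [iv_curve()] with at least `2k` points.
#' @param k Number of points per limb (default 3, the conventional choice).
#' @return Dimensionless slope ratio; `Inf` with a warning when the
#'   depolarized-limb slope is zero.
#' @export
rectification_degree <- function(iv, k = 3) {
  stopifnot(inherits(iv, "iv_curve"))
  n <- length(iv$potential_mV)
  if (n < 2L * k)
    stop(sprintf("need at least %d points for k = %d per limb", 2L * k, k))
  limb_slope <- function(idx) {
    unname(stats::coef(stats::lm(iv$current_nA[idx] ~ iv$potential_mV[idx]))[2L])
  }
  s_neg <- limb_slope(seq_len(k))
  s_pos <- limb_slope(seq.int(n - k + 1L, n))
  if (s_pos == 0) {
    warning("depolarized-limb slope is zero; rectification degree infinite")
    return(Inf)
  }
  s_neg / s_pos
}

#' Integrate the evoked charge of a current trace
#'
#' Trapezoidal time integral of the baseline-corrected current over the
#' integration window, converted from nA s to coulombs. The baseline is the
#' mean current over the 5 s preceding the trace's substrate-application
#' window (0 with a warning if no pre-application samples exist); anchoring
#' the baseline to the application rather than the integration window keeps
#' charge additive over adjacent sub-windows. The sign is preserved —
#' inward charge is negative — and the magnitude is reported alongside.
#'
#' @param trace A [current_trace()].
#' @param window Length-2 integration window in seconds; defaults to the
#'   trace's application window.
#' @return A list: `charge_c` (signed, C), `magnitude_c` (C),
#'   `baseline_nA`.
#' @export
integrate_charge <- function(trace, window = trace$window) {
  stopifnot(inherits(trace, "current_trace"))
  t <- trace$time_s
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("'window' must be (start, end) with start < end")
  if (window[1L] < t[1L] || window[2L] > t[length(t)])
    stop("integration window lies outside the trace")
  app_start <- trace$window[1L]
  pre <- t >= (app_start - 5) & t < app_start
  if (!any(pre)) {
    warning("no samples in the 5 s before the application window; baseline taken as 0")
    baseline <- 0
  } else {
    baseline <- mean(trace$current_nA[pre])
  }
  inside <- t >= window[1L] & t <= window[2L]
  ti <- t[inside]
  yi <- trace$current_nA[inside] - baseline
  if (length(ti) < 2L) stop("fewer than 2 samples inside the integration window")
  q_nas <- sum(diff(ti) * (yi[-length(yi)] + yi[-1L]) / 2) # trapezoid, nA*s
  q_c <- q_nas * 1e-9
  list(charge_c = q_c, magnitude_c = abs(q_c), baseline_nA = baseline)
}

#' Moles of substrate from scintillation counts
#'
#' Converts background-corrected disintegrations per minute to moles of
#' radiolabeled substrate using the tracer's specific activity, with
#' 2.22e12 dpm per Ci.
#'
#' @param dpm_sample Counts in the sample (dpm).
#' @param dpm_background Counts in non-injected controls (dpm); must not
#'   exceed the sample.
#' @param specific_activity Tracer specific activity, Ci per mmol (> 0).
#' @return Moles of substrate.
#' @examples
#' moles_from_tracer(8.88e5, 0, specific_activity = 0.4) # 1e-9 mol
#' @export
moles_from_tracer <- function(dpm_sample, dpm_background = 0,
                              specific_activity) {
  if (!is.finite(specific_activity) || specific_activity <= 0)
    stop("'specific_activity' must be > 0 (Ci/mmol)")
  if (any(dpm_background > dpm_sample))
    stop("background counts exceed sample counts")
  (dpm_sample - dpm_background) / (2.22e12 * specific_activity) * 1e-3
}

#' Charge-to-flux ratio
#'
#' Moles of elementary charge moved (integrated charge magnitude divided by
#' the Faraday constant) per mole of radiolabeled substrate accumulated over
#' the same period. For a tightly coupled transporter this estimates the net
#' charge per transport cycle, `z_T = n_Na - n_Cl`.
#'
#' @param charge Signed charge in coulombs, or the result of
#'   [integrate_charge()].
#' @param moles_substrate Moles of substrate taken up (> 0), e.g. from
#'   [moles_from_tracer()].
#' @param consts Physical constants (for the Faraday constant).
#' @return An object of class `charge_flux`: `charge_c` (signed),
#'   `moles_charge`, `moles_substrate`, `ratio` (charges per substrate
#'   molecule).
#' @export
charge_to_flux <- function(charge, moles_substrate, consts = phys_constants()) {
  if (is.list(charge)) charge <- charge$charge_c
  if (!is.finite(moles_substrate) || moles_substrate <= 0)
    stop("'moles_substrate' must be > 0")
  moles_charge <- abs(charge) / consts$faraday
  structure(list(charge_c = charge,
                 moles_charge = moles_charge,
                 moles_substrate = moles_substrate,
                 ratio = moles_charge / moles_substrate),
            class = "charge_flux")
}

#' @export
print.charge_flux <- function(x, ...) {
  cat(sprintf("Charge-to-flux: %.3g charges per substrate molecule\n", x$ratio))
  cat(sprintf("  charge %.3g C (%.3g mol charge), substrate %.3g mol\n",
              x$charge_c, x$moles_charge, x$moles_substrate))
  invisible(x)
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("I/V curve, %d potentials (%g to %g mV), n = %s oocytes\n",
              length(x$potential_mV), min(x$potential_mV), max(x$potential_mV),
              format(x$n_oocytes)))
  print(data.frame(potential_mV = x$potential_mV, current_nA = x$current_nA,
                   sem_nA = x$sem_nA), row.names = FALSE)
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  dt <- x$time_s[2L] - x$time_s[1L]
  cat(sprintf("Current trace: %d samples at %.4g Hz, holding %g mV, window [%g, %g] s\n",
              length(x$time_s), 1 / dt, x$holding_mV, x$window[1L], x$window[2L]))
  invisible(x)
}
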