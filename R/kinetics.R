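#' Construct an uptake dataset
#'
#' Concentration-rate observations from a radiotracer uptake assay, with
#' replicates kept as individual rows. Rates are in nmol substrate per mg
#' protein per 10 min (the assay's natural unit) unless noted otherwise;
#' concentration units are recorded and carried through to fitted constants.
#'
#' @param concentration Concentrations of the varied species (>= 0).
#' @param rate Transport rates, same length.
#' @param replicate Optional replicate labels (recycled if length 1).
#' @param conc_unit Concentration unit label, e.g. "mM" or "uM".
#' @param construct Construct name (e.g. "wtGlyT2", "mock").
#' @param varied_species Which species is varied ("Na", "Cl", "glycine").
#' @param background_subtracted Whether mock background has been removed.
#' @return A data frame of class `uptake_dataset` with columns
#'   `concentration`, `rate`, `replicate` and the metadata as attributes.
#' @export
uptake_dataset <- function(concentration, rate, replicate = 1L,
                           conc_unit = "mM", construct = NA_character_,
                           varied_species = NA_character_,
                           background_subtracted = FALSE) {
  if (length(concentration) != length(rate))
    stop("'concentration' and 'rate' must have equal length")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0")
  if (any(!is.finite(rate))) stop("rates must be finite")
  d <- data.frame(concentration = as.numeric(concentration),
                  rate = as.numeric(rate),
                  replicate = rep_len(replicate, length(rate)))
  structure(d, class = c("uptake_dataset", "data.frame"),
            conc_unit = conc_unit, construct = construct,
            varied_species = varied_species,
            background_subtracted = isTRUE(background_subtracted))
}

#' Subtract mock-cell background uptake
#'
#' Removes nonspecific accumulation measured in mock-transfected cells: the
#' per-concentration mean mock rate is subtracted from every sample
#' replicate at that concentration. Rates driven negative are clipped to
#' zero (with a warning carrying the count) so the concentration grid stays
#' matched for fitting.
#'
#' @param sample,mock [uptake_dataset()] objects on identical concentration
#'   grids (as sets of distinct concentrations).
#' @return The background-corrected `uptake_dataset`; attribute
#'   `n_clipped` records how many rates were clipped to zero.
#' @export
subtract_background <- function(sample, mock) {
  stopifnot(inherits(sample, "uptake_dataset"), inherits(mock, "uptake_dataset"))
  sc <- sort(unique(sample$concentration))
  mc <- sort(unique(mock$concentration))
  unmatched <- c(setdiff(sc, mc), setdiff(mc, sc))
  if (length(unmatched))
    stop("sample and mock concentration grids differ at: ",
         paste(signif(unmatched, 6), collapse = ", "))
  mock_mean <- tapply(mock$rate, mock$concentration, mean)
  corrected <- sample$rate - mock_mean[as.character(sample$concentration)]
  n_clipped <- sum(corrected < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d background-corrected rate(s) were negative and clipped to 0",
                    n_clipped))
    corrected <- pmax(corrected, 0)
  }
  out <- uptake_dataset(sample$concentration, unname(corrected),
                        replicate = sample$replicate,
                        conc_unit = attr(sample, "conc_unit"),
                        construct = attr(sample, "construct"),
                        varied_species = attr(sample, "varied_species"),
                        background_subtracted = TRUE)
  attr(out, "n_clipped") <- n_clipped
  out
}

# Shared saturation-fit engine. The Hill model v = Vmax C^n / (EC50^n + C^n)
# is fitted by Levenberg-Marquardt least squares on the raw replicate rates
# (unweighted). Initialization is deterministic: Vmax from the largest mean
# rate, EC50 from the concentration whose mean rate is nearest half-max,
# and the Hill exponent multi-started over {0.5, 1, 2, 3} with best-SSE
# selection (or fixed for the Michaelis-Menten case).
fit_saturation <- function(data, fix_n = NULL) {
  stopifnot(inherits(data, "uptake_dataset"))
  conc <- data$concentration
  rate <- data$rate
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations to fit saturation kinetics")
  if (isTRUE(all(rate == rate[1L])))
    stop("rates are all equal; saturation curve unidentifiable")

  mean_rate <- tapply(rate, conc, mean)
  grid <- as.numeric(names(mean_rate))
  o <- order(grid)
  grid <- grid[o]
  mean_rate <- mean_rate[o]
  vmax0 <- max(mean_rate)
  pos <- grid > 0
  ec50_0 <- grid[pos][which.min(abs(mean_rate[pos] - vmax0 / 2))]
  n_starts <- if (is.null(fix_n)) c(0.5, 1, 2, 3) else fix_n

  df <- data.frame(C = conc, v = rate)
  best <- NULL
  best_sse <- Inf
  for (n0 in n_starts) {
    fm <- if (is.null(fix_n)) {
      try(minpack.lm::nlsLM(
        v ~ vmax * C^n / (ec50^n + C^n), data = df,
        start = list(vmax = vmax0, ec50 = ec50_0, n = n0),
        control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        v ~ vmax * C^n0 / (ec50^n0 + C^n0), data = df,
        start = list(vmax = vmax0, ec50 = ec50_0),
        control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    }
    if (inherits(fm, "try-error")) next
    if (any(stats::coef(fm) <= 0)) next # invalid saturation parameters
    sse <- sum(stats::residuals(fm)^2)
    if (sse < best_sse) { best <- fm; best_sse <- sse }
  }
  if (is.null(best))
    stop("saturation fit failed to converge from any start value")

  cf <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  sst <- sum((rate - mean(rate))^2)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_
  # saturation approached? compare top of curve with rate at lowest conc
  low <- mean_rate[[1L]]
  saturation_warning <- is.finite(low) && low > 0 && max(mean_rate) < 2 * low
  list(coef = cf, se = se, sse = best_sse, r_squared = r2,
       vcov = tryCatch(stats::vcov(best), error = function(e) NULL),
       saturation_warning = saturation_warning,
       n_obs = length(rate), fitted_model = best)
}

#' Fit the Hill equation to uptake data
#'
#' Least-squares fit of \eqn{v = V_{max} C^n / (EC_{50}^n + C^n)} to
#' concentration-rate data, as used for the sodium dependence of transport.
#' Replicates enter individually and unweighted. Initialization is
#' deterministic (multi-start over the Hill exponent); see Details of the
#' package vignette for the numerical choices.
#'
#' @param data An [uptake_dataset()] with >= 4 distinct concentrations.
#' @return An object of class `hill_fit`: `vmax`, `ec50`, `n_hill`, their
#'   asymptotic standard errors, `r_squared`, `sse`, and
#'   `saturation_warning` (TRUE when the curve top is less than twice the
#'   rate at the lowest concentration, i.e. saturation was not approached).
#' @export
fit_hill <- function(data) {
  res <- fit_saturation(data, fix_n = NULL)
  structure(list(vmax = unname(res$coef["vmax"]),
                 ec50 = unname(res$coef["ec50"]),
                 n_hill = unname(res$coef["n"]),
                 vmax_se = unname(res$se["vmax"]),
                 ec50_se = unname(res$se["ec50"]),
                 n_hill_se = unname(res$se["n"]),
                 r_squared = res$r_squared, sse = res$sse,
                 conc_unit = attr(data, "conc_unit"),
                 saturation_warning = res$saturation_warning,
                 n_obs = res$n_obs),
            class = "hill_fit")
}

#' Fit the Michaelis-Menten equation to uptake data
#'
#' The Hill model with the exponent fixed at 1:
#' \eqn{v = V_{max} C / (K_m + C)}, as used for the chloride and glycine
#' dependence of transport. `Km` is reported in the dataset's concentration
#' unit.
#'
#' @param data An [uptake_dataset()] with >= 4 distinct concentrations.
#' @return An object of class `mm_fit`: `vmax`, `km`, standard errors,
#'   `efficiency` (`vmax/km`, see [transport_efficiency()]), `r_squared`,
#'   `sse`, `saturation_warning`.
#' @export
fit_mm <- function(data) {
  res <- fit_saturation(data, fix_n = 1)
  vmax <- unname(res$coef["vmax"]); km <- unname(res$coef["ec50"])
  structure(list(vmax = vmax, km = km,
                 vmax_se = unname(res$se["vmax"]),
                 km_se = unname(res$se["ec50"]),
                 efficiency = vmax / km,
                 r_squared = res$r_squared, sse = res$sse,
                 vcov = res$vcov,
                 conc_unit = attr(data, "conc_unit"),
                 saturation_warning = res$saturation_warning,
                 n_obs = res$n_obs),
            class = "mm_fit")
}

#' Catalytic efficiency Vmax/Km of a Michaelis-Menten fit
#'
#' Ratio of the fitted maximal rate to the Michaelis constant, with a
#' first-order (delta-method) standard error propagated from the fit's
#' parameter covariance. Note this is the ratio of the fitted means; when a
#' published table averages per-experiment ratios instead, the two need not
#' agree.
#'
#' @param fit An [fit_mm()] result.
#' @return A list `estimate`, `se`.
#' @examples
#' \dontrun{transport_efficiency(fit_mm(d))}
#' @export
transport_efficiency <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  est <- fit$vmax / fit$km
  se <- NA_real_
  if (!is.null(fit$vcov) && all(c("vmax", "ec50") %in% rownames(fit$vcov))) {
    v <- fit$vcov
    # delta method for f = vmax/km: grad = (1/km, -vmax/km^2)
    g <- c(1 / fit$km, -fit$vmax / fit$km^2)
    se <- sqrt(drop(t(g) %*% v[c("vmax", "ec50"), c("vmax", "ec50")] %*% g))
  } else if (is.finite(fit$vmax_se) && is.finite(fit$km_se)) {
    se <- abs(est) * sqrt((fit$vmax_se / fit$vmax)^2 + (fit$km_se / fit$km)^2)
  }
  list(estimate = est, se = se)
}

#' Evaluate a fitted saturation curve
#'
#' @param object A `hill_fit` or `mm_fit`.
#' @param conc Concentrations at which to evaluate.
#' @param ... Unused.
#' @return Predicted rates.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  object$vmax * conc^object$n_hill / (object$ec50^object$n_hill + conc^object$n_hill)
}

#' @rdname predict.hill_fit
#' @export
predict.mm_fit <- function(object, conc, ...) {
  object$vmax * conc / (object$km + conc)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Vmax %.4g +/- %.2g, EC50 %.4g +/- %.2g %s, n %.3g +/- %.2g\n",
              x$vmax, x$vmax_se, x$ec50, x$ec50_se, x$conc_unit,
              x$n_hill, x$n_hill_se))
  cat(sprintf("  R^2 = %.4f on %d observations\n", x$r_squared, x$n_obs))
  if (isTRUE(x$saturation_warning))
    cat("  warning: saturation not approached within the tested range\n")
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax %.4g +/- %.2g, Km %.4g +/- %.2g %s\n",
              x$vmax, x$vmax_se, x$km, x$km_se, x$conc_unit))
  cat(sprintf("  Vmax/Km = %.3g, R^2 = %.4f on %d observations\n",
              x$efficiency, x$r_squared, x$n_obs))
  if (isTRUE(x$saturation_warning))
    cat("  warning: saturation not approached within the tested range\n")
  invisible(x)
}
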