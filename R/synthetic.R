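#' Specification of a synthetic cotransport experiment
#'
#' Collects the ground-truth stoichiometry, ionic conditions, I/V shape
#' parameters, noise levels and the mandatory seed for the synthetic
#' generators. Every generated artifact carries its generating parameters
#' so recovery tests are self-describing.
#'
#' Noise enters three ways: additive Gaussian noise on currents
#' (`noise_sd_current`, nA), additive Gaussian noise on per-oocyte reversal
#' potentials (`noise_sd_erev`, mV), and multiplicative Gaussian noise on
#' uptake rates (`noise_cv_rate`, coefficient of variation). All default to
#' zero (noiseless).
#'
#' @param stoichiometry A [stoichiometry()] object.
#' @param conditions An [ion_conditions()] object.
#' @param max_conductance Conductance scale g of the synthetic I/V,
#'   nA/mV. The default 0.3 puts noiseless currents at about -70 nA at
#'   -150 mV for a net-charge-2 transporter, the scale of oocyte
#'   recordings.
#' @param rectification_v0 Midpoint of the sigmoidal rectification factor,
#'   mV.
#' @param rectification_k Steepness of the rectification factor, mV;
#'   `Inf` disables rectification (factor identically 1).
#' @param noise_sd_current SD of current noise, nA (>= 0).
#' @param noise_sd_erev SD of reversal-potential noise, mV (>= 0).
#' @param noise_cv_rate CV of uptake-rate noise (>= 0).
#' @param n_replicates Default replicate/oocyte count.
#' @param seed Integer seed; mandatory, there is no implicit randomness.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(stoichiometry, conditions,
                            max_conductance = 0.3,
                            rectification_v0 = -30, rectification_k = 30,
                            noise_sd_current = 0, noise_sd_erev = 0,
                            noise_cv_rate = 0, n_replicates = 3L, seed) {
  stopifnot(inherits(stoichiometry, "stoichiometry"),
            inherits(conditions, "ion_conditions"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' is mandatory: synthetic experiments carry no implicit randomness")
  for (nm in c("noise_sd_current", "noise_sd_erev", "noise_cv_rate")) {
    if (get(nm) < 0) stop(sprintf("'%s' must be >= 0", nm))
  }
  if (max_conductance <= 0) stop("'max_conductance' must be > 0")
  structure(list(stoichiometry = stoichiometry, conditions = conditions,
                 max_conductance = max_conductance,
                 rectification_v0 = rectification_v0,
                 rectification_k = rectification_k,
                 noise_sd_current = noise_sd_current,
                 noise_sd_erev = noise_sd_erev,
                 noise_cv_rate = noise_cv_rate,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Hierarchical child seed: a fixed prime stride keeps streams for different
# units (oocytes, replicates, curves) independent of how many are drawn, so
# adding replicates never perturbs earlier ones. Stays below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

# sigmoidal inward-rectification factor in (0, 1]
rectification_factor <- function(v, v0, k) {
  if (is.infinite(k)) return(rep(1, length(v)))
  1 / (1 + exp((v - v0) / k))
}

#' Generate a family of synthetic I/V curves across external Na+ levels
#'
#' For each external sodium concentration, steady-state currents on the
#' standard -150 to +30 mV grid are drawn from
#' \eqn{I(V) = g\,z_T\,(V - E_T)\,\sigma(V)} with
#' \eqn{\sigma(V) = 1/(1 + e^{(V - V_0)/k})} enforcing inward
#' rectification, plus Gaussian noise. The noiseless curve crosses zero
#' exactly at the thermodynamic reversal potential of the spec's
#' stoichiometry and conditions, which is the property the analysis chain
#' must recover.
#'
#' @param spec A [simulation_spec()] with nonzero net charge.
#' @param na_o_list External Na+ concentrations, mM.
#' @param potentials Voltage grid, mV (default the -150..+30 step-20
#'   protocol).
#' @return A list of [iv_curve()] objects, one per Na+ level; each carries
#'   attributes `na_o_mM` and `e_rev_true_mV`.
#' @export
gen_iv_family <- function(spec, na_o_list,
                          potentials = seq(-150, 30, by = 20)) {
  stopifnot(inherits(spec, "simulation_spec"))
  z <- net_charge(spec$stoichiometry)
  if (z == 0) stop("electroneutral stoichiometry: synthetic I/V undefined")
  out <- vector("list", length(na_o_list))
  for (i in seq_along(na_o_list)) {
    cond_i <- spec$conditions
    cond_i$na_o <- na_o_list[i]
    e_t <- reversal_potential(spec$stoichiometry, cond_i)
    sig <- rectification_factor(potentials, spec$rectification_v0,
                                spec$rectification_k)
    current <- spec$max_conductance * z * (potentials - e_t) * sig
    if (spec$noise_sd_current > 0) {
      set.seed(child_seed(spec$seed, i))
      current <- current + stats::rnorm(length(current),
                                        sd = spec$noise_sd_current)
    }
    iv <- iv_curve(potentials, current,
                   condition = list(na_o_mM = na_o_list[i]))
    attr(iv, "na_o_mM") <- na_o_list[i]
    attr(iv, "e_rev_true_mV") <- e_t
    out[[i]] <- iv
  }
  out
}

#' Generate per-oocyte reversal-potential series
#'
#' Each simulated oocyte contributes one measured reversal potential per
#' external Na+ level: the thermodynamic value for the spec's stoichiometry
#' and conditions plus Gaussian measurement noise (`noise_sd_erev`).
#' Downstream, [fit_reversal_series()] / [fit_reversal_per_oocyte()] must
#' recover the model's slope per decade.
#'
#' @param spec A [simulation_spec()].
#' @param na_o_list External Na+ concentrations, mM.
#' @param n_oocytes Number of oocytes (default `spec$n_replicates`).
#' @return A data frame of class `rev_pot_series` with columns `oocyte_id`,
#'   `na_o_mM`, `e_rev_mV`; attribute `slope_true_mV` holds the generating
#'   slope per decade.
#' @export
gen_erev_series <- function(spec, na_o_list, n_oocytes = spec$n_replicates) {
  stopifnot(inherits(spec, "simulation_spec"))
  e_t <- vapply(na_o_list, function(na) {
    cond_i <- spec$conditions
    cond_i$na_o <- na
    reversal_potential(spec$stoichiometry, cond_i)
  }, numeric(1))
  rows <- vector("list", n_oocytes)
  for (j in seq_len(n_oocytes)) {
    noise <- 0
    if (spec$noise_sd_erev > 0) {
      set.seed(child_seed(spec$seed, j))
      noise <- stats::rnorm(length(na_o_list), sd = spec$noise_sd_erev)
    }
    rows[[j]] <- data.frame(oocyte_id = sprintf("oocyte_%02d", j),
                            na_o_mM = na_o_list,
                            e_rev_mV = e_t + noise)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rev_pot_series", "data.frame")
  attr(out, "slope_true_mV") <- slope_per_decade(
    spec$stoichiometry, spec$conditions$temperature_c)
  out
}

#' Generate a synthetic charge-to-flux experiment
#'
#' Emulates the 1-minute simultaneous current / radiotracer-uptake protocol
#' at a fixed holding potential: over `duration` seconds a constant
#' transport rate moves `N = rate * duration` moles of substrate, carrying
#' an evoked inward current of amplitude `z_T * F * N / duration` (A,
#' reported in nA) above baseline, while the accumulated tracer yields
#' `N * 1e3 * specific_activity * 2.22e12` dpm above the non-injected
#' background. Gaussian current noise is added per sample. Running the
#' analysis chain ([integrate_charge()], [moles_from_tracer()],
#' [charge_to_flux()]) on the noiseless output returns exactly the net
#' charge per cycle.
#'
#' @param spec A [simulation_spec()] with positive net charge.
#' @param transport_rate Substrate transport rate, mol/s.
#' @param duration Application window length, s (default 60).
#' @param specific_activity Tracer specific activity, Ci/mmol (default 0.4).
#' @param dpm_background Non-injected-oocyte background counts, dpm.
#' @param pre_s,post_s Baseline and washout padding around the window, s.
#' @param sample_rate_hz Trace sampling rate (default 1000 Hz).
#' @param unit Index of the simulated oocyte (seeds its noise stream).
#' @return A list: `trace` ([current_trace()]), `dpm_sample`,
#'   `dpm_background`, `specific_activity`, and ground truth
#'   `moles_true`, `z_t_true`.
#' @export
gen_charge_flux_experiment <- function(spec, transport_rate, duration = 60,
                                       specific_activity = 0.4,
                                       dpm_background = 200,
                                       pre_s = 10, post_s = 5,
                                       sample_rate_hz = 1000, unit = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  z <- net_charge(spec$stoichiometry)
  if (z <= 0) stop("charge-to-flux simulation requires positive net charge")
  if (transport_rate <= 0) stop("'transport_rate' must be > 0 (mol/s)")
  f <- phys_constants()$faraday
  n_mol <- transport_rate * duration
  amp_na <- -(z * f * n_mol / duration) * 1e9 # inward, nA
  dt <- 1 / sample_rate_hz
  t <- seq(0, pre_s + duration + post_s, by = dt)
  w <- c(pre_s, pre_s + duration)
  current <- ifelse(t >= w[1L] & t <= w[2L], amp_na, 0)
  if (spec$noise_sd_current > 0) {
    set.seed(child_seed(spec$seed, unit))
    current <- current + stats::rnorm(length(current),
                                      sd = spec$noise_sd_current)
  }
  dpm_sample <- n_mol * 1e3 * specific_activity * 2.22e12 + dpm_background
  list(trace = current_trace(t, current, holding_mV = -60, window = w),
       dpm_sample = dpm_sample,
       dpm_background = dpm_background,
       specific_activity = specific_activity,
       moles_true = n_mol, z_t_true = z)
}

#' Generate a synthetic uptake dataset
#'
#' Draws concentration-rate data from a Hill or Michaelis-Menten curve with
#' multiplicative Gaussian noise, `v = model(C) * (1 + eps)`,
#' `eps ~ N(0, noise_cv_rate)`, with `spec$n_replicates` replicates per
#' concentration. Optionally appends mock-background rows (constant mean
#' rate, same noise model) flagged `construct = "mock"` via the returned
#' `mock` element.
#'
#' @param model `"hill"` or `"mm"`.
#' @param params Named list: `vmax`, `ec50` (or `km`), and `n` for the Hill
#'   model.
#' @param concentrations Concentration grid.
#' @param spec A [simulation_spec()] (supplies noise CV, replicates, seed).
#' @param mock_mean Mean mock-cell background rate; when > 0 a matching
#'   mock dataset is generated.
#' @param conc_unit Concentration unit label.
#' @return A list: `data` (an [uptake_dataset()], attribute `params_true`),
#'   and `mock` (an `uptake_dataset` or NULL).
#' @export
gen_uptake_dataset <- function(model = c("hill", "mm"), params,
                               concentrations, spec, mock_mean = 0,
                               conc_unit = "mM") {
  model <- match.arg(model)
  stopifnot(inherits(spec, "simulation_spec"))
  vmax <- params$vmax
  khalf <- if (!is.null(params$ec50)) params$ec50 else params$km
  n <- if (model == "hill") params$n else 1
  if (is.null(vmax) || is.null(khalf) || (model == "hill" && is.null(params$n)))
    stop("'params' must supply vmax, ec50/km and (for hill) n")
  conc <- rep(concentrations, each = spec$n_replicates)
  repl <- rep(seq_len(spec$n_replicates), times = length(concentrations))
  truth <- vmax * conc^n / (khalf^n + conc^n)
  set.seed(child_seed(spec$seed, 1L))
  eps <- if (spec$noise_cv_rate > 0)
    stats::rnorm(length(conc), sd = spec$noise_cv_rate) else 0
  # measured sample rates include any nonspecific background; the analysis
  # removes it again via subtract_background()
  data <- uptake_dataset(conc, truth * (1 + eps) + mock_mean, replicate = repl,
                         conc_unit = conc_unit,
                         varied_species = if (model == "hill") "Na" else "Cl")
  attr(data, "params_true") <- list(vmax = vmax, khalf = khalf, n = n)
  mock <- NULL
  if (mock_mean > 0) {
    set.seed(child_seed(spec$seed, 2L))
    eps_m <- if (spec$noise_cv_rate > 0)
      stats::rnorm(length(conc), sd = spec$noise_cv_rate) else 0
    mock <- uptake_dataset(conc, rep(mock_mean, length(conc)) * (1 + eps_m),
                           replicate = repl,
                           conc_unit = conc_unit, construct = "mock",
                           varied_species = attr(data, "varied_species"))
  }
  list(data = data, mock = mock)
}
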