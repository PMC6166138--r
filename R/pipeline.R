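#' Run the end-to-end stoichiometry analysis pipeline
#'
#' Strings the analysis stages together per construct — uptake kinetics
#' (background subtraction, Hill fit of the Na+ dependence, Michaelis-Menten
#' fit of the Cl- dependence), reversal-potential slope analysis with
#' sodium-coupling inference, charge-to-flux estimation, and I/V
#' rectification — and assembles a stoichiometry report with full
#' provenance (inputs, seed, config hash).
#'
#' @param config A configuration list, or path to a YAML/JSON file. Top
#'   level: `seed`, `temperature_c`, optional `constants` and `conditions`
#'   overrides, and `constructs`, a named list of per-construct blocks.
#'   Each construct block names its assumed `stoichiometry`
#'   (`n_na`, `n_cl`) and either a `simulate` block (sub-blocks `erev`,
#'   `charge_flux`, `iv`, `uptake_na`, `uptake_cl`; see the synthetic
#'   generators) or a `files` block (`erev_csv`, `iv_csv`, `uptake_na_csv`,
#'   `uptake_cl_csv`).
#' @param out_json Optional path; when given, the report is also written as
#'   machine-readable JSON.
#' @return An object of class `stoichiometry_report`.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML/JSON file path")
  if (is.null(config$constructs) || !length(config$constructs))
    stop("config must name at least one construct under 'constructs'")
  if (is.null(config$seed)) stop("config must supply a 'seed'")

  temperature_c <- config$temperature_c %||% 18
  consts <- do.call(phys_constants, as.list(config$constants %||% list()))
  base_cond <- do.call(ion_conditions, c(
    as.list(config$conditions %||%
              list(na_o = 100, cl_o = 100, gly_o = 1)),
    if (is.null(config$conditions$temperature_c))
      list(temperature_c = temperature_c)))

  blocks <- lapply(names(config$constructs), function(nm) {
    analyze_construct(nm, config$constructs[[nm]], base_cond, consts,
                      temperature_c, as.integer(config$seed))
  })
  names(blocks) <- names(config$constructs)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  report <- structure(list(
    constructs = blocks,
    provenance = list(seed = as.integer(config$seed),
                      temperature_c = temperature_c,
                      config_hash = unname(tools::md5sum(tf)),
                      inputs = pipeline_inputs(config))),
    class = "stoichiometry_report")
  unlink(tf)
  if (!is.null(out_json)) write_report_json(report, out_json)
  report
}

pipeline_inputs <- function(config) {
  files <- unlist(lapply(config$constructs, function(b) b$files), use.names = TRUE)
  if (is.null(files)) "simulation only" else as.list(files)
}

# one construct: run whichever stages its block configures
analyze_construct <- function(name, block, base_cond, consts,
                              temperature_c, seed) {
  if (is.null(block$stoichiometry))
    stop(sprintf("construct '%s': missing 'stoichiometry' (n_na, n_cl)", name))
  stoich <- stoichiometry(block$stoichiometry$n_na, block$stoichiometry$n_cl)
  z <- net_charge(stoich)
  sim <- block$simulate
  files <- block$files
  spec <- simulation_spec(
    stoich, base_cond,
    noise_sd_current = sim$noise_sd_current %||% 0,
    noise_sd_erev = sim$erev$noise_sd_erev %||% 0,
    noise_cv_rate = sim$noise_cv_rate %||% 0,
    n_replicates = sim$n_replicates %||% 3L,
    seed = seed)
  out <- list(stoichiometry_assumed = list(n_na = stoich$n_na,
                                           n_cl = stoich$n_cl, z_t = z),
              warnings = character())
  note <- function(msg) out$warnings <<- c(out$warnings, msg)

  # reversal-potential slope and sodium-coupling inference
  series <- NULL
  if (!is.null(files$erev_csv)) series <- read_reversal_series(files$erev_csv)
  else if (!is.null(sim$erev))
    series <- gen_erev_series(spec, unlist(sim$erev$na_o_list),
                              n_oocytes = sim$erev$n_oocytes %||% 8L)
  if (!is.null(series)) {
    per <- fit_reversal_per_oocyte(series)
    pooled <- fit_reversal_series(series)
    out$erev_slope <- list(mean_slope_mV_per_decade = per$mean_slope,
                           se_mean = per$se_mean,
                           n_oocytes = per$n_oocytes,
                           pooled_slope = pooled$slope,
                           pooled_r_squared = pooled$r_squared)
    out$n_na_inferred <- infer_n_na(per$mean_slope, z, temperature_c, consts)
  }

  # charge-to-flux
  if (!is.null(sim$charge_flux)) {
    cf <- sim$charge_flux
    n_rep <- cf$n_repeats %||% spec$n_replicates
    ratios <- vapply(seq_len(n_rep), function(u) {
      ex <- gen_charge_flux_experiment(
        spec, transport_rate = cf$transport_rate,
        duration = cf$duration %||% 60,
        specific_activity = cf$specific_activity %||% 0.4,
        unit = u)
      q <- integrate_charge(ex$trace)
      m <- moles_from_tracer(ex$dpm_sample, ex$dpm_background,
                             ex$specific_activity)
      charge_to_flux(q, m, consts)$ratio
    }, numeric(1))
    out$charge_to_flux <- list(
      mean_ratio = mean(ratios),
      sem = if (n_rep > 1L) stats::sd(ratios) / sqrt(n_rep) else 0,
      n = n_rep)
  }

  # I/V curve: rectification and (when present) reversal
  iv <- NULL
  if (!is.null(files$iv_csv)) iv <- read_iv_csv(files$iv_csv)
  else if (!is.null(sim$iv))
    iv <- gen_iv_family(spec, sim$iv$na_o %||% base_cond$na_o)[[1L]]
  if (!is.null(iv)) {
    out$rectification_degree <- rectification_degree(iv)
    out$e_rev_mV <- tryCatch(estimate_erev(iv), error = function(e) {
      note(paste0("I/V: ", conditionMessage(e)))
      NA_real_
    })
  }

  # uptake kinetics
  load_uptake <- function(file_key, sim_key, model) {
    bundle <- NULL
    if (!is.null(files[[file_key]])) bundle <- read_uptake_csv(files[[file_key]])
    else if (!is.null(sim[[sim_key]])) {
      s <- sim[[sim_key]]
      bundle <- gen_uptake_dataset(model, params = s,
                                   concentrations = unlist(s$concentrations),
                                   spec = spec,
                                   mock_mean = s$mock_mean %||% 0,
                                   conc_unit = s$conc_unit %||% "mM")
    }
    if (is.null(bundle)) return(NULL)
    d <- bundle$data
    if (!is.null(bundle$mock)) {
      d <- withCallingHandlers(subtract_background(d, bundle$mock),
                               warning = function(w) {
                                 note(conditionMessage(w))
                                 invokeRestart("muffleWarning")
                               })
    }
    d
  }
  d_na <- load_uptake("uptake_na_csv", "uptake_na", "hill")
  if (!is.null(d_na)) {
    hf <- fit_hill(d_na)
    if (isTRUE(hf$saturation_warning))
      note("Na+ uptake: saturation not approached within tested range")
    out$hill_na <- list(vmax = hf$vmax, ec50 = hf$ec50, ec50_se = hf$ec50_se,
                        n_hill = hf$n_hill, n_hill_se = hf$n_hill_se,
                        r_squared = hf$r_squared,
                        conc_unit = hf$conc_unit, n_obs = hf$n_obs)
  }
  d_cl <- load_uptake("uptake_cl_csv", "uptake_cl", "mm")
  if (!is.null(d_cl)) {
    mf <- fit_mm(d_cl)
    eff <- transport_efficiency(mf)
    out$mm_cl <- list(vmax = mf$vmax, vmax_se = mf$vmax_se,
                      km = mf$km, km_se = mf$km_se,
                      efficiency = eff$estimate, efficiency_se = eff$se,
                      r_squared = mf$r_squared,
                      conc_unit = mf$conc_unit, n_obs = mf$n_obs)
  }
  out
}

#' Write a stoichiometry report as JSON
#'
#' @param report A `stoichiometry_report` from [run_pipeline()].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "stoichiometry_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  cat("Stoichiometry report\n")
  cat(sprintf("  seed %d, %.1f C, config %s\n",
              x$provenance$seed, x$provenance$temperature_c,
              x$provenance$config_hash))
  for (nm in names(x$constructs)) {
    b <- x$constructs[[nm]]
    cat(sprintf("\n== %s (assumed %gNa:%gCl:1, z_T = %+g) ==\n", nm,
                b$stoichiometry_assumed$n_na, b$stoichiometry_assumed$n_cl,
                b$stoichiometry_assumed$z_t))
    if (!is.null(b$erev_slope))
      cat(sprintf("  E_rev slope: %.2f +/- %.2f mV/decade (n = %d oocytes); inferred n_Na = %.2f\n",
                  b$erev_slope$mean_slope_mV_per_decade, b$erev_slope$se_mean,
                  b$erev_slope$n_oocytes, b$n_na_inferred))
    if (!is.null(b$charge_to_flux))
      cat(sprintf("  charge-to-flux: %.2f +/- %.2f charges/molecule (n = %d)\n",
                  b$charge_to_flux$mean_ratio, b$charge_to_flux$sem,
                  b$charge_to_flux$n))
    if (!is.null(b$rectification_degree))
      cat(sprintf("  rectification degree: %.2f; E_rev %s mV\n",
                  b$rectification_degree,
                  ifelse(is.na(b$e_rev_mV), "not reached",
                         sprintf("%.1f", b$e_rev_mV))))
    if (!is.null(b$hill_na))
      cat(sprintf("  Na+ Hill fit: EC50 %.3g %s, n = %.2f (R^2 %.3f)\n",
                  b$hill_na$ec50, b$hill_na$conc_unit, b$hill_na$n_hill,
                  b$hill_na$r_squared))
    if (!is.null(b$mm_cl))
      cat(sprintf("  Cl- MM fit: Km %.3g %s, Vmax %.3g, Vmax/Km %.3g (R^2 %.3f)\n",
                  b$mm_cl$km, b$mm_cl$conc_unit, b$mm_cl$vmax,
                  b$mm_cl$efficiency, b$mm_cl$r_squared))
    if (length(b$warnings))
      cat("  notes:", paste(b$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}
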