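# shared fixtures: canonical stoichiometries and a one-decade Na+ gradient
glyt2_stoich <- stoichiometry(3, 1)
glyt1_stoich <- stoichiometry(2, 1)

# external Na+ one decade above internal, Cl- and substrate symmetric:
# isolates the pure sodium term of the reversal-potential model
decade_cond <- ion_conditions(na_o = 100, cl_o = 40, gly_o = 10,
                              na_i = 10, cl_i = 40, gly_i = 10,
                              temperature_c = 18)

# closed-form OLS slope, independent of stats::lm
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

make_spec <- function(stoich = glyt2_stoich, cond = decade_cond, seed = 1, ...) {
  simulation_spec(stoich, cond, seed = seed, ...)
}

run_charge_flux_chain <- function(spec, transport_rate = 1e-13, ...) {
  ex <- gen_charge_flux_experiment(spec, transport_rate = transport_rate, ...)
  q <- integrate_charge(ex$trace)
  m <- moles_from_tracer(ex$dpm_sample, ex$dpm_background, ex$specific_activity)
  charge_to_flux(q, m)$ratio
}
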