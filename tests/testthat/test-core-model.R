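test_that("reversal potential is zero for symmetric gradients and flips sign under side swap", {
  sym <- ion_conditions(na_o = 100, cl_o = 40, gly_o = 10,
                        na_i = 100, cl_i = 40, gly_i = 10)
  expect_equal(reversal_potential(glyt2_stoich, sym), 0)

  set.seed(42)
  for (i in 1:25) {
    cond <- ion_conditions(na_o = runif(1, 1, 150), cl_o = runif(1, 1, 150),
                           gly_o = runif(1, 0.1, 20), na_i = runif(1, 1, 50),
                           cl_i = runif(1, 1, 80), gly_i = runif(1, 0.1, 20),
                           temperature_c = runif(1, 0, 45))
    st <- stoichiometry(sample(0:4, 1), sample(0:4, 1))
    if (net_charge(st) == 0) next
    expect_equal(reversal_potential(st, swap_sides(cond)),
                 -reversal_potential(st, cond))
  }
})

test_that("one decade of external Na+ gives the hand-computed potential", {
  # 2.3 * 8.314 * 291.15 / 96485 * 1000 = 57.70 mV per decade-equivalent;
  # times n_na/z_t = 3/2 for the 3Na:1Cl cycle
  expect_equal(reversal_potential(glyt2_stoich, decade_cond),
               2.3 * 8.314 * 291.15 / 96485 * 1000 * 1.5, tolerance = 1e-12)
  expect_equal(reversal_potential(glyt2_stoich, decade_cond), 86.55,
               tolerance = 1e-4)
})

test_that("electroneutral stoichiometry and bad concentrations are rejected", {
  neutral <- stoichiometry(1, 1)
  expect_error(reversal_potential(neutral, decade_cond), "undefined")
  expect_error(slope_per_decade(neutral), "undefined")
  expect_error(infer_n_na(86.5, z_t = 0), "nonzero")
  expect_error(ion_conditions(na_o = 0, cl_o = 40, gly_o = 10), "positive")
  expect_error(ion_conditions(na_o = 100, cl_o = 40, gly_o = 10,
                              temperature_c = 60), "temperature")
})

test_that("slope predictions at 18 C match the thermodynamic model", {
  expect_equal(slope_per_decade(glyt2_stoich, 18), 86.55, tolerance = 1e-4)
  expect_equal(slope_per_decade(glyt1_stoich, 18), 115.41, tolerance = 1e-4)
})

test_that("slope inversion recovers n_Na and is exact as a round trip", {
  expect_equal(infer_n_na(86.49, z_t = 2, temperature_c = 18), 2.99,
               tolerance = 0.005)
  expect_equal(infer_n_na(113.50, z_t = 1, temperature_c = 18), 1.97,
               tolerance = 0.005)
  for (n_na in c(1, 2, 3, 4)) {
    for (temp in c(0, 18, 37, 45)) {
      st <- stoichiometry(n_na, 0.5) # any nonzero net charge
      expect_equal(infer_n_na(slope_per_decade(st, temp), net_charge(st), temp),
                   n_na, tolerance = 1e-12)
    }
  }
})

test_that("decade identity: E_T at 10x Na+ minus E_T equals the slope per decade", {
  for (st in list(glyt2_stoich, glyt1_stoich, stoichiometry(4, 1))) {
    c1 <- ion_conditions(na_o = 12, cl_o = 40, gly_o = 10, temperature_c = 25)
    c10 <- ion_conditions(na_o = 120, cl_o = 40, gly_o = 10, temperature_c = 25)
    expect_equal(reversal_potential(st, c10) - reversal_potential(st, c1),
                 slope_per_decade(st, 25), tolerance = 1e-12)
  }
})

test_that("slope per decade increases strictly with temperature", {
  temps <- seq(0, 45, by = 5)
  slopes <- vapply(temps, function(tc) slope_per_decade(glyt2_stoich, tc),
                   numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("fitting a noiseless model series returns the exact slope with R^2 = 1", {
  na <- c(20, 40, 60, 80, 100)
  er <- vapply(na, function(x) {
    cond <- decade_cond
    cond$na_o <- x
    reversal_potential(glyt2_stoich, cond)
  }, numeric(1))
  fit <- fit_reversal_series(data.frame(na_o_mM = na, e_rev_mV = er))
  expect_equal(fit$slope, slope_per_decade(glyt2_stoich, 18), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 5L)
})

test_that("a two-point series gives the expected line", {
  fit <- fit_reversal_series(data.frame(na_o_mM = c(10, 100),
                                        e_rev_mV = c(0, 86.5)))
  expect_equal(fit$slope, 86.5)
  expect_equal(fit$intercept, -86.5)
})

test_that("degenerate reversal series are rejected", {
  expect_error(fit_reversal_series(data.frame(na_o_mM = c(50, 50),
                                              e_rev_mV = c(1, 2))),
               "distinct")
  expect_error(fit_reversal_series(data.frame(na_o_mM = c(-1, 100),
                                              e_rev_mV = c(0, 1))))
  expect_error(fit_reversal_series(data.frame(x = 1:3)), "na_o_mM")
})

test_that("noisy synthetic series recover the model slope within 2 SE", {
  spec <- make_spec(noise_sd_erev = 5, seed = 101)
  series <- gen_erev_series(spec, c(20, 40, 60, 80, 100), n_oocytes = 8)
  per <- fit_reversal_per_oocyte(series)
  expect_equal(per$n_oocytes, 8L)
  expect_lt(abs(per$mean_slope - slope_per_decade(glyt2_stoich, 18)),
            2 * per$se_mean)
})
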