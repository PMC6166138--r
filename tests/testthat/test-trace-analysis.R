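protocol_grid <- seq(-150, 30, by = 20)

test_that("evoked I/V is the pointwise difference with SEMs in quadrature", {
  v <- protocol_grid
  with_gly <- iv_curve(v, -0.5 * v - 40, sem_nA = 3)
  bg <- iv_curve(v, -0.1 * v, sem_nA = 4)
  ev <- evoked_iv(with_gly, bg)
  expect_equal(ev$current_nA, -0.4 * v - 40)
  expect_equal(ev$sem_nA, rep(5, length(v)))

  zero <- iv_curve(v, rep(0, length(v)))
  expect_equal(evoked_iv(with_gly, zero)$current_nA, with_gly$current_nA)
  expect_equal(evoked_iv(with_gly, with_gly)$current_nA, rep(0, length(v)))
  expect_error(evoked_iv(with_gly, iv_curve(v + 5, v)), "grids differ")
})

test_that("normalization pins the reference current to -1 and is idempotent", {
  v <- protocol_grid
  iv <- iv_curve(v, 0.45 * v) # linear through origin, -67.5 nA at -150 mV
  nz <- normalize_iv(iv)
  expect_equal(nz$current_nA[nz$potential_mV == -150], -1)
  expect_equal(nz$current_nA, 0.45 * v / 67.5)
  expect_equal(normalize_iv(nz)$current_nA, nz$current_nA)
  expect_error(normalize_iv(iv, reference_potential = -155), "not on the")
  expect_error(normalize_iv(iv_curve(c(-150, 0, 30, 50), c(0, 1, 2, 3))),
               "zero")
})

test_that("reversal potential is interpolated from the single zero crossing", {
  expect_equal(estimate_erev(iv_curve(c(-10, 10), c(-5, 5))), 0)
  # asymmetric bracket: crossing at -30 + 20 * 3/8
  expect_equal(estimate_erev(iv_curve(c(-30, -10), c(-3, 5))), -22.5)
  expect_error(estimate_erev(iv_curve(protocol_grid,
                                      -10 + 0.02 * protocol_grid)),
               "does not reverse")
  wobbly <- iv_curve(c(-60, -40, -20, 0), c(-1, 1, -1, 1))
  expect_error(estimate_erev(wobbly), "more than once")
})

test_that("generated I/V curves reverse at the thermodynamic potential", {
  # reduced driving force (low external substrate) so E_T lies inside the
  # -150..+30 mV protocol, as in the reversal-potential experiments
  weak_drive <- ion_conditions(na_o = 100, cl_o = 40, gly_o = 1,
                               temperature_c = 18)
  spec <- make_spec(cond = weak_drive)
  for (na in c(12, 20, 30, 40)) {
    iv <- gen_iv_family(spec, na)[[1]]
    # off-grid reversal: linear interpolation of the rectifying (curved)
    # I/V is accurate to well under a sixth of the 20-mV step
    expect_lt(abs(estimate_erev(iv) - attr(iv, "e_rev_true_mV")), 3)
  }

  # reversal placed exactly on a grid point is recovered exactly
  on_grid <- 10 * 10^(-30 / slope_per_decade(glyt2_stoich, 18))
  iv30 <- gen_iv_family(make_spec(), on_grid)[[1]]
  expect_equal(attr(iv30, "e_rev_true_mV"), -30, tolerance = 1e-9)
  expect_lt(abs(estimate_erev(iv30) - (-30)), 0.5)
})

test_that("rectification degree is 1 for affine curves and scale-invariant", {
  v <- protocol_grid
  lin <- iv_curve(v, 0.3 * v - 12)
  expect_equal(rectification_degree(lin), 1.0, tolerance = 1e-12)

  cubic <- iv_curve(v, 0.2 * v + 1e-5 * v^3)
  neg <- head(order(v), 3); pos <- tail(order(v), 3)
  oracle <- ols_slope(v[neg], cubic$current_nA[neg]) /
    ols_slope(v[pos], cubic$current_nA[pos])
  expect_equal(rectification_degree(cubic), oracle, tolerance = 1e-12)
  expect_equal(rectification_degree(iv_curve(v, 17 * cubic$current_nA)),
               oracle, tolerance = 1e-12)
})

test_that("a 4x steeper hyperpolarized limb gives rectification degree 4", {
  v <- protocol_grid
  i <- ifelse(v < -50, 0.8 * (v + 50), 0.2 * (v + 50))
  expect_equal(rectification_degree(iv_curve(v, i)), 4.0, tolerance = 1e-12)
  flat_pos <- ifelse(v < -50, 0.8 * (v + 50), 0)
  expect_warning(r <- rectification_degree(iv_curve(v, flat_pos)), "infinite")
  expect_identical(r, Inf)
})

test_that("charge integration matches closed forms and is additive and linear", {
  t <- seq(0, 75, by = 1e-3)
  rect <- current_trace(t, ifelse(t >= 10 & t <= 70, -100, 0),
                        window = c(10, 70))
  q <- integrate_charge(rect)
  expect_equal(q$magnitude_c, 6.0e-6, tolerance = 1e-12)
  expect_lt(q$charge_c, 0)
  expect_equal(q$baseline_nA, 0)

  flat <- current_trace(t, rep(-3, length(t)), window = c(10, 70))
  expect_equal(integrate_charge(flat)$charge_c, 0) # baseline removes holding current

  # ramp from 0 at t=10 to -60 at t=70: triangle area 0.5*60*60 nA s
  ramp_i <- ifelse(t >= 10 & t <= 70, -(t - 10), 0)
  ramp <- current_trace(t, ramp_i, window = c(10, 70))
  expect_equal(integrate_charge(ramp)$magnitude_c, 0.5 * 60 * 60 * 1e-9,
               tolerance = 1e-12)

  q1 <- integrate_charge(ramp, c(10, 40))$charge_c
  q2 <- integrate_charge(ramp, c(40, 70))$charge_c
  expect_equal(q1 + q2, integrate_charge(ramp)$charge_c, tolerance = 1e-12)

  scaled <- current_trace(t, 2.5 * ramp_i, window = c(10, 70))
  expect_equal(integrate_charge(scaled)$charge_c,
               2.5 * integrate_charge(ramp)$charge_c, tolerance = 1e-12)

  expect_error(integrate_charge(ramp, c(-5, 70)), "outside")
})

test_that("tracer counts convert to moles through the specific activity", {
  expect_equal(moles_from_tracer(500, 500, 0.4), 0)
  expect_equal(moles_from_tracer(8.88e5, 0, 0.4), 1.0e-9, tolerance = 1e-12)
  expect_equal(moles_from_tracer(8.88e5, 0, 0.8),
               moles_from_tracer(8.88e5, 0, 0.4) / 2)
  expect_error(moles_from_tracer(100, 200, 0.4), "exceed")
  expect_error(moles_from_tracer(100, 0, 0), "specific_activity")
})

test_that("charge-to-flux returns charges per molecule by construction", {
  f <- phys_constants()$faraday
  m <- 3.2e-11
  expect_equal(charge_to_flux(-2 * f * m, m)$ratio, 2.0, tolerance = 1e-12)
  expect_equal(charge_to_flux(f * m, m)$ratio, 1.0, tolerance = 1e-12)
  expect_error(charge_to_flux(1e-6, 0), "moles_substrate")
})

test_that("the noiseless synthetic chain returns the generating net charge", {
  for (case in list(list(s = glyt2_stoich, z = 2),
                    list(s = glyt1_stoich, z = 1),
                    list(s = stoichiometry(4, 1), z = 3))) {
    for (dur in c(30, 60)) {
      spec <- make_spec(stoich = case$s)
      ratio <- run_charge_flux_chain(spec, transport_rate = 2e-13,
                                     duration = dur)
      expect_equal(ratio, case$z, tolerance = 1e-6)
    }
  }
})
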