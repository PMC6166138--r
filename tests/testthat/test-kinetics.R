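hill_curve <- function(conc, vmax, ec50, n) vmax * conc^n / (ec50^n + conc^n)
log_grid <- function(n, from = 1, to = 300) exp(seq(log(from), log(to), length.out = n))

test_that("background subtraction is exact arithmetic and preserves grids", {
  s <- uptake_dataset(c(10, 10, 50, 50), c(5.0, 5.2, 8.0, 8.4), conc_unit = "uM")
  zero_mock <- uptake_dataset(c(10, 50), c(0, 0), conc_unit = "uM")
  expect_equal(subtract_background(s, zero_mock)$rate, s$rate)

  flat <- uptake_dataset(c(10, 10, 50, 50), c(5.0, 5.0, 8.0, 8.0),
                         conc_unit = "uM")
  self_sub <- subtract_background(flat, flat)
  expect_equal(self_sub$rate, rep(0, 4))
  expect_true(attr(self_sub, "background_subtracted"))
  expect_equal(attr(self_sub, "n_clipped"), 0L)

  m <- uptake_dataset(c(10, 50), c(1.2, 2.0), conc_unit = "uM")
  expect_equal(subtract_background(s, m)$rate[1], 3.8)

  expect_error(subtract_background(s, uptake_dataset(c(10, 60), c(1, 1))),
               "grids differ.*60")
})

test_that("rates driven negative by subtraction are clipped with a count", {
  s <- uptake_dataset(c(1, 2), c(0.5, 3))
  m <- uptake_dataset(c(1, 2), c(1.0, 1.0))
  expect_warning(out <- subtract_background(s, m), "1 .*clipped")
  expect_equal(out$rate, c(0, 2))
  expect_equal(attr(out, "n_clipped"), 1L)
})

test_that("Hill fit recovers generating parameters exactly on noiseless data", {
  conc <- log_grid(8, 2, 400)
  d <- uptake_dataset(conc, hill_curve(conc, vmax = 1, ec50 = 50, n = 2))
  fit <- fit_hill(d)
  expect_equal(fit$vmax, 1, tolerance = 1e-6)
  expect_equal(fit$ec50, 50, tolerance = 1e-6)
  expect_equal(fit$n_hill, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # half-saturation identity of the fitted curve
  expect_equal(predict(fit, fit$ec50), fit$vmax / 2, tolerance = 1e-12)
})

test_that("Michaelis-Menten fit recovers Table-style kinetic parameters exactly", {
  conc <- log_grid(10, 10, 2000)
  d <- uptake_dataset(conc, hill_curve(conc, 32.5, 133.5, 1), conc_unit = "uM")
  fit <- fit_mm(d)
  expect_equal(fit$vmax, 32.5, tolerance = 1e-8)
  expect_equal(fit$km, 133.5, tolerance = 1e-8)
  expect_equal(predict(fit, fit$km), fit$vmax / 2, tolerance = 1e-12)
  # a free-exponent Hill fit on the same data finds n ~ 1
  expect_equal(fit_hill(d)$n_hill, 1, tolerance = 1e-4)
})

test_that("transport efficiency is Vmax/Km with sensible propagation", {
  conc <- log_grid(10, 10, 2000)
  fit <- fit_mm(uptake_dataset(conc, hill_curve(conc, 32.5, 133.5, 1),
                               conc_unit = "uM"))
  eff <- transport_efficiency(fit)
  expect_equal(eff$estimate, 32.5 / 133.5, tolerance = 1e-8)
  expect_equal(round(eff$estimate, 2), 0.24)

  fit2 <- fit
  fit2$vmax <- 2 * fit$vmax
  fit2$km <- fit$km
  expect_equal(transport_efficiency(fit2)$estimate, 2 * eff$estimate)
  fit3 <- fit
  fit3$vmax <- fit3$km
  expect_equal(transport_efficiency(fit3)$estimate, 1.0)
})

test_that("Hill SSE never exceeds Michaelis-Menten SSE and scaling acts only on Vmax", {
  set.seed(7)
  conc <- log_grid(9, 1, 500)
  for (i in 1:5) {
    rate <- hill_curve(conc, 10, 80, 1.4) * (1 + rnorm(length(conc), sd = 0.08))
    d <- uptake_dataset(conc, rate)
    expect_lte(fit_hill(d)$sse, fit_mm(d)$sse + 1e-9)

    k <- 3.7
    f1 <- fit_hill(d)
    f2 <- fit_hill(uptake_dataset(conc, k * rate))
    expect_equal(f2$vmax, k * f1$vmax, tolerance = 1e-4)
    expect_equal(f2$ec50, f1$ec50, tolerance = 1e-4)
    expect_equal(f2$n_hill, f1$n_hill, tolerance = 1e-4)
  }
})

test_that("Vmax-normalized rates give a fitted Vmax of about 1", {
  conc <- log_grid(10, 2, 400)
  rate <- hill_curve(conc, 1, 65.5, 1.63)
  expect_equal(fit_hill(uptake_dataset(conc, rate))$vmax, 1, tolerance = 1e-6)
})

test_that("noisy Hill data recover EC50 within 15 percent", {
  spec <- make_spec(noise_cv_rate = 0.05, n_replicates = 3, seed = 11)
  bundle <- gen_uptake_dataset("hill",
                               params = list(vmax = 2.0, ec50 = 65.5, n = 1.63),
                               concentrations = log_grid(12, 2, 300),
                               spec = spec)
  fit <- fit_hill(bundle$data)
  expect_lt(abs(fit$ec50 - 65.5) / 65.5, 0.15)
  expect_gt(fit$r_squared, 0.9)
})

test_that("underdetermined or flat uptake data are rejected, shallow data flagged", {
  expect_error(fit_hill(uptake_dataset(c(1, 2, 3), c(1, 2, 3))), "4 distinct")
  expect_error(fit_hill(uptake_dataset(1:5, rep(2, 5))), "all equal")
  # curve nearly flat over the tested range: top below twice the lowest rate
  conc <- c(50, 100, 200, 400)
  shallow <- uptake_dataset(conc, hill_curve(conc, 100, 5, 1))
  expect_true(fit_mm(shallow)$saturation_warning)
})
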