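test_that("Cp polynomial integral matches closed forms and quadrature", {
  # constant Cp: 100 J/(K mol) over 46.35 K is 4.635 kJ/mol
  expect_equal(cp_integral(cp_polynomial(100), 298.15, 344.5), 4.635)
  expect_equal(cp_integral(cp_polynomial(100), 320, 320), 0)

  # quadratic polynomial against numerical quadrature
  p <- cp_polynomial(c(15, 0.22, 3e-4), scale = 0.965, range = c(260, 420))
  num <- stats::integrate(function(T) cp_value(p, T), 300, 400)$value / 1000
  expect_equal(cp_integral(p, 300, 400), num, tolerance = 1e-9)

  # additive over adjacent intervals
  expect_equal(cp_integral(p, 300, 350) + cp_integral(p, 350, 400),
               cp_integral(p, 300, 400))

  expect_error(cp_integral(p, 200, 300), "validity range")
  expect_error(cp_polynomial(c(-5, 0)), "non-positive")
})

test_that("synthetic Cp fixtures reproduce the published corrections", {
  p1 <- synthetic_cp_polynomial("furfurylamine")
  p2 <- synthetic_cp_polynomial("5-methylfurfurylamine")
  expect_equal(cp_integral(p1, 298.15, 344.5), 5.4, tolerance = 1e-6)
  expect_equal(cp_integral(p2, 298.15, 339.9), 6.0, tolerance = 1e-6)
  expect_equal(correct_to_reference_T(54.5, p1, 344.5), 49.1, tolerance = 1e-6)
  expect_equal(correct_to_reference_T(59.3, p2, 339.9), 53.3, tolerance = 1e-6)
  # zero integral leaves the observation unchanged
  expect_equal(correct_to_reference_T(54.5, p1, 298.15 + 1e-9), 54.5,
               tolerance = 1e-6)
  # linear in the observed enthalpy
  expect_equal(correct_to_reference_T(60, p1, 344.5) -
                 correct_to_reference_T(50, p1, 344.5), 10)
  # the JSON fixture on disk matches the built-in polynomial
  path <- system.file("extdata", "cp_furfurylamine_synthetic.json",
                      package = "thermoredux")
  expect_equal(read_cp_polynomial(path)$coef, p1$coef)
})

test_that("in-situ calibration constant is the literature/observed ratio", {
  expect_equal(calvet_calibration(c(51.4, 51.4), 51.4)$k, 1)
  # observations biased +2 percent
  obs <- 51.42 * 1.02 + c(0, 0, 0)
  k <- calvet_calibration(obs, 51.42)$k
  expect_equal(k, 1 / 1.02, tolerance = 1e-9)
  expect_error(calvet_calibration(54.5, 51.4), "at least 2")
  expect_warning(calvet_calibration(c(60, 60.2), 51.4), "outside")
})

test_that("drop-run reduction round-trips a known vaporization enthalpy", {
  p <- synthetic_cp_polynomial("furfurylamine")
  runs0 <- generate_calvet_runs(noise_sd = 0, seed = 2)
  res0 <- reduce_calvet(runs0, p)
  expect_equal(res0$dvapH$value, 49.1, tolerance = 1e-9)
  expect_equal(res0$dH_at_T$u, 0, tolerance = 1e-12)

  set.seed(31)
  runs <- generate_calvet_runs(noise_sd = 0.98, seed = 31)
  res <- reduce_calvet(runs, p)
  expect_equal(res$n_runs, 6)
  sdom <- sd(runs$dH_obs) / sqrt(6)
  expect_equal(res$dH_at_T$u, sdom)
  expect_equal(res$dvapH$u, 2 * sdom)  # no calibration contribution, k exact
  expect_equal(res$dvapH$value, mean(runs$dH_obs) - 5.4, tolerance = 1e-6)

  expect_error(reduce_calvet(runs[1, ], p), "at least 2")
  mixed <- dplyr::mutate(runs, T_oven = 344.5 + run)
  expect_error(reduce_calvet(mixed, p), "mixed oven temperatures")

  gl <- glance(res)
  expect_equal(gl$cp_correction, 5.4, tolerance = 1e-6)
  expect_equal(nrow(tidy(res)), 6)
})

test_that("calibration constant propagates into the reduced result", {
  p <- synthetic_cp_polynomial("furfurylamine")
  runs <- generate_calvet_runs(noise_sd = 0, seed = 8)
  biased <- dplyr::mutate(runs, dH_obs = dH_obs * 1.02)
  cal <- calvet_calibration(c(51.42, 51.42) * 1.02, 51.42)
  res <- reduce_calvet(biased, p, calibration = cal)
  expect_equal(res$dvapH$value, 49.1, tolerance = 1e-9)
})
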