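test_that("ignition energy follows the capacitor discharge formula", {
  expect_equal(ignition_energy(1400e-6, 40, 40), 0)
  expect_equal(ignition_energy(1400e-6, 40, 20), 0.84)
  expect_error(ignition_energy(1400e-6, 20, 40), "inconsistent record")
})

test_that("isothermal bomb process energy matches direct evaluation", {
  expect_equal(energy_ipb(15907.1, 0, du_ign = 0), 0)
  expect_equal(energy_ipb(15907.1, 1.2, du_ign = 0.8, eps_f = 16.0),
               -(15907.1 + 16.0) * 1.2 + 0.8)
  expect_equal(round(energy_ipb(15907.1, 1.2, du_ign = 0.8, eps_f = 16.0), 1),
               -19106.9)
  # linearity in the temperature rise
  expect_equal(energy_ipb(15907.1, 2.4, eps_f = 16),
               2 * energy_ipb(15907.1, 1.2, eps_f = 16))
  # water-mass deviation term
  expect_equal(energy_ipb(15000, 1, dm_h2o = 10, cp_water = 4.184),
               -(15000 + 41.84))
})

test_that("Regnault-Pfaundler extraction recovers a known adiabatic rise", {
  tr <- simulate_trace(delta_T_ad = 1.2, noise_sd = 0)
  red <- reduce_trace(tr)
  expect_lt(abs(red$delta_T_ad - 1.2), 1e-4)
  expect_equal(red$cooling_constant, 1.5e-3 / 60, tolerance = 1e-3)
  expect_equal(red$T_convergence, 298.6, tolerance = 1e-4)

  # no heat exchange: plain final-minus-initial temperature
  tr0 <- simulate_trace(1.2, cooling_constant = 0, noise_sd = 0)
  expect_equal(reduce_trace(tr0)$delta_T_ad, 1.2, tolerance = 1e-9)

  # doubling the injected energy doubles the extracted rise
  red2 <- reduce_trace(simulate_trace(2.4, noise_sd = 0))
  expect_equal(red2$delta_T_ad / red$delta_T_ad, 2, tolerance = 1e-6)

  # Dickinson extrapolation agrees with Regnault-Pfaundler at this leak rate
  redd <- reduce_trace(tr, method = "dickinson")
  expect_equal(redd$delta_T_ad, 1.2, tolerance = 5e-3)

  expect_error(reduce_trace(tr[, c("time", "temperature")]),
               "incomplete record")
  expect_error(reduce_trace(tr[, c("time", "temperature")],
                            t_ignition = 10, t_after = 5),
               "non-monotone")
})

test_that("noise-free synthetic experiments round-trip the massic energy", {
  truth <- -29588
  runs <- generate_bomb_experiments(n_runs = 3, true_massic_energy = truth,
                                    noise_sd = 0, seed = 21)
  red <- reduce_bomb(runs, "C5H7NO", 15907.1)
  expect_true(all(abs(red$massic_energy - truth) / abs(truth) < 5e-4))
  expect_equal(red$co2_recovery, rep(1, 3), tolerance = 1e-12)
  expect_true(all(red$note == ""))

  # without traces the chain is algebraically exact
  runs2 <- generate_bomb_experiments(n_runs = 3, true_massic_energy = truth,
                                     noise_sd = 0, traces = FALSE, seed = 21)
  red2 <- reduce_bomb(runs2, "C5H7NO", 15907.1)
  expect_equal(red2$massic_energy, rep(truth, 3), tolerance = 1e-10)
})

test_that("sample mass can be recovered from collected CO2", {
  runs <- generate_bomb_experiments(n_runs = 2, noise_sd = 0, traces = FALSE,
                                    seed = 5)
  masked <- dplyr::mutate(runs, m_sample = NA_real_)
  red <- reduce_bomb(masked, "C5H7NO", 15907.1)
  expect_equal(red$m_sample, runs$m_sample, tolerance = 1e-10)
  expect_equal(red$massic_energy, rep(-29588.1, 2), tolerance = 1e-9)
})

test_that("corrections are individually switchable and degenerate cleanly", {
  runs <- generate_bomb_experiments(n_runs = 2, noise_sd = 0, traces = FALSE,
                                    seed = 9)
  all_off <- list(fuse = FALSE, melinex = FALSE, hno3 = FALSE,
                  standard_state = FALSE)
  red <- reduce_bomb(runs, "C5H7NO", 15907.1, corrections = all_off)
  expect_equal(red$massic_energy, red$du_ipb / red$m_sample)
  expect_equal(red$du_fuse, rep(0, 2))
  expect_equal(red$du_melinex, rep(0, 2))
  expect_equal(red$du_hno3, rep(0, 2))
  expect_equal(red$du_sigma, rep(0, 2))

  # a millimole of nitric acid contributes 59.7 J
  one <- tibble::tibble(m_sample = 0.6, m_fuse = 0, m_melinex = 0,
                        delta_T_ad = 1.2, du_ign = 0, n_hno3 = 1e-3,
                        eps_f = 0)
  with_hno3 <- reduce_bomb(one, "C5H7NO", 15907.1,
                           corrections = list(standard_state = FALSE))
  without <- reduce_bomb(one, "C5H7NO", 15907.1, corrections = all_off)
  expect_equal((with_hno3$massic_energy - without$massic_energy) * 0.6, 59.7)

  # a user-supplied standard-state hook replaces the simplified term
  hook <- function(row, m_sample) 12.34
  hooked <- reduce_bomb(one, "C5H7NO", 15907.1, washburn_hook = hook)
  expect_equal(hooked$du_sigma, 12.34)
})

test_that("out-of-window CO2 recovery is flagged, not fatal", {
  run <- tibble::tibble(m_sample = 0.6, m_fuse = 0.003, m_melinex = 0.05,
                        delta_T_ad = 1.2, du_ign = 0.8, n_hno3 = 3e-4,
                        eps_f = 16, m_co2 = 1.5)
  red <- reduce_bomb(run, "C5H7NO", 15907.1)
  expect_match(red$note, "CO2 recovery")
})

test_that("benzoic-acid calibration recovers the energy equivalent", {
  truth <- 15907.1
  runs <- generate_bomb_experiments(
    n_runs = 4, true_massic_energy = -26434, fuel = "C7H6O2",
    m_melinex_range = c(0, 0), eps_cal = truth, noise_sd = 0,
    traces = FALSE, seed = 13, dudp_sample = -0.12)
  cal <- calibrate_bomb(runs)
  expect_s3_class(cal, "bomb_calibration")
  expect_equal(cal$eps_cal$value, truth, tolerance = 1e-9)
  expect_equal(cal$eps_cal$u, 0, tolerance = 1e-7)
  expect_equal(cal$n_runs, 4)
  expect_error(calibrate_bomb(runs[1, ]), "at least 2 runs")

  # noisy traces: recovery within the scatter of the runs
  noisy <- generate_bomb_experiments(
    n_runs = 6, true_massic_energy = -26434, fuel = "C7H6O2",
    m_melinex_range = c(0, 0), eps_cal = truth, noise_sd = 1e-4,
    seed = 14, dudp_sample = -0.12)
  caln <- calibrate_bomb(noisy)
  expect_lt(abs(caln$eps_cal$value - truth), 6 * max(caln$eps_cal$u, 0.5))
  gl <- glance(caln)
  expect_equal(gl$certificate, -26434)
})
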