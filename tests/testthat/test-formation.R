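test_that("replicate statistics reproduce mean and sdom", {
  fa <- summarize_replicates(combustion_replicates("furfurylamine"))
  expect_equal(fa$n, 6)
  expect_equal(round_table(fa$mean), -29588.1)
  expect_equal(round_table(fa$sdom), 2.0)

  mf <- summarize_replicates(combustion_replicates("5-methylfurfurylamine"))
  expect_equal(mf$n, 8)
  expect_equal(round_table(mf$sdom), 3.3)

  same <- summarize_replicates(rep(-100, 5))
  expect_equal(same$sdom, 0)
  expect_error(summarize_replicates(-1), "at least 2")

  expect_named(glance(fa), c("mean", "sdom", "n", "sd"))
  expect_equal(nrow(tidy(fa)), 6)
})

test_that("expanded uncertainty follows the doubled relative RSS convention", {
  # no auxiliary components: twice the relative sdom times the value
  expect_equal(expanded_uncertainty(2873.5, 2.0 / 29588.1),
               2 * 2.0 / 29588.1 * 2873.5)
  # the budget that reproduces a 0.9 kJ/mol expanded uncertainty on 2873.5
  expect_equal(round_table(expanded_uncertainty(2873.5, 1.565e-4)), 0.9)
  # monotone: adding a component never shrinks the result
  base <- expanded_uncertainty(1000, 1e-4, c(2e-4))
  expect_gte(expanded_uncertainty(1000, 1e-4, c(2e-4, 1e-4)), base)
})

test_that("molar conversion and gas-work term reproduce the printed chain", {
  M1 <- molar_mass("C5H7NO")
  dcU1 <- molar_combustion_energy(-29588.1, M1)
  expect_equal(round_table(dcU1$value), -2873.5)
  dcH1 <- enthalpy_from_energy(dcU1, -0.75)
  expect_equal(round_table(dcH1$value), -2875.4)

  dcU2 <- molar_combustion_energy(-31577.4, molar_mass("C6H9NO"))
  dcH2 <- enthalpy_from_energy(dcU2, balance_combustion("C6H9NO"))
  expect_equal(round_table(dcH2$value - dcU2$value), -3.1)
  expect_equal(molar_combustion_energy(0, M1)$value, 0)
  expect_equal(enthalpy_from_energy(qty(-100, 0, "kJ/mol"), 0)$value, -100)
})

test_that("Hess derivation gives the liquid formation enthalpies", {
  r1 <- balance_combustion("C5H7NO")
  fl1 <- formation_liquid(qty(-2875.4, 0.9, "kJ/mol"), r1)
  expect_equal(round_table(fl1$value), -92.6)
  expect_equal(round_table(fl1$u), 1.1)

  r2 <- balance_combustion("C6H9NO")
  fl2 <- formation_liquid(qty(-3512.8, 1.3, "kJ/mol"), r2)
  expect_equal(round_table(fl2$value), -134.5)
  expect_equal(round_table(fl2$u), 1.5)

  # Hess consistency: algebraic inverse returns the combustion enthalpy
  cst <- thermo_constants()
  back <- r1$nu_co2 * cst$dfH_co2$value + r1$nu_h2o * cst$dfH_h2o$value -
    fl1$value
  expect_equal(back, -2875.4)

  # a fuel whose combustion enthalpy equals the product sum forms at zero
  ref_sum <- r1$nu_co2 * cst$dfH_co2$value + r1$nu_h2o * cst$dfH_h2o$value
  expect_equal(formation_liquid(qty(ref_sum, 0, "kJ/mol"), r1)$value, 0)
})

test_that("gas-phase formation combines liquid value and vaporization", {
  g1 <- formation_gas(qty(-92.6, 1.1, "kJ/mol"), qty(49.1, 0.8, "kJ/mol"))
  expect_equal(g1$value, -43.5)
  expect_equal(round_table(g1$u), 1.4)
  g2 <- formation_gas(qty(-134.5, 1.5, "kJ/mol"), qty(53.3, 0.9, "kJ/mol"))
  expect_equal(g2$value, -81.2)
  expect_equal(round_table(g2$u), 1.7)
  id <- formation_gas(qty(-92.6, 1.1, "kJ/mol"), qty(0, 0, "kJ/mol"))
  expect_equal(id$value, -92.6)
  expect_equal(id$u, 1.1)
})

test_that("each derivation step never shrinks the uncertainty", {
  set.seed(3)
  for (i in 1:15) {
    u_in <- runif(1, 0.1, 2)
    dcH <- qty(runif(1, -4000, -2000), u_in, "kJ/mol")
    r <- balance_combustion(sprintf("C%dH%dNO", sample(3:8, 1),
                                    sample(c(4, 6, 8), 1)))
    fl <- formation_liquid(dcH, r)
    expect_gte(fl$u, u_in)
    fg <- formation_gas(fl, qty(50, 0.5, "kJ/mol"))
    expect_gte(fg$u, fl$u)
  }
})

test_that("the full chain object carries every stage coherently", {
  ch <- derive_formation(combustion_replicates("furfurylamine"),
                         fuel = "C5H7NO", expanded_u = 0.9,
                         vaporization = qty(49.1, 0.8, "kJ/mol"))
  expect_s3_class(ch, "thermo_chain")
  expect_equal(round_table(ch$dcU$value), -2873.5)
  expect_equal(round_table(ch$dcH$value), -2875.4)
  expect_equal(round_table(ch$dfH_liquid$value), -92.6)
  expect_equal(round_table(ch$dfH_gas$value), -43.5)
  expect_equal(round_table(ch$dfH_gas$u), 1.4)

  td <- tidy(ch)
  expect_true(all(c("stage", "value", "u", "printed") %in% names(td)))
  expect_equal(td$printed[td$stage == "dcH_liquid"], 2875.4)
  gl <- glance(ch)
  expect_equal(gl$delta_n_gas, -0.75)

  # computed budget path: expanded_u = NULL uses the relative components
  ch2 <- derive_formation(combustion_replicates("furfurylamine"),
                          fuel = "C5H7NO",
                          rel_budget = c(0.7 / 15907.1, 3 / 26434))
  expect_gt(ch2$dcU$u, 0)
  expect_lt(ch2$dcU$u, 1)
})
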