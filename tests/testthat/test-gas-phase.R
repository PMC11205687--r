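test_that("Boltzmann populations sum to one and honour limits", {
  expect_equal(boltzmann_populations(c(0, 0)), c(0.5, 0.5))
  p <- boltzmann_populations(c(0, 2.82))
  expect_equal(sum(p), 1)
  expect_equal(round(100 * p, 1), c(75.7, 24.3))
  # an unreachable conformer carries zero population
  expect_equal(boltzmann_populations(c(0, 1e6)), c(1, 0))
  # invariance under a common shift of the free-energy scale
  expect_equal(boltzmann_populations(c(5, 7.82)), p)

  set.seed(6)
  for (i in 1:25) {
    dG <- runif(sample(2:6, 1), 0, 30)
    T <- runif(1, 150, 600)
    pops <- boltzmann_populations(dG, T)
    expect_equal(sum(pops), 1)
    expect_true(all(pops >= 0))
    # populations ordered opposite to free energies
    expect_equal(order(pops, decreasing = TRUE), order(dG))
  }
})

test_that("conformer weighting averages absolute enthalpies", {
  expect_equal(conformer_weighted_enthalpy(-363.5, 0), -363.5)
  h <- conformer_weighted_enthalpy(c(-363.5, -363.5 + 1e-3), c(0, 0))
  expect_equal(h, -363.5 + 5e-4)
  set.seed(12)
  for (i in 1:10) {
    H <- -400 + runif(5, 0, 0.05)
    dG <- runif(5, 0, 20)
    expect_equal(conformer_weighted_enthalpy(H, dG),
                 sum(boltzmann_populations(dG) * H))
  }
})

make_registry <- function() {
  species_registry(
    name = c("furan", "methylfuran", "thiophene_analog", "target"),
    formula = c("C4H4O", "C5H6O", "C4H4O", "C5H6O"),
    dfH_g = c(-34.7, -76.4, 115.0, NA),
    u_dfH_g = c(0.8, 1.2, 1.0, NA),
    H_absolute = c(-230.01, -269.35, -229.96, -269.31)
  )
}

test_that("reaction parsing handles coefficients and the unknown marker", {
  rxn <- parse_reaction("furan + 2 methylfuran -> thiophene_analog + ?target")
  expect_equal(rxn$coef, c(-1, -2, 1, 1))
  expect_equal(rxn$unknown, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rxn$species[4], "target")
  expect_error(parse_reaction("A + B"), "exactly one '->'")
  expect_error(parse_reaction("?A -> ?B"), "more than one")
})

test_that("reaction enthalpy converts balanced absolute-enthalpy sums", {
  reg <- make_registry()
  # identity reaction has zero enthalpy
  idf <- parse_reaction("furan -> furan")
  expect_equal(reaction_enthalpy(idf, reg), 0)
  # two-species balanced swap: 0.05 hartree difference
  rxn <- parse_reaction("furan -> thiophene_analog")
  expect_equal(reaction_enthalpy(rxn, reg), (-229.96 + 230.01) * 2625.4997)
  # reversing negates
  rev <- parse_reaction("thiophene_analog -> furan")
  expect_equal(reaction_enthalpy(rev, reg), -reaction_enthalpy(rxn, reg))
  # unbalanced reactions are rejected before any arithmetic
  bad <- parse_reaction("furan -> methylfuran")
  expect_error(reaction_enthalpy(bad, reg), "not element-balanced")
})

test_that("solving for the unknown round-trips randomly built reactions", {
  reg <- make_registry()
  rxn <- parse_reaction("furan + ?target -> thiophene_analog + methylfuran")
  drH <- reaction_enthalpy(rxn, reg)
  est <- solve_unknown_formation(rxn, drH, reg)
  # recomputing the reaction enthalpy from the solved value is the identity
  filled <- reg
  filled$dfH_g[filled$name == "target"] <- est$value
  sp <- filled[match(rxn$species, filled$name), ]
  expect_equal(sum(rxn$coef * sp$dfH_g), drH)

  # unknown on either side gives sign-consistent results
  flip <- parse_reaction("thiophene_analog + methylfuran -> furan + ?target")
  est2 <- solve_unknown_formation(flip, -drH, reg)
  expect_equal(est2$value, est$value)

  # trivial transfer: zero reaction enthalpy copies the known value
  copyr <- parse_reaction("furan -> ?thiophene_analog")
  reg2 <- make_registry()
  reg2$dfH_g[reg2$name == "furan"] <- -50
  est3 <- solve_unknown_formation(copyr, 0, reg2)
  expect_equal(est3$value, -50)

  expect_error(solve_unknown_formation(parse_reaction("furan -> furan"),
                                       0, reg), "exactly one unknown")

  set.seed(19)
  for (i in 1:10) {
    # random stoichiometry x furan + y thiophene_analog (isomers, balanced)
    x <- sample(1:3, 1)
    txt <- sprintf("%d furan -> %d ?thiophene_analog", x, x)
    r <- parse_reaction(txt)
    dr <- reaction_enthalpy(r, reg)
    e <- solve_unknown_formation(r, dr, reg)
    sp <- reg[match(r$species, reg$name), ]
    sp$dfH_g[r$unknown] <- e$value
    expect_equal(sum(r$coef * sp$dfH_g), dr)
  }
})

test_that("mean-over-reactions estimation reports mean and sdom", {
  reg <- make_registry()
  reactions <- c("furan + ?target -> thiophene_analog + methylfuran",
                 "2 furan + ?target -> 2 thiophene_analog + methylfuran")
  est <- estimate_formation_gas(reactions, reg)
  expect_s3_class(est, "formation_estimate")
  expect_equal(nrow(est$per_reaction), 2)
  expect_equal(est$estimate$value, mean(est$per_reaction$dfH_g))
  expect_equal(est$estimate$u,
               sd(est$per_reaction$dfH_g) / sqrt(2))
})

test_that("substitution increments transfer with RSS uncertainties", {
  t1 <- increment_estimate(qty(-38.9, 0.6, "kJ/mol"), qty(147.3, 4.5, "kJ/mol"))
  expect_equal(round_table(t1$value), 108.4)
  expect_equal(round_table(t1$u), 4.5)
  t2 <- increment_estimate(qty(-81.9, 0.9, "kJ/mol"), qty(159.4, 5.0, "kJ/mol"))
  expect_equal(round_table(t2$value), 77.5)
  expect_equal(round_table(t2$u), 5.1)
  idn <- increment_estimate(qty(-38.9, 0.6, "kJ/mol"), qty(0, 0, "kJ/mol"))
  expect_equal(idn$value, -38.9)
})

test_that("the monomer/dimer cycle reproduces both vaporization branches", {
  tw <- dimer_cycle(-38.9, -92.6, -24)
  expect_equal(tw$dvapH, c(53.7, 83.4))
  lit <- dimer_cycle(-38.9, -105.4, -24)
  expect_equal(lit$dvapH, c(66.5, 109.0))
  # dimer minus twice the monomer is the dimerization enthalpy, identically
  set.seed(23)
  for (i in 1:10) {
    g <- runif(1, -120, 0); l <- runif(1, -160, -20); dd <- runif(1, -40, 0)
    dc <- dimer_cycle(g, l, dd)
    expect_equal(dc$dvapH[2] - 2 * dc$dvapH[1], dd)
  }
  # zero dimerization enthalpy: dimer branch is exactly twice the monomer
  z <- dimer_cycle(-38.9, -92.6, 0)
  expect_equal(z$dvapH[2], 2 * z$dvapH[1])
})
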