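#' Boltzmann conformer populations
#'
#' Fractional abundances proportional to `exp(-dG / (R T))` from relative
#' Gibbs free energies. Computed with the log-sum-exp shift so arbitrarily
#' large `dG` values are handled without underflow.
#'
#' @param dG Numeric vector of relative free energies, kJ/mol (minimum need
#'   not be zero; only differences matter).
#' @param T Temperature, K.
#' @param constants A [thermo_constants()] bundle.
#' @return Numeric vector of fractions summing to 1.
#' @examples
#' boltzmann_populations(c(0, 2.82)) # ~ 0.757 / 0.243
#' @export
boltzmann_populations <- function(dG, T = 298.15, constants = thermo_constants()) {
  stopifnot(T > 0, length(dG) >= 1)
  x <- -(dG - min(dG)) * 1000 / (constants$R * T)
  w <- exp(x)
  w / sum(w)
}

#' Conformer-weighted absolute enthalpy
#'
#' Population-weighted mean of conformer absolute enthalpies, with weights
#' from the Boltzmann distribution over relative free energies.
#'
#' @param H Numeric vector of conformer absolute enthalpies (hartree).
#' @param dG Relative free energies, kJ/mol (same order as `H`).
#' @param T Temperature, K.
#' @param constants A [thermo_constants()] bundle.
#' @return Weighted enthalpy, hartree.
#' @export
conformer_weighted_enthalpy <- function(H, dG, T = 298.15,
                                        constants = thermo_constants()) {
  stopifnot(length(H) == length(dG))
  sum(boltzmann_populations(dG, T, constants) * H)
}

#' Parse a reaction from plain text
#'
#' Syntax: `"A + 2 B -> C + D"`, optionally with one species prefixed `?`
#' to mark it as the unknown whose formation enthalpy is to be solved for,
#' e.g. `"furan + ?thiophene -> 2-furaldehyde"`. Species names may contain
#' anything but `+`, `>` and leading coefficients; coefficients are
#' non-negative numbers separated from the name by whitespace.
#'
#' @param text Reaction string with a single `->`.
#' @return A tibble with columns `species`, `coef` (signed: products
#'   positive, reactants negative), `unknown` (logical).
#' @examples
#' parse_reaction("furan + ?thiophenemethylamine -> thiophene + furfurylamine")
#' @export
parse_reaction <- function(text) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("reaction must contain exactly one '->'", call. = FALSE)
  parse_side <- function(s, sign) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty reaction side", call. = FALSE)
    purrr::map_dfr(terms, function(tm) {
      unknown <- startsWith(tm, "?")
      if (unknown) tm <- sub("^\\?\\s*", "", tm)
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)\\s+(.*)$", tm))[[1]]
      if (length(m) == 3) {
        coef <- as.numeric(m[2]); sp <- m[3]
      } else {
        coef <- 1; sp <- tm
      }
      if (startsWith(sp, "?")) { unknown <- TRUE; sp <- sub("^\\?\\s*", "", sp) }
      tibble::tibble(species = sp, coef = sign * coef, unknown = unknown)
    })
  }
  out <- dplyr::bind_rows(parse_side(sides[1], -1), parse_side(sides[2], +1))
  if (sum(out$unknown) > 1) stop("more than one species marked unknown", call. = FALSE)
  out
}

# Look up registry rows by species name; registry is a data frame with at
# least `name` and `formula` columns.
registry_lookup <- function(rxn, registry) {
  idx <- match(rxn$species, registry$name)
  if (anyNA(idx)) {
    stop("species not in registry: ",
         paste(rxn$species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  registry[idx, ]
}

#' Check element balance of a reaction against a species registry
#'
#' Element balance is the mandatory part of the isodesmic criterion: every
#' reaction used to transfer formation enthalpies must conserve C, H, N and
#' O exactly. (Bond-type conservation, the full isodesmic condition, is the
#' reaction designer's responsibility and is not checked here.)
#'
#' @param rxn A parsed reaction from [parse_reaction()].
#' @param registry Species registry (tibble with `name`, `formula`).
#' @param tol Tolerance on element counts.
#' @return `TRUE` invisibly, or an error describing the imbalance.
#' @export
check_element_balance <- function(rxn, registry, tol = 1e-9) {
  sp <- registry_lookup(rxn, registry)
  counts <- purrr::map(sp$formula, ~ unclass(as_formula(.x)))
  net <- Reduce(`+`, purrr::map2(counts, rxn$coef, ~ .x * .y))
  if (any(abs(net) > tol)) {
    bad <- names(net)[abs(net) > tol]
    stop("reaction is not element-balanced (", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reaction enthalpy from computed absolute enthalpies
#'
#' `sum(coef * H_absolute)` over all participants (products positive),
#' converted from hartree to kJ/mol. The reaction must be element-balanced;
#' the balance check runs before any arithmetic.
#'
#' @param rxn A parsed reaction ([parse_reaction()]).
#' @param registry Species registry with columns `name`, `formula`,
#'   `H_absolute` (hartree, conformer-weighted where appropriate).
#' @param constants A [thermo_constants()] bundle (hartree conversion).
#' @return Reaction enthalpy, kJ/mol.
#' @export
reaction_enthalpy <- function(rxn, registry, constants = thermo_constants()) {
  check_element_balance(rxn, registry)
  sp <- registry_lookup(rxn, registry)
  if (any(is.na(sp$H_absolute))) {
    stop("missing absolute enthalpy for: ",
         paste(sp$name[is.na(sp$H_absolute)], collapse = ", "), call. = FALSE)
  }
  sum(rxn$coef * sp$H_absolute) * constants$hartree_kJ_mol
}

#' Solve a working reaction for an unknown formation enthalpy
#'
#' Given the reaction enthalpy (typically from [reaction_enthalpy()]) and
#' experimental formation enthalpies of every other participant, solves
#' `drH = sum(coef * dfH)` for the single species marked unknown. The
#' uncertainty is the root-sum-square of the scaled participant
#' uncertainties (the reaction enthalpy itself is treated as exact, the
#' convention when it comes from a composite quantum-chemistry method).
#'
#' @param rxn A parsed reaction with exactly one `unknown` species.
#' @param drH Reaction enthalpy, kJ/mol.
#' @param registry Species registry with columns `name`, `formula`, `dfH_g`
#'   and `u_dfH_g` (kJ/mol).
#' @return `qty`: formation enthalpy of the unknown, kJ/mol.
#' @export
solve_unknown_formation <- function(rxn, drH, registry) {
  n_unknown <- sum(rxn$unknown)
  if (n_unknown != 1) {
    stop("reaction must mark exactly one unknown species (found ", n_unknown, ")",
         call. = FALSE)
  }
  sp <- registry_lookup(rxn, registry)
  iu <- which(rxn$unknown)
  if (abs(rxn$coef[iu]) < 1e-12) stop("unknown has zero coefficient", call. = FALSE)
  known <- rxn[-iu, ]; ksp <- sp[-iu, ]
  if (any(is.na(ksp$dfH_g))) {
    stop("missing experimental formation enthalpy for: ",
         paste(ksp$name[is.na(ksp$dfH_g)], collapse = ", "), call. = FALSE)
  }
  value <- (drH - sum(known$coef * ksp$dfH_g)) / rxn$coef[iu]
  u_known <- ksp$u_dfH_g
  u_known[is.na(u_known)] <- 0
  u <- rss_combine(abs(known$coef) * u_known) / abs(rxn$coef[iu])
  qty(value, u, "kJ/mol")
}

#' Estimate a formation enthalpy from a set of working reactions
#'
#' Runs [reaction_enthalpy()] and [solve_unknown_formation()] for each
#' reaction and reports the per-reaction estimates plus their mean and
#' standard deviation of the mean — the convention for composite-method
#' estimates averaged over several working reactions.
#'
#' @param reactions Character vector of reaction strings (see
#'   [parse_reaction()]), each with the same unknown species.
#' @param registry Species registry with `name`, `formula`, `H_absolute`,
#'   `dfH_g`, `u_dfH_g`.
#' @param constants A [thermo_constants()] bundle.
#' @return A list of class `"formation_estimate"`: `estimate` (`qty`, mean
#'   +/- sdom), `per_reaction` tibble.
#' @export
estimate_formation_gas <- function(reactions, registry,
                                   constants = thermo_constants()) {
  per <- purrr::map_dfr(reactions, function(txt) {
    rxn <- parse_reaction(txt)
    drH <- reaction_enthalpy(rxn, registry, constants)
    est <- solve_unknown_formation(rxn, drH, registry)
    tibble::tibble(reaction = txt, unknown = rxn$species[rxn$unknown],
                   drH = drH, dfH_g = est$value, u = est$u)
  })
  n <- nrow(per)
  m <- mean(per$dfH_g)
  sdom <- if (n >= 2) stats::sd(per$dfH_g) / sqrt(n) else per$u[1]
  structure(list(estimate = qty(m, sdom, "kJ/mol"), per_reaction = per),
            class = "formation_estimate")
}

#' @export
print.formation_estimate <- function(x, ...) {
  cat("<formation_estimate>", format(x$estimate, digits = 1), "over",
      nrow(x$per_reaction), "reaction(s)\n")
  invisible(x)
}

#' @export
tidy.formation_estimate <- function(x, ...) x$per_reaction

#' Apply a substitution or group increment to a formation enthalpy
#'
#' Transfers an enthalpic increment (e.g. an oxygen -> sulfur ring
#' substitution, or a methylation) established on one family of compounds to
#' a structurally analogous one: `base + increment`, uncertainties combined
#' by root-sum-square.
#'
#' @param base `qty`: formation enthalpy of the parent compound, kJ/mol.
#' @param increment `qty`: enthalpic increment, kJ/mol.
#' @return `qty` in kJ/mol.
#' @examples
#' increment_estimate(qty(-38.9, 0.6, "kJ/mol"), qty(147.3, 4.5, "kJ/mol"))
#' @export
increment_estimate <- function(base, increment) {
  base <- as_qty(base, "kJ/mol"); increment <- as_qty(increment, "kJ/mol")
  base + increment
}

#' Monomer/dimer vaporization enthalpies from a thermochemical cycle
#'
#' If a liquid vaporizes to monomeric gas, the vaporization enthalpy is
#' `dfH(g) - dfH(l)`; if it vaporizes entirely to a gas-phase dimer, the
#' cycle through two moles of monomer gives
#' `2 dfH(g) - 2 dfH(l) + ddimH`, with `ddimH` the dimerization enthalpy
#' (2 monomers -> dimer, negative for exothermic association). Comparing the
#' two against the measured vaporization enthalpy diagnoses which species
#' leaves the liquid.
#'
#' @param dfH_gas Gas-phase (monomer) formation enthalpy, kJ/mol (`qty` or
#'   number).
#' @param dfH_liquid Liquid-phase formation enthalpy, kJ/mol.
#' @param ddimH Dimerization enthalpy, kJ/mol (default -24).
#' @return A tibble with columns `species` ("monomer", "dimer"), `dvapH`
#'   and `u`.
#' @examples
#' dimer_cycle(-38.9, -92.6, -24) # 53.7 and 83.4 kJ/mol
#' @export
dimer_cycle <- function(dfH_gas, dfH_liquid, ddimH = -24) {
  g <- as_qty(dfH_gas, "kJ/mol"); l <- as_qty(dfH_liquid, "kJ/mol")
  d <- as_qty(ddimH, "kJ/mol")
  mono <- g - l
  dim <- g * 2 - l * 2 + d
  tibble::tibble(species = c("monomer", "dimer"),
                 dvapH = c(mono$value, dim$value),
                 u = c(mono$u, dim$u))
}

#' A species registry template
#'
#' Builds a registry tibble from vectors; a registry row needs a `name`, a
#' `formula`, and at least one of an experimental gas-phase formation
#' enthalpy (`dfH_g`, `u_dfH_g`) or a computed absolute enthalpy
#' (`H_absolute`, hartree) to participate in working reactions.
#'
#' @param name,formula Character vectors.
#' @param dfH_g,u_dfH_g,H_absolute Numeric vectors (NA where not available).
#' @return A tibble.
#' @export
species_registry <- function(name, formula, dfH_g = NA_real_,
                             u_dfH_g = NA_real_, H_absolute = NA_real_) {
  tibble::tibble(name = name, formula = formula, dfH_g = dfH_g,
                 u_dfH_g = u_dfH_g, H_absolute = H_absolute)
}

#' Read a species registry from JSON or CSV
#'
#' JSON: an array of objects with fields matching [species_registry()]
#' columns. CSV: a header row with the same names.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return A tibble.
#' @export
read_species_registry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df <- tibble::as_tibble(df)
  for (col in c("dfH_g", "u_dfH_g", "H_absolute")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df
}
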