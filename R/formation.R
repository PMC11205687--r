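#' Summarize replicate massic energies
#'
#' Mean and standard deviation of the mean (sdom = sd / sqrt(n)) of the
#' replicate massic combustion energies of one compound.
#'
#' @param values Numeric vector of massic energies (J/g), or a data frame
#'   with a `massic_energy` column (e.g. the output of [reduce_bomb()]).
#' @return An object of class `"replicate_summary"`: `mean`, `sdom`, `n`,
#'   `values`.
#' @examples
#' summarize_replicates(c(-29591.73, -29582.70, -29589.96,
#'                        -29589.56, -29593.49, -29581.42))
#' @export
summarize_replicates <- function(values) {
  if (is.data.frame(values)) values <- values$massic_energy
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 replicates", call. = FALSE)
  structure(list(mean = mean(values),
                 sdom = stats::sd(values) / sqrt(length(values)),
                 n = length(values), values = values),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %.1f ± %.1f J/g (n = %d)\n", x$mean, x$sdom, x$n))
  invisible(x)
}

#' @export
tidy.replicate_summary <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$values), massic_energy = x$values,
                 deviation = x$values - x$mean)
}

#' @export
glance.replicate_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, sdom = x$sdom, n = x$n, sd = stats::sd(x$values))
}

#' Expanded uncertainty of a combustion result
#'
#' Thermochemical convention (Rossini/Olofsson): the expanded uncertainty is
#' twice the root-sum-square of the relative standard deviation of the mean
#' of the sample burns and the relative uncertainties of calibration and
#' auxiliary quantities, applied to the magnitude of the derived value.
#'
#' @param value The derived quantity the uncertainty refers to (e.g. molar
#'   combustion energy, kJ/mol); only its magnitude enters.
#' @param rel_sdom Relative sdom of the sample replicates.
#' @param rel_components Numeric vector of additional relative components
#'   (calibration, certificate, auxiliary energies).
#' @return Expanded uncertainty in the units of `value`.
#' @examples
#' expanded_uncertainty(2873.5, 1.565e-4)  # 0.9 when the budget RSS is 1.565e-4
#' @export
expanded_uncertainty <- function(value, rel_sdom, rel_components = numeric(0)) {
  2 * rss_combine(c(rel_sdom, rel_components)) * abs(value)
}

#' Molar combustion energy from the mean massic energy
#'
#' @param massic Mean massic energy, J/g (number or `replicate_summary`).
#' @param M Molar mass, g/mol (`qty` or number).
#' @param u Expanded uncertainty to attach, kJ/mol (optional).
#' @return `qty` in kJ/mol, sign preserved (negative = exothermic).
#' @export
molar_combustion_energy <- function(massic, M, u = 0) {
  if (inherits(massic, "replicate_summary")) massic <- massic$mean
  if (is_qty(M)) M <- M$value
  stopifnot(M > 0)
  qty(massic * M / 1000, u, "kJ/mol")
}

#' Combustion enthalpy from combustion energy
#'
#' Adds the pressure-volume work term for the net change in gaseous moles:
#' `dcH = dcU + delta_n * R * T`.
#'
#' @param dcU Molar combustion energy, kJ/mol (`qty` or number).
#' @param delta_n Net gaseous moles formed per mole fuel (from
#'   [delta_n_gas()] or a `combustion_reaction`).
#' @param constants A [thermo_constants()] bundle (supplies R and T_ref).
#' @return `qty` in kJ/mol; the work term carries no uncertainty.
#' @export
enthalpy_from_energy <- function(dcU, delta_n, constants = thermo_constants()) {
  if (inherits(delta_n, "combustion_reaction")) delta_n <- delta_n_gas(delta_n)
  dcU <- as_qty(dcU, "kJ/mol")
  dcU + qty(delta_n * constants$R * constants$T_ref / 1000, 0, "kJ/mol")
}

#' Liquid-phase formation enthalpy by Hess's law
#'
#' \deqn{\Delta_f H^\circ_m(l) = \nu_{CO_2}\Delta_f H^\circ[CO_2(g)] +
#'   \nu_{H_2O}\Delta_f H^\circ[H_2O(l)] - \Delta_c H^\circ_m(l)}
#' with the uncertainty combined by root-sum-square over the combustion
#' enthalpy and the scaled reference-value uncertainties.
#'
#' @param dcH Molar combustion enthalpy, kJ/mol (`qty`).
#' @param reaction A `combustion_reaction` from [balance_combustion()].
#' @param constants A [thermo_constants()] bundle (CODATA CO2/H2O values).
#' @return `qty` in kJ/mol.
#' @export
formation_liquid <- function(dcH, reaction, constants = thermo_constants()) {
  stopifnot(inherits(reaction, "combustion_reaction"))
  dcH <- as_qty(dcH, "kJ/mol")
  v <- reaction$nu_co2 * constants$dfH_co2$value +
    reaction$nu_h2o * constants$dfH_h2o$value - dcH$value
  u <- rss_combine(c(dcH$u,
                     reaction$nu_co2 * constants$dfH_co2$u,
                     reaction$nu_h2o * constants$dfH_h2o$u))
  qty(v, u, "kJ/mol")
}

#' Gas-phase formation enthalpy from the liquid value and vaporization
#'
#' Simple sum with root-sum-square uncertainties; both quantities must refer
#' to 298.15 K.
#'
#' @param dfH_l Liquid-phase formation enthalpy, kJ/mol (`qty`).
#' @param dvapH Vaporization enthalpy at the reference temperature, kJ/mol
#'   (`qty`).
#' @return `qty` in kJ/mol.
#' @examples
#' formation_gas(qty(-92.6, 1.1, "kJ/mol"), qty(49.1, 0.8, "kJ/mol"))
#' @export
formation_gas <- function(dfH_l, dvapH) {
  dfH_l <- as_qty(dfH_l, "kJ/mol"); dvapH <- as_qty(dvapH, "kJ/mol")
  qty(dfH_l$value + dvapH$value, rss_combine(c(dfH_l$u, dvapH$u)), "kJ/mol")
}

#' Full derivation chain: replicates to formation enthalpies
#'
#' Runs the whole table chain for one compound: replicate statistics, molar
#' combustion energy, combustion enthalpy via the gas-mole work term, Hess
#' derivation of the liquid-phase formation enthalpy, and (when a
#' vaporization enthalpy is supplied) the gas-phase formation enthalpy.
#'
#' `rounding = "table"` reproduces the convention of published
#' thermochemical tables, where each tabulated stage is rounded to one
#' decimal in kJ/mol before feeding the next stage; `"none"` (default)
#' carries full precision through the chain and rounds only for display.
#'
#' @param replicates Numeric vector of massic energies (J/g), a data frame
#'   with a `massic_energy` column, or a `replicate_summary`.
#' @param fuel Fuel formula.
#' @param expanded_u Expanded uncertainty of the molar combustion energy,
#'   kJ/mol. Either a number (e.g. taken from a published table) or `NULL`,
#'   in which case it is computed from `rel_budget`.
#' @param rel_budget Relative uncertainty components entering
#'   [expanded_uncertainty()] besides the replicate sdom (calibration,
#'   certificate, ...); used only when `expanded_u` is `NULL`.
#' @param vaporization Optional `qty`: vaporization enthalpy at 298.15 K.
#' @param constants A [thermo_constants()] bundle.
#' @param rounding `"none"` or `"table"`, see Details.
#' @return An object of class `"thermo_chain"` with every stage as a `qty`,
#'   plus the reaction and replicate summary; use [tidy.thermo_chain()] for
#'   a table-shaped view.
#' @examples
#' derive_formation(combustion_replicates("furfurylamine"),
#'                  fuel = "C5H7NO", expanded_u = 0.9,
#'                  vaporization = qty(49.1, 0.8, "kJ/mol"))
#' @export
derive_formation <- function(replicates, fuel, expanded_u = NULL,
                             rel_budget = numeric(0), vaporization = NULL,
                             constants = thermo_constants(),
                             rounding = c("none", "table")) {
  rounding <- match.arg(rounding)
  rep_sum <- if (inherits(replicates, "replicate_summary")) replicates
             else summarize_replicates(replicates)
  fuel <- as_formula(fuel)
  reaction <- balance_combustion(fuel)
  M <- molar_mass(fuel, constants)

  if (is.null(expanded_u)) {
    expanded_u <- expanded_uncertainty(rep_sum$mean * M$value / 1000,
                                       abs(rep_sum$sdom / rep_sum$mean),
                                       rel_budget)
  }
  stage <- function(q) if (rounding == "table") {
    qty(round_table(q$value), round_table(q$u), q$unit)
  } else q

  dcU <- stage(molar_combustion_energy(rep_sum$mean, M, abs(expanded_u)))
  dcH <- stage(enthalpy_from_energy(dcU, reaction, constants))
  dfH_l <- stage(formation_liquid(dcH, reaction, constants))
  dfH_g <- if (!is.null(vaporization)) {
    stage(formation_gas(dfH_l, vaporization))
  } else NULL

  structure(list(fuel = fuel, reaction = reaction, molar_mass = M,
                 replicates = rep_sum, dcU = dcU, dcH = dcH,
                 dfH_liquid = dfH_l, dvapH = vaporization, dfH_gas = dfH_g,
                 rounding = rounding, constants = constants),
            class = "thermo_chain")
}

#' @export
print.thermo_chain <- function(x, ...) {
  cat("<thermo_chain>", format(x$fuel), "\n")
  cat(sprintf("  massic energy     %10.1f ± %.1f J/g (n = %d)\n",
              x$replicates$mean, x$replicates$sdom, x$replicates$n))
  cat(sprintf("  dcU(l)            %10.1f ± %.1f kJ/mol\n", x$dcU$value, x$dcU$u))
  cat(sprintf("  dcH(l)            %10.1f ± %.1f kJ/mol\n", x$dcH$value, x$dcH$u))
  cat(sprintf("  dfH(l)            %10.1f ± %.1f kJ/mol\n",
              x$dfH_liquid$value, x$dfH_liquid$u))
  if (!is.null(x$dfH_gas)) {
    cat(sprintf("  dvapH             %10.1f ± %.1f kJ/mol\n",
                x$dvapH$value, x$dvapH$u))
    cat(sprintf("  dfH(g)            %10.1f ± %.1f kJ/mol\n",
                x$dfH_gas$value, x$dfH_gas$u))
  }
  invisible(x)
}

#' Tidy a derivation chain into a table-shaped tibble
#'
#' One row per derived stage, with magnitudes as printed in thermochemical
#' tables (`-dcU`, `-dcH`, `-dfH(l)` columns positive for exothermic
#' combustion) alongside the signed values.
#'
#' @param x A `thermo_chain`.
#' @param ... Ignored.
#' @return A tibble with columns `stage`, `value`, `u`, `printed` (magnitude
#'   rounded to one decimal) and `unit`.
#' @export
tidy.thermo_chain <- function(x, ...) {
  rows <- list(
    list(stage = "massic_energy", q = qty(x$replicates$mean, x$replicates$sdom, "J/g")),
    list(stage = "dcU_liquid", q = x$dcU),
    list(stage = "dcH_liquid", q = x$dcH),
    list(stage = "dfH_liquid", q = x$dfH_liquid)
  )
  if (!is.null(x$dvapH)) rows <- c(rows, list(list(stage = "dvapH", q = x$dvapH)))
  if (!is.null(x$dfH_gas)) rows <- c(rows, list(list(stage = "dfH_gas", q = x$dfH_gas)))
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(stage = r$stage, value = r$q$value, u = r$q$u,
                   printed = round_table(abs(r$q$value)),
                   printed_u = round_table(r$q$u), unit = r$q$unit)
  })
}

#' @export
glance.thermo_chain <- function(x, ...) {
  tibble::tibble(fuel = format(x$fuel), n_replicates = x$replicates$n,
                 molar_mass = x$molar_mass$value,
                 delta_n_gas = delta_n_gas(x$reaction),
                 dfH_liquid = x$dfH_liquid$value, u_dfH_liquid = x$dfH_liquid$u,
                 dfH_gas = if (is.null(x$dfH_gas)) NA_real_ else x$dfH_gas$value,
                 u_dfH_gas = if (is.null(x$dfH_gas)) NA_real_ else x$dfH_gas$u)
}

#' Plot a derivation chain as an enthalpy ladder
#'
#' @param object A `thermo_chain`.
#' @param ... Ignored.
#' @return A ggplot object showing each derived stage with its uncertainty.
#' @export
autoplot.thermo_chain <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$unit == "kJ/mol", ]
  td$stage <- factor(td$stage, levels = rev(td$stage))
  ggplot2::ggplot(td, ggplot2::aes(.data$value, .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$value - .data$u, xmax = .data$value + .data$u),
      height = 0.2) +
    ggplot2::labs(x = "kJ/mol", y = NULL, title = format(object$fuel)) +
    ggplot2::theme_minimal()
}
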