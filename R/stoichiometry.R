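#' Balance the idealized combustion reaction of a CaHbNcOd fuel
#'
#' The standard-state combustion convention: liquid fuel plus gaseous oxygen
#' gives gaseous CO2, liquid water and gaseous N2,
#' \deqn{C_aH_bN_cO_d(l) + (a + b/4 - d/2)\,O_2(g) \rightarrow
#'       a\,CO_2(g) + (b/2)\,H_2O(l) + (c/2)\,N_2(g).}
#' Coefficients are quarters/halves of integer element counts, hence exactly
#' representable; no rounding enters the gas-mole bookkeeping.
#'
#' @param fuel A `chem_formula` or formula string with at least one C or H.
#' @return A list of class `"combustion_reaction"` with fields `fuel`,
#'   `nu_o2`, `nu_co2`, `nu_h2o`, `nu_n2`, `delta_n_gas`.
#' @examples
#' balance_combustion("C5H7NO") # 6.25 O2 -> 5 CO2 + 3.5 H2O + 0.5 N2
#' @export
balance_combustion <- function(fuel) {
  f <- unclass(as_formula(fuel))
  a <- f[["C"]]; b <- f[["H"]]; cc <- f[["N"]]; d <- f[["O"]]
  if (a <= 0 && b <= 0) stop("fuel must contain carbon or hydrogen", call. = FALSE)
  nu_o2 <- a + b / 4 - d / 2
  if (nu_o2 < 0) {
    stop("invalid fuel: more oxygen than the combustion products can carry",
         call. = FALSE)
  }
  r <- list(fuel = as_formula(fuel),
            nu_o2 = nu_o2, nu_co2 = a, nu_h2o = b / 2, nu_n2 = cc / 2)
  r$delta_n_gas <- r$nu_co2 + r$nu_n2 - r$nu_o2
  structure(r, class = "combustion_reaction")
}

#' @export
print.combustion_reaction <- function(x, ...) {
  co <- function(v) if (v == 1) "" else paste0(format(v), " ")
  cat(sprintf("%s (l) + %sO2 (g) -> %sCO2 (g) + %sH2O (l) + %sN2 (g)\n",
              format(x$fuel), co(x$nu_o2), co(x$nu_co2), co(x$nu_h2o), co(x$nu_n2)))
  cat("  delta_n(gas) =", x$delta_n_gas, "\n")
  invisible(x)
}

#' Net change in moles of gas across a combustion reaction
#'
#' Fuel and water are condensed, so the gaseous ledger is
#' `nu_CO2 + nu_N2 - nu_O2`. This is the quantity that converts the molar
#' combustion energy to the combustion enthalpy via `delta_n * R * T`.
#'
#' @param r A `combustion_reaction` from [balance_combustion()].
#' @return Numeric, moles of gas formed per mole of fuel (negative when gas
#'   is consumed net).
#' @export
delta_n_gas <- function(r) {
  stopifnot(inherits(r, "combustion_reaction"))
  r$nu_co2 + r$nu_n2 - r$nu_o2
}

#' Theoretical CO2 mass from complete combustion
#'
#' @param fuel A `chem_formula` or string.
#' @param sample_mass Mass of fuel burned, g.
#' @param constants A [thermo_constants()] bundle.
#' @return CO2 mass in g.
#' @seealso [sample_mass_from_co2()] for the inverse.
#' @export
theoretical_co2_mass <- function(fuel, sample_mass, constants = thermo_constants()) {
  stopifnot(sample_mass >= 0)
  sample_mass * co2_per_gram(fuel, constants)
}

# g of CO2 produced per g of material burned
co2_per_gram <- function(fuel, constants = thermo_constants()) {
  f <- as_formula(fuel)
  n_c <- unclass(f)[["C"]]
  if (n_c <= 0) stop("invalid fuel: no carbon, CO2 accounting undefined", call. = FALSE)
  m_co2 <- molar_mass("CO2", constants)$value
  n_c * m_co2 / molar_mass(f, constants)$value
}

#' Sample mass implied by a collected CO2 mass
#'
#' Inverts the CO2 stoichiometry after removing the CO2 attributable to
#' auxiliary materials (fuse, sample bag). This mirrors the practice of
#' determining the quantity of compound burned from the total carbon dioxide
#' recovered in the absorption tubes.
#'
#' @param m_co2_total Total CO2 collected, g.
#' @param fuel Fuel formula.
#' @param aux_co2 CO2 attributable to auxiliary materials, g (default 0).
#' @param constants A [thermo_constants()] bundle.
#' @return Sample mass, g.
#' @export
sample_mass_from_co2 <- function(m_co2_total, fuel, aux_co2 = 0,
                                 constants = thermo_constants()) {
  residual <- m_co2_total - aux_co2
  if (residual < -1e-12) {
    stop("inconsistent record: collected CO2 is less than the auxiliary contribution",
         call. = FALSE)
  }
  max(residual, 0) / co2_per_gram(fuel, constants)
}
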