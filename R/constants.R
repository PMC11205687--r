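#' Physical constants and reference data for thermochemical reduction
#'
#' Bundles the gas constant, reference temperature, CODATA standard molar
#' enthalpies of formation of CO2(g) and H2O(l), IUPAC 2013 conventional
#' relative atomic masses (C, H, N, O), and the hartree -> kJ/mol conversion.
#' Every value can be overridden, either programmatically or from a JSON
#' config file, so the reduction chain is fully auditable.
#'
#' @param config Optional path to a JSON file whose top-level fields override
#'   the defaults (same names as the arguments below; `dfH_co2` and `dfH_h2o`
#'   given as `list(value=, u=)`).
#' @param R Gas constant, J/(K mol).
#' @param T_ref Reference temperature, K.
#' @param dfH_co2 `qty`, standard molar enthalpy of formation of CO2(g) at
#'   `T_ref`, kJ/mol.
#' @param dfH_h2o `qty`, standard molar enthalpy of formation of H2O(l) at
#'   `T_ref`, kJ/mol.
#' @param atomic_masses Named numeric vector of relative atomic masses.
#' @param hartree_kJ_mol Conversion factor from hartree to kJ/mol.
#'
#' @return A list of class `"thermo_constants"`.
#' @examples
#' cst <- thermo_constants()
#' cst$dfH_co2
#' @export
thermo_constants <- function(config = NULL,
                             R = 8.314462,
                             T_ref = 298.15,
                             dfH_co2 = qty(-393.51, 0.13, "kJ/mol"),
                             dfH_h2o = qty(-285.830, 0.040, "kJ/mol"),
                             atomic_masses = c(C = 12.011, H = 1.008,
                                               N = 14.007, O = 15.999),
                             hartree_kJ_mol = 2625.4997) {
  cst <- list(R = R, T_ref = T_ref, dfH_co2 = dfH_co2, dfH_h2o = dfH_h2o,
              atomic_masses = atomic_masses, hartree_kJ_mol = hartree_kJ_mol)
  if (!is.null(config)) {
    if (!file.exists(config)) stop("constants config not found: ", config, call. = FALSE)
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    for (nm in intersect(names(cfg), c("R", "T_ref", "hartree_kJ_mol"))) {
      cst[[nm]] <- as.numeric(cfg[[nm]])
    }
    for (nm in intersect(names(cfg), c("dfH_co2", "dfH_h2o"))) {
      cst[[nm]] <- qty(cfg[[nm]]$value, cfg[[nm]]$u %||% 0, "kJ/mol")
    }
    if (!is.null(cfg$atomic_masses)) {
      am <- unlist(cfg$atomic_masses)
      cst$atomic_masses[names(am)] <- am
    }
  }
  structure(cst, class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("<thermo_constants>\n")
  cat("  R            ", x$R, "J/(K mol)\n")
  cat("  T_ref        ", x$T_ref, "K\n")
  cat("  dfH[CO2(g)]  ", format(x$dfH_co2), "\n")
  cat("  dfH[H2O(l)]  ", format(x$dfH_h2o), "\n")
  cat("  atomic masses", paste(names(x$atomic_masses),
                               x$atomic_masses, collapse = "  "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
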