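#' Built-in auxiliary combustion materials
#'
#' Massic combustion energies and physical properties of the auxiliary
#' materials that burn alongside the sample: the Melinex (polyester) sample
#' bag and the cotton-thread fuse. Values are the conventional literature
#' ones for this instrument class; rows can be overridden or extended by
#' binding a modified tibble into the reduction calls.
#'
#' Columns: `name`, `delta_cu` (massic combustion energy, J/g, negative),
#' `u_delta_cu` (J/g), `water_fraction` (mass fraction of water to strip from
#' the as-weighed mass), `cp` (J/(g K)), `dudp` ((du/dp)_T, J/(g MPa)),
#' `density` (g/cm3), `formula` (empirical, for CO2 accounting).
#'
#' @return A tibble, one row per material.
#' @export
auxiliary_materials <- function() {
  tibble::tribble(
    ~name,      ~delta_cu, ~u_delta_cu, ~water_fraction, ~cp,  ~dudp, ~density, ~formula,
    "melinex",  -22902,    5,           0.0032,          1.3,  -0.03, 1.38,     "C10H8O4",
    "cotton",   -16240,    0,           0,               1.67, -0.29, 1.50,     "CH1.686O0.843"
  )
}

#' Electrical ignition energy from a capacitor discharge
#'
#' The ignition energy is the change in stored energy of the firing
#' capacitor, `0.5 C (V1^2 - V2^2)`.
#'
#' @param capacitance Capacitance in farad (the apparatus uses 1400 uF).
#' @param v_before,v_after Potential difference across the capacitor before
#'   and after discharge, V; `v_before >= v_after >= 0`.
#' @return Energy in J.
#' @examples
#' ignition_energy(1400e-6, 40, 20) # 0.84 J
#' @export
ignition_energy <- function(capacitance = 1400e-6, v_before, v_after) {
  stopifnot(capacitance > 0)
  if (any(v_after > v_before)) {
    stop("inconsistent record: v_after exceeds v_before", call. = FALSE)
  }
  if (any(v_after < 0)) stop("negative voltage", call. = FALSE)
  0.5 * capacitance * (v_before^2 - v_after^2)
}

#' Energy of the isothermal bomb process
#'
#' \deqn{\Delta U(IPB) = -\{\varepsilon_{cal} + \Delta m(H_2O)\,c_p(H_2O,l)
#'   + \varepsilon_f\}\,\Delta T_{ad} + \Delta U(ign)}
#' Negative for an exothermic combustion. `eps_cal` is referred to the
#' nominal calorimeter water load; `dm_h2o` is the deviation of the actual
#' water mass from that load.
#'
#' @param eps_cal Energy equivalent of the calorimeter, J/K (value or `qty`).
#' @param delta_T_ad Adiabatic temperature rise, K.
#' @param du_ign Ignition energy, J.
#' @param dm_h2o Deviation of calorimeter water mass from nominal, g.
#' @param eps_f Energy equivalent of the bomb contents after ignition, J/K.
#' @param cp_water Massic heat capacity of liquid water, J/(g K).
#' @return Energy in J.
#' @export
energy_ipb <- function(eps_cal, delta_T_ad, du_ign = 0, dm_h2o = 0,
                       eps_f = 0, cp_water = 4.184) {
  if (is_qty(eps_cal)) eps_cal <- eps_cal$value
  -(eps_cal + dm_h2o * cp_water + eps_f) * delta_T_ad + du_ign
}

# Resolve per-run inputs shared by sample reductions and calibrations:
# ignition energy, auxiliary energies, nitric-acid term, simplified
# standard-state term, and CO2 bookkeeping. `row` is a one-row list.
experiment_corrections <- function(row, aux, constants, corrections, p_bomb,
                                   dudp_sample, m_sample = NULL) {
  getv <- function(nm, default = 0) {
    v <- row[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }
  mel <- aux[aux$name == "melinex", ]
  cot <- aux[aux$name == "cotton", ]

  du_ign <- row[["du_ign"]]
  if (is.null(du_ign) || is.na(du_ign)) {
    du_ign <- ignition_energy(getv("c_ign", 1400e-6), getv("v_before"), getv("v_after"))
  }

  m_fuse <- getv("m_fuse")
  m_mel_dry <- getv("m_melinex") * (1 - mel$water_fraction)
  n_hno3 <- getv("n_hno3")
  if (is.na(getv("n_hno3", NA_real_)) && !is.null(row[["v_titre"]])) {
    # titre volume (cm3) of the default 0.1 mol/dm3 acid
    n_hno3 <- getv("v_titre") * getv("molarity", 0.1) / 1000
  }

  du_fuse <- if (corrections$fuse) m_fuse * cot$delta_cu else 0
  du_melinex <- if (corrections$melinex) m_mel_dry * mel$delta_cu else 0
  du_hno3 <- if (corrections$hno3) n_hno3 * -59.7e3 else 0

  aux_co2 <- 0
  if (m_fuse > 0) aux_co2 <- aux_co2 + m_fuse * co2_per_gram(cot$formula, constants)
  if (m_mel_dry > 0) aux_co2 <- aux_co2 + m_mel_dry * co2_per_gram(mel$formula, constants)

  du_sigma_aux <- if (corrections$standard_state) {
    (p_bomb - 0.1) * (m_mel_dry * mel$dudp + m_fuse * cot$dudp)
  } else 0
  du_sigma_sample <- function(m_s) {
    if (corrections$standard_state) (p_bomb - 0.1) * m_s * dudp_sample else 0
  }

  list(du_ign = du_ign, du_fuse = du_fuse, du_melinex = du_melinex,
       du_hno3 = du_hno3, du_sigma_aux = du_sigma_aux,
       du_sigma_sample = du_sigma_sample, aux_co2 = aux_co2,
       m_fuse = m_fuse, m_melinex_dry = m_mel_dry, n_hno3 = n_hno3)
}

default_corrections <- function(corrections = list()) {
  utils::modifyList(list(fuse = TRUE, melinex = TRUE, hno3 = TRUE,
                         standard_state = TRUE), corrections)
}

#' Reduce bomb combustion experiments to standard massic energies
#'
#' The workhorse of the combustion chain. For each experiment row the
#' adiabatic temperature rise is taken directly or extracted from its
#' temperature trace, the isothermal-bomb-process energy is evaluated, and
#' the auxiliary-material (fuse, Melinex bag), nitric-acid and standard-state
#' corrections are removed to leave the standard massic energy of combustion
#' of the sample:
#' \deqn{\Delta_c u^\circ = \frac{\Delta U(IPB) - \Delta U(fuse) -
#'   \Delta U(Melinex) - \Delta U(HNO_3) - \Delta U_\Sigma}{m_{sample}}.}
#'
#' The sample mass may be given directly (`m_sample`) or recovered from the
#' collected CO2 after subtracting the fuse and Melinex contributions. When
#' both are present the CO2 recovery ratio is reported and a warning is
#' attached when it falls outside \[0.99, 1.01\].
#'
#' The standard-state correction is the simplified pressure term
#' `m (du/dp)_T (p - 0.1 MPa)` summed over sample, Melinex and fuse; a full
#' user-supplied correction can be injected through `washburn_hook`.
#'
#' @param experiments Data frame, one row per combustion run. Recognised
#'   columns: `m_sample` (g, may be NA), `m_fuse` (g), `m_melinex` (as
#'   weighed, g), `dm_h2o` (g), `delta_T_ad` (K) or `trace` (list column of
#'   time/temperature/period data frames), `du_ign` (J) or
#'   `c_ign`/`v_before`/`v_after`, `n_hno3` (mol) or `v_titre` (cm3),
#'   `m_co2` (g), `eps_f` (J/K).
#' @param fuel Fuel formula (string or `chem_formula`).
#' @param calibration Energy equivalent: a [calibrate_bomb()] result, a
#'   `qty`, or a plain number in J/K.
#' @param aux Auxiliary-material table, see [auxiliary_materials()].
#' @param constants A [thermo_constants()] bundle.
#' @param corrections Named list of switches (`fuse`, `melinex`, `hno3`,
#'   `standard_state`), all `TRUE` by default.
#' @param p_bomb Bomb oxygen pressure, MPa (default 3.04).
#' @param dudp_sample Pressure coefficient (du/dp)_T of the sample,
#'   J/(g MPa); -0.2 is the typical organic-compound value.
#' @param cp_water J/(g K).
#' @param buoyancy Multiplicative apparent-to-true mass factor (default 1).
#' @param washburn_hook Optional `function(row, m_sample)` returning a full
#'   standard-state correction in J that replaces the simplified term.
#' @return A tibble with one row per run: the reduced `massic_energy` (J/g),
#'   the sample mass actually used, `delta_T_ad`, `du_ipb`, every correction
#'   term, `co2_recovery`, and a `note` column carrying warnings.
#' @examples
#' runs <- generate_bomb_experiments(n_runs = 2, noise_sd = 0, seed = 1)
#' reduce_bomb(runs, fuel = "C5H7NO", calibration = 15907.1)
#' @export
reduce_bomb <- function(experiments, fuel, calibration,
                        aux = auxiliary_materials(),
                        constants = thermo_constants(),
                        corrections = list(), p_bomb = 3.04,
                        dudp_sample = -0.2, cp_water = 4.184,
                        buoyancy = 1, washburn_hook = NULL) {
  corrections <- default_corrections(corrections)
  eps_cal <- if (inherits(calibration, "bomb_calibration")) {
    calibration$eps_cal$value
  } else if (is_qty(calibration)) calibration$value else as.numeric(calibration)
  fuel <- as_formula(fuel)
  experiments <- tibble::as_tibble(experiments)

  purrr::map_dfr(seq_len(nrow(experiments)), function(i) {
    row <- as.list(experiments[i, ])
    row <- purrr::map(row, function(v) if (is.list(v)) v[[1]] else v)
    note <- character(0)

    dT <- row[["delta_T_ad"]]
    if (is.null(dT) || is.na(dT)) {
      if (is.null(row[["trace"]])) {
        stop("incomplete record: no delta_T_ad and no trace in run ", i, call. = FALSE)
      }
      dT <- reduce_trace(row[["trace"]])$delta_T_ad
    }
    if (dT <= 0) stop("non-positive temperature rise in run ", i, call. = FALSE)

    cx <- experiment_corrections(row, aux, constants, corrections, p_bomb, dudp_sample)
    du_ipb <- energy_ipb(eps_cal, dT, cx$du_ign,
                         dm_h2o = row[["dm_h2o"]] %||% 0,
                         eps_f = row[["eps_f"]] %||% 0, cp_water = cp_water)
    if (is.na(du_ipb)) stop("incomplete record in run ", i, call. = FALSE)

    m_sample <- row[["m_sample"]]
    m_co2 <- row[["m_co2"]]
    if (is.null(m_sample) || is.na(m_sample)) {
      if (is.null(m_co2) || is.na(m_co2)) {
        stop("incomplete record: neither m_sample nor m_co2 in run ", i, call. = FALSE)
      }
      m_sample <- sample_mass_from_co2(m_co2, fuel, cx$aux_co2, constants)
    }
    if (m_sample <= 0) stop("non-positive sample mass in run ", i, call. = FALSE)
    m_sample <- m_sample * buoyancy

    co2_recovery <- NA_real_
    if (!is.null(m_co2) && !is.na(m_co2)) {
      expected <- theoretical_co2_mass(fuel, m_sample, constants) + cx$aux_co2
      co2_recovery <- m_co2 / expected
      if (co2_recovery < 0.99 || co2_recovery > 1.01) {
        note <- c(note, sprintf("CO2 recovery ratio %.4f outside [0.99, 1.01]",
                                co2_recovery))
      }
    }

    du_sigma <- if (!is.null(washburn_hook)) {
      washburn_hook(row, m_sample)
    } else {
      cx$du_sigma_aux + cx$du_sigma_sample(m_sample)
    }

    massic <- (du_ipb - cx$du_fuse - cx$du_melinex - cx$du_hno3 - du_sigma) / m_sample

    tibble::tibble(
      run = row[["run"]] %||% i,
      m_sample = m_sample, delta_T_ad = dT, du_ign = cx$du_ign,
      du_ipb = du_ipb, du_fuse = cx$du_fuse, du_melinex = cx$du_melinex,
      du_hno3 = cx$du_hno3, du_sigma = du_sigma,
      co2_recovery = co2_recovery, massic_energy = massic,
      note = paste(note, collapse = "; ")
    )
  })
}

#' Calibrate the calorimeter with a certified reference material
#'
#' Burns of certificated benzoic acid determine the energy equivalent of the
#' calorimeter. Each run is reduced in reverse: the known chemical energy
#' (certificate massic energy times sample mass, plus fuse, nitric-acid and
#' standard-state terms) and the ignition energy fix the total energy
#' equivalent, from which the bomb-contents term and the water-mass deviation
#' (referred to the nominal 3119.6 g load) are removed. The result is the
#' mean over runs with the standard deviation of the mean as its uncertainty.
#'
#' @param runs Data frame of calibration burns; same schema as
#'   [reduce_bomb()] (benzoic-acid pellets need no Melinex bag, so
#'   `m_melinex` is typically 0).
#' @param certificate Certified massic energy of combustion under certificate
#'   conditions, J/g (`qty` or number); the NBS 39j value is
#'   -(26434 +/- 3) J/g.
#' @param reference_formula Empirical formula of the reference material
#'   (benzoic acid, C7H6O2).
#' @param dudp_reference Pressure coefficient of the reference, J/(g MPa).
#' @inheritParams reduce_bomb
#' @return An object of class `"bomb_calibration"` with fields `eps_cal`
#'   (`qty`, J/K), `n_runs`, `per_run` (tibble), `certificate`.
#' @examples
#' runs <- generate_bomb_experiments(
#'   n_runs = 3, true_massic_energy = -26434, fuel = "C7H6O2",
#'   m_melinex_range = c(0, 0), noise_sd = 0, seed = 7)
#' calibrate_bomb(runs)
#' @export
calibrate_bomb <- function(runs, certificate = qty(-26434, 3, "J/g"),
                           reference_formula = "C7H6O2",
                           aux = auxiliary_materials(),
                           constants = thermo_constants(),
                           corrections = list(), p_bomb = 3.04,
                           dudp_reference = -0.12, cp_water = 4.184) {
  runs <- tibble::as_tibble(runs)
  if (nrow(runs) < 2) {
    stop("calibration needs at least 2 runs to report an uncertainty", call. = FALSE)
  }
  corrections <- default_corrections(corrections)
  certificate <- as_qty(certificate, "J/g")

  per_run <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    row <- as.list(runs[i, ])
    row <- purrr::map(row, function(v) if (is.list(v)) v[[1]] else v)
    dT <- row[["delta_T_ad"]]
    if (is.null(dT) || is.na(dT)) dT <- reduce_trace(row[["trace"]])$delta_T_ad
    cx <- experiment_corrections(row, aux, constants, corrections, p_bomb,
                                 dudp_reference)
    m_s <- row[["m_sample"]]
    if (is.null(m_s) || is.na(m_s)) {
      m_s <- sample_mass_from_co2(row[["m_co2"]], reference_formula, cx$aux_co2,
                                  constants)
    }
    du_chem <- m_s * certificate$value + cx$du_fuse + cx$du_melinex +
      cx$du_hno3 + cx$du_sigma_aux + cx$du_sigma_sample(m_s)
    eps_total <- (cx$du_ign - du_chem) / dT
    eps_cal <- eps_total - (row[["eps_f"]] %||% 0) -
      (row[["dm_h2o"]] %||% 0) * cp_water
    tibble::tibble(run = row[["run"]] %||% i, m_sample = m_s,
                   delta_T_ad = dT, eps_cal = eps_cal)
  })

  m <- mean(per_run$eps_cal)
  sdom <- stats::sd(per_run$eps_cal) / sqrt(nrow(per_run))
  structure(list(eps_cal = qty(m, sdom, "J/K"), n_runs = nrow(per_run),
                 per_run = per_run, certificate = certificate),
            class = "bomb_calibration")
}

#' @export
print.bomb_calibration <- function(x, ...) {
  cat("<bomb_calibration>", format(x$eps_cal, digits = 1), "from", x$n_runs, "runs\n")
  invisible(x)
}

#' @export
tidy.bomb_calibration <- function(x, ...) {
  dplyr::mutate(x$per_run, deviation = .data$eps_cal - mean(.data$eps_cal))
}

#' @export
glance.bomb_calibration <- function(x, ...) {
  tibble::tibble(eps_cal = x$eps_cal$value, u_eps_cal = x$eps_cal$u,
                 n_runs = x$n_runs,
                 certificate = x$certificate$value,
                 u_certificate = x$certificate$u)
}
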