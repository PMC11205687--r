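#' Simulate a bomb-calorimeter temperature trace
#'
#' Closed-form Newtonian model of the calorimeter record: in the fore period
#' the temperature relaxes toward the jacket convergence temperature with
#' cooling constant `k`; at ignition an energy release equivalent to an
#' adiabatic rise `delta_T_ad` enters with a fast exponential time constant
#' `tau`, superimposed on the same Newtonian exchange,
#' \deqn{T(t) = T_{conv} + (T_{ign}-T_{conv})e^{-kt} +
#'   \Delta T_{ad}\,\frac{r}{r-k}\left(e^{-kt} - e^{-rt}\right),\quad r = 1/\tau.}
#' This is a model of the instrument class sufficient to validate
#' heat-exchange corrections, not a combustion-kinetics simulation.
#'
#' @param delta_T_ad True adiabatic temperature rise, K.
#' @param T_ignition Temperature at ignition, K.
#' @param T_convergence Jacket convergence temperature, K.
#' @param cooling_constant Newtonian cooling constant, 1/s (1.5e-3 per
#'   minute, the typical magnitude for this instrument class, is 2.5e-5/s).
#' @param tau Time constant of the main-period energy release, s.
#' @param interval Reading interval, s.
#' @param n_fore,n_main,n_after Number of readings per period.
#' @param noise_sd Gaussian noise on each reading, K (the instrument
#'   resolution is 1e-4 K). Uses the current RNG state; seed upstream.
#' @return A tibble with columns `time` (s, ignition at 0), `temperature`
#'   (K) and `period`.
#' @examples
#' tr <- simulate_trace(delta_T_ad = 1.2, noise_sd = 0)
#' reduce_trace(tr)$delta_T_ad
#' @export
simulate_trace <- function(delta_T_ad, T_ignition = 298.150,
                           T_convergence = 298.6,
                           cooling_constant = 1.5e-3 / 60, tau = 45,
                           interval = 10, n_fore = 100, n_main = 100,
                           n_after = 100, noise_sd = 1e-4) {
  stopifnot(delta_T_ad >= 0, tau > 0, interval > 0, cooling_constant >= 0)
  k <- cooling_constant; r <- 1 / tau
  t_fore <- seq(-n_fore * interval, 0, by = interval)
  t_post <- seq(interval, (n_main + n_after) * interval, by = interval)
  T_fore <- T_convergence + (T_ignition - T_convergence) * exp(-k * t_fore)
  gain <- if (abs(r - k) < 1e-12) {
    delta_T_ad * r * t_post * exp(-r * t_post)  # degenerate r = k limit
  } else {
    delta_T_ad * r / (r - k) * (exp(-k * t_post) - exp(-r * t_post))
  }
  T_post <- T_convergence + (T_ignition - T_convergence) * exp(-k * t_post) + gain
  out <- tibble::tibble(
    time = c(t_fore, t_post),
    temperature = c(T_fore, T_post),
    period = c(rep("fore", length(t_fore)),
               rep("main", n_main), rep("after", n_after))
  )
  if (noise_sd > 0) {
    out$temperature <- out$temperature + stats::rnorm(nrow(out), 0, noise_sd)
  }
  out
}

#' Generate synthetic bomb-combustion experiments
#'
#' Produces a set of experiment records statistically faithful to a
#' combustion campaign on a liquid C/H/N/O compound: sample sealed in a
#' Melinex bag, cotton fuse, capacitor ignition, nitric-acid formation, CO2
#' collection, and a fore/main/after temperature trace following the
#' Newtonian model of [simulate_trace()]. The record is constructed so that
#' the reduction chain ([reduce_bomb()]) recovers `true_massic_energy`
#' exactly in the noise-free limit.
#'
#' @param n_runs Number of experiments.
#' @param true_massic_energy True standard massic energy of combustion, J/g
#'   (negative).
#' @param fuel Fuel formula.
#' @param seed Integer seed; mandatory so campaigns are reproducible.
#' @param sample_mass_range,fuse_mass_range,m_melinex_range Uniform sampling
#'   ranges, g.
#' @param eps_cal Energy equivalent, J/K.
#' @param eps_f Bomb-contents energy equivalent, J/K.
#' @param dm_h2o_range Range of calorimeter-water deviation, g.
#' @param n_hno3_range Range of nitric acid formed, mol.
#' @param T_convergence,cooling_constant,tau,interval Trace model
#'   parameters, see [simulate_trace()].
#' @param noise_sd Temperature noise per reading, K.
#' @param traces If `TRUE` (default) each run carries a `trace` to be
#'   reduced; if `FALSE` the exact `delta_T_ad` is recorded instead.
#' @param aux Auxiliary-material table.
#' @param constants A [thermo_constants()] bundle.
#' @param p_bomb,dudp_sample,cp_water As in [reduce_bomb()].
#' @return A tibble with the [reduce_bomb()] input schema.
#' @export
generate_bomb_experiments <- function(n_runs = 6,
                                      true_massic_energy = -29588.1,
                                      fuel = "C5H7NO", seed,
                                      sample_mass_range = c(0.5, 0.7),
                                      fuse_mass_range = c(0.002, 0.004),
                                      m_melinex_range = c(0.04, 0.06),
                                      eps_cal = 15907.1, eps_f = 16,
                                      dm_h2o_range = c(-0.5, 0.5),
                                      n_hno3_range = c(2e-4, 4e-4),
                                      T_convergence = 298.6,
                                      cooling_constant = 1.5e-3 / 60,
                                      tau = 45, interval = 10,
                                      noise_sd = 1e-4, traces = TRUE,
                                      aux = auxiliary_materials(),
                                      constants = thermo_constants(),
                                      p_bomb = 3.04, dudp_sample = -0.2,
                                      cp_water = 4.184) {
  if (missing(seed)) stop("seed is required for reproducible generation", call. = FALSE)
  set.seed(seed)
  corrections <- default_corrections(list())
  runif_in <- function(rg) stats::runif(1, rg[1], rg[2])

  purrr::map_dfr(seq_len(n_runs), function(i) {
    m_sample <- runif_in(sample_mass_range)
    m_fuse <- runif_in(fuse_mass_range)
    m_melinex <- runif_in(m_melinex_range)
    dm_h2o <- runif_in(dm_h2o_range)
    n_hno3 <- runif_in(n_hno3_range)
    v_before <- 40
    v_after <- stats::runif(1, 18, 22)

    row <- list(m_fuse = m_fuse, m_melinex = m_melinex, n_hno3 = n_hno3,
                c_ign = 1400e-6, v_before = v_before, v_after = v_after)
    cx <- experiment_corrections(row, aux, constants, corrections, p_bomb,
                                 dudp_sample)
    du_chem <- m_sample * true_massic_energy + cx$du_fuse + cx$du_melinex +
      cx$du_hno3 + cx$du_sigma_aux + cx$du_sigma_sample(m_sample)
    dT_ad <- (cx$du_ign - du_chem) / (eps_cal + dm_h2o * cp_water + eps_f)

    m_co2 <- theoretical_co2_mass(fuel, m_sample, constants) + cx$aux_co2

    out <- tibble::tibble(
      run = i, m_sample = m_sample, m_fuse = m_fuse, m_melinex = m_melinex,
      dm_h2o = dm_h2o, n_hno3 = n_hno3, c_ign = 1400e-6,
      v_before = v_before, v_after = v_after, eps_f = eps_f, m_co2 = m_co2
    )
    if (traces) {
      out$delta_T_ad <- NA_real_
      out$trace <- list(simulate_trace(
        dT_ad, T_convergence = T_convergence,
        cooling_constant = cooling_constant, tau = tau, interval = interval,
        noise_sd = noise_sd))
    } else {
      out$delta_T_ad <- dT_ad
    }
    out
  })
}

#' Generate synthetic Calvet drop runs
#'
#' Each observed enthalpy is the true vaporization enthalpy at the reference
#' temperature plus the gas-phase heat-capacity integral up to the oven
#' temperature, plus Gaussian noise — the statistical structure of a drop
#' campaign whose reduction ([reduce_calvet()]) round-trips to the truth.
#'
#' @param n_runs Number of drops (the campaign convention is 6).
#' @param true_dvapH True vaporization enthalpy at `T_ref`, kJ/mol.
#' @param cp A [cp_polynomial()].
#' @param T_oven Oven temperature, K.
#' @param noise_sd Per-run noise, kJ/mol. The default 0.98 gives a standard
#'   deviation of the mean of about 0.4 kJ/mol over six drops, the scatter
#'   scale of the instrument.
#' @param m_sample_range Sample-mass sampling range, mg.
#' @param T_ref Reference temperature, K.
#' @param seed Integer seed; mandatory.
#' @return A tibble with columns `run`, `m_sample` (mg), `T_oven` (K),
#'   `dH_obs` (kJ/mol).
#' @export
generate_calvet_runs <- function(n_runs = 6, true_dvapH = 49.1,
                                 cp = synthetic_cp_polynomial("furfurylamine"),
                                 T_oven = 344.5, noise_sd = 0.98,
                                 m_sample_range = c(3, 7), T_ref = 298.15,
                                 seed) {
  if (missing(seed)) stop("seed is required for reproducible generation", call. = FALSE)
  stopifnot(n_runs >= 2)
  set.seed(seed)
  dH_true <- true_dvapH + cp_integral(cp, T_ref, T_oven)
  tibble::tibble(
    run = seq_len(n_runs),
    m_sample = stats::runif(n_runs, m_sample_range[1], m_sample_range[2]),
    T_oven = T_oven,
    dH_obs = dH_true + stats::rnorm(n_runs, 0, noise_sd)
  )
}
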