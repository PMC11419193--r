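# Physical constants and unit conversions. All internal physics is SI
# (m, s, Pa, kg); user-facing interfaces use mmHg, mm, mL/min and uL.

#' @keywords internal
MMHG_TO_PA <- 133.322

#' @keywords internal
M3S_TO_MLMIN <- 6e7  # m^3/s -> mL/min

#' Hemodynamic boundary-condition and fluid parameters
#'
#' Bundles the constants of the steady network flow model: the Dirichlet root
#' pressure (mean arterial pressure), the venous sink pressure behind every
#' terminal node, the blood viscosity entering the Hagen-Poiseuille edge
#' conductance, and the lumped terminal conductance parameter `gamma_a`.
#' `gamma_a / mu` is the hydraulic conductance (m^3/(Pa s)) of the
#' unsegmented vasculature connecting each terminal node to the sink.
#'
#' @param p_map Root (mean arterial) pressure, mmHg.
#' @param p_cvp Sink (central venous) pressure, mmHg.
#' @param mu Blood dynamic viscosity, Pa s.
#' @param gamma_a Terminal conductance parameter, m^3. Must be >= 0; it is
#'   usually set by [calibrate_gamma_a()] rather than by hand.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(p_map = 100, p_cvp = 5, mu = 8.9e-4, gamma_a = 1e-10) {
  if (!is.numeric(p_map) || !is.numeric(p_cvp) || p_map <= p_cvp)
    stop("p_map must exceed p_cvp")
  if (mu <= 0) stop("mu must be positive")
  if (gamma_a < 0) stop("gamma_a must be non-negative")
  structure(list(p_map = p_map, p_cvp = p_cvp, mu = mu, gamma_a = gamma_a),
            class = "flow_params")
}

#' Bolus composition and reaction parameters
#'
#' Physical properties of the injected dichloroacetyl chloride (DCACl) /
#' Lipiodol bolus and of the carrier blood, plus the first-order hydrolysis
#' time constant `gamma_t` (1/s) that the calibration machinery estimates.
#' The DCACl volume fraction defaults to `epsilon = M * W / rho_dcacl`
#' (2 M, molar mass 0.147 kg/mol, density 1532 kg/m^3), i.e. 0.1919.
#'
#' @param gamma_t Hydrolysis time constant, 1/s.
#' @param epsilon DCACl volume fraction of the bolus (dimensionless). If
#'   `NULL`, computed as `molarity * 1000 * molar_mass / rho_dcacl`.
#' @param rho_dcacl DCACl density, kg/m^3.
#' @param rho_o Bolus density, kg/m^3.
#' @param cp_o Bolus specific heat, J/(kg K) (recorded; the energy equation
#'   uses the blood values).
#' @param mu_o Bolus viscosity, Pa s (recorded; the flow field is solved with
#'   blood viscosity only and the bolus is advected passively).
#' @param h Exothermic energy release of hydrolysis, J/mol.
#' @param molar_mass DCACl molar mass, kg/mol.
#' @param molarity DCACl molarity in the bolus, mol/L.
#' @param rho_b,cp_b Blood density (kg/m^3) and specific heat (J/(kg K)).
#' @param v_dcacl_ul Injected bolus volume, microlitres.
#' @return An object of class `bolus_params`.
#' @export
bolus_params <- function(gamma_t = 13, epsilon = NULL,
                         rho_dcacl = 1532, rho_o = 1280,
                         cp_o = 1970, mu_o = 7e-4,
                         h = 138e3, molar_mass = 0.147, molarity = 2,
                         rho_b = 1045, cp_b = 3600,
                         v_dcacl_ul = 200) {
  if (is.null(epsilon))
    epsilon <- dcacl_saturation(molarity, molar_mass, rho_dcacl)
  stopifnot(epsilon > 0, epsilon < 1,
            rho_dcacl > 0, rho_o > 0, cp_o > 0, h > 0,
            molar_mass > 0, gamma_t >= 0, v_dcacl_ul > 0,
            rho_b > 0, cp_b > 0)
  structure(list(gamma_t = gamma_t, epsilon = epsilon,
                 rho_dcacl = rho_dcacl, rho_o = rho_o, cp_o = cp_o,
                 mu_o = mu_o, h = h, molar_mass = molar_mass,
                 molarity = molarity, rho_b = rho_b, cp_b = cp_b,
                 v_dcacl_ul = v_dcacl_ul),
            class = "bolus_params")
}

#' DCACl volume fraction of the bolus from molarity and molar mass
#'
#' `epsilon = M * W / rho_DCACl` with molarity in mol/L (converted to
#' mol/m^3), molar mass in kg/mol and density in kg/m^3. With the defaults
#' (2 M, 0.147 kg/mol, 1532 kg/m^3) this evaluates to 0.1919.
#'
#' @param molarity mol/L
#' @param molar_mass kg/mol
#' @param rho_dcacl kg/m^3
#' @return Dimensionless volume fraction in (0, 1).
#' @export
dcacl_saturation <- function(molarity = 2, molar_mass = 0.147,
                             rho_dcacl = 1532) {
  stopifnot(molarity > 0, molar_mass > 0, rho_dcacl > 0)
  molarity * 1000 * molar_mass / rho_dcacl
}

#' Default run configuration
#'
#' All model constants in one list, suitable for serialization to YAML and
#' for the command-line interface. A run started from this configuration
#' uses the standard parameter set of the model.
#'
#' @param delta Damage threshold for embolization tagging, fraction in (0,1).
#' @param seed Integer seed used for every stochastic component.
#' @return A named list with `flow`, `bolus`, `delta` and `seed` entries.
#' @export
default_config <- function(delta = 0.01, seed = 1L) {
  stopifnot(delta > 0, delta < 1)
  list(flow = unclass(flow_params()), bolus = unclass(bolus_params()),
       delta = delta, seed = as.integer(seed))
}
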