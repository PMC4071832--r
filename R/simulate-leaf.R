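#' Rubisco and RuBP-regeneration kinetics at leaf temperature
#'
#' Arrhenius-scaled Michaelis constants for carboxylation (K_c) and
#' oxygenation (K_o), and the effective K_m = K_c (1 + O/K_o) with O the
#' chloroplastic oxygen mole fraction. 25 degC values: K_c 404.9 umol mol^-1
#' (E_a 79 430 J mol^-1), K_o 278.4 mmol mol^-1 (E_a 36 380 J mol^-1).
#'
#' @param T_leaf Leaf temperature, degC.
#' @param O Oxygen mole fraction, mmol mol^-1. Default 210.
#' @return A list with `K_c` (umol mol^-1), `K_o` (mmol mol^-1), `K_m`
#'   (umol mol^-1), `gamma_star` (umol mol^-1).
#' @export
fvcb_kinetics <- function(T_leaf, O = 210) {
  K_c <- arrhenius(T_leaf, 404.9, 79430)
  K_o <- arrhenius(T_leaf, 278.4, 36380)
  list(K_c = K_c, K_o = K_o, K_m = K_c * (1 + O / K_o),
       gamma_star = gamma_star_at_temperature(T_leaf))
}

#' Physiological parameters of one simulated leaf
#'
#' @param g_sc_true Stomatal conductance to CO2, mol m^-2 s^-1.
#' @param g_m_true Mesophyll conductance to CO2, mol m^-2 s^-1.
#' @param J_true Electron transport rate, umol e- m^-2 s^-1.
#' @param V_cmax Maximum carboxylation rate, umol m^-2 s^-1.
#' @param R_d Day respiration, umol m^-2 s^-1.
#' @param T_leaf Leaf temperature, degC.
#' @param C_a Ambient CO2 mole fraction, umol mol^-1. Default 400
#'   (the cuvette setpoint).
#' @param PPFD Incident light, umol m^-2 s^-1. Default 1800 (saturating).
#' @return A list of class `leaf_params`.
#' @export
leaf_params <- function(g_sc_true, g_m_true, J_true, V_cmax = 1e6, R_d = 1,
                        T_leaf = 30, C_a = 400, PPFD = 1800) {
  for (nm in c("g_sc_true", "g_m_true", "J_true", "V_cmax", "R_d", "C_a", "PPFD")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  check_scalar_number(T_leaf, "T_leaf", lower = -10, upper = 60)
  if (C_a <= gamma_star_at_temperature(T_leaf)) {
    abort("`C_a` must exceed Gamma* at T_leaf.", class = "photolim_infeasible_parameters")
  }
  structure(list(g_sc_true = g_sc_true, g_m_true = g_m_true, J_true = J_true,
                 V_cmax = V_cmax, R_d = R_d, T_leaf = T_leaf, C_a = C_a,
                 PPFD = PPFD),
            class = "leaf_params")
}

#' Steady-state leaf photosynthesis (forward FvCB model)
#'
#' Solves the coupled diffusion-biochemistry fixed point
#' A = min(A_c, A_j) with
#' A_j = J (C_c - Gamma*) / (4 C_c + 8 Gamma*) - R_d (RuBP regeneration),
#' A_c = V_cmax (C_c - Gamma*) / (C_c + K_m) - R_d (Rubisco), and
#' C_c = C_a - A (1/g_sc + 1/g_m), by bisection on C_c in (Gamma*, C_a\].
#'
#' @param params A [leaf_params()] object.
#' @param tol Bisection residual tolerance on C_c, umol mol^-1.
#'   Default 1e-10.
#' @return A list: `A_N`, `C_i`, `C_c` and `limiting_branch` (`"RuBP"` or
#'   `"Rubisco"`).
#' @examples
#' p <- leaf_params(g_sc_true = 0.2, g_m_true = 0.2, J_true = 150, R_d = 1,
#'                  T_leaf = 25)
#' simulate_leaf_steady_state(p)
#' @export
simulate_leaf_steady_state <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "leaf_params"))
  kin <- fvcb_kinetics(params$T_leaf)
  gs <- kin$gamma_star
  r_tot <- 1 / params$g_sc_true + 1 / params$g_m_true

  assim <- function(C_c) {
    A_j <- params$J_true * (C_c - gs) / (4 * C_c + 8 * gs) - params$R_d
    A_c <- params$V_cmax * (C_c - gs) / (C_c + kin$K_m) - params$R_d
    pmin(A_j, A_c)
  }
  resid <- function(C_c) params$C_a - assim(C_c) * r_tot - C_c

  lo <- gs + 1e-12; hi <- params$C_a
  if (resid(lo) < 0 || resid(hi) > 0) {
    abort("No steady-state solution in (Gamma*, C_a]: infeasible parameters.",
          class = "photolim_infeasible_parameters")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  C_c <- (lo + hi) / 2
  A_N <- assim(C_c)
  A_j <- params$J_true * (C_c - gs) / (4 * C_c + 8 * gs) - params$R_d
  A_c <- params$V_cmax * (C_c - gs) / (C_c + kin$K_m) - params$R_d
  list(A_N = A_N, C_i = params$C_a - A_N / params$g_sc_true, C_c = C_c,
       limiting_branch = if (A_j <= A_c) "RuBP" else "Rubisco")
}

#' Back-calculate fluorescence signals from an electron transport rate
#'
#' Inverts J = Phi_PSII * PPFD * psii_fraction * absorptance and renders the
#' pair (F_s, F_m') at a fixed (arbitrary) F_m'; only the ratio carries
#' information, so the scale is immaterial.
#'
#' @param J Electron transport rate, umol e- m^-2 s^-1.
#' @param PPFD Incident light, umol m^-2 s^-1.
#' @param constants A [fluor_constants()] object.
#' @param F_m_prime Rendered maximal fluorescence, arbitrary units.
#'   Default 2000.
#' @return A tibble with columns `F_s` and `F_m_prime`. Vectorised over `J`
#'   and `PPFD`.
#' @examples
#' fluorescence_from_J(209.25, 1800) # F_s = 1500
#' @export
fluorescence_from_J <- function(J, PPFD, constants = fluor_constants(),
                                F_m_prime = 2000) {
  phi <- J / (PPFD * constants$psii_fraction * constants$absorptance)
  if (any(phi > 1 + 1e-12) || any(phi < 0)) {
    abort("Implied Phi_PSII outside [0, 1]: J too large for this PPFD.",
          class = "photolim_invalid_input")
  }
  phi <- pmin(phi, 1)
  tibble(F_s = F_m_prime * (1 - phi), F_m_prime = F_m_prime)
}
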