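#' Fluorescence-to-electron-transport constants
#'
#' Constants used to convert PSII photochemical efficiency into a linear
#' electron transport rate: the fraction of absorbed quanta reaching PSII
#' (0.5 assumes equal energy partitioning between the photosystems) and the
#' leaf absorptance (0.93, a typical integrating-sphere value for
#' sclerophyllous leaves).
#'
#' @param psii_fraction Fraction of absorbed photons partitioned to PSII,
#'   in (0, 1]. Default 0.5.
#' @param absorptance Leaf absorptance (1 - reflectance - transmittance),
#'   in (0, 1]. Default 0.93.
#' @return A list of class `fluor_constants`.
#' @examples
#' fluor_constants()
#' @export
fluor_constants <- function(psii_fraction = 0.5, absorptance = 0.93) {
  if (!is.numeric(psii_fraction) || psii_fraction <= 0 || psii_fraction > 1) {
    abort("`psii_fraction` must be in (0, 1].", class = "photolim_invalid_constant")
  }
  if (!is.numeric(absorptance) || absorptance <= 0 || absorptance > 1) {
    abort("`absorptance` must be in (0, 1].", class = "photolim_invalid_constant")
  }
  structure(list(psii_fraction = psii_fraction, absorptance = absorptance),
            class = "fluor_constants")
}

#' Actual PSII photochemical efficiency from modulated fluorescence
#'
#' Computes Phi_PSII = (Fm' - Fs) / Fm' from steady-state fluorescence in the
#' light and the light-saturating-pulse maximum.
#'
#' @param F_s Steady-state fluorescence (arbitrary units), `0 <= F_s <= F_m_prime`.
#' @param F_m_prime Maximal fluorescence under a saturating pulse; must be > 0.
#' @return Phi_PSII, dimensionless in \[0, 1\]. Vectorised.
#' @examples
#' phi_psii(1500, 2000) # 0.25
#' @export
phi_psii <- function(F_s, F_m_prime) {
  if (any(!is.finite(F_m_prime)) || any(F_m_prime <= 0)) {
    abort("`F_m_prime` must be positive and finite.",
          class = "photolim_invalid_fluorescence")
  }
  if (any(!is.finite(F_s)) || any(F_s < 0) || any(F_s > F_m_prime)) {
    abort("`F_s` must satisfy 0 <= F_s <= F_m_prime.",
          class = "photolim_invalid_fluorescence")
  }
  (F_m_prime - F_s) / F_m_prime
}

#' Linear electron transport rate from PSII efficiency
#'
#' J = Phi_PSII * PPFD * psii_fraction * absorptance, in umol electrons
#' m^-2 s^-1.
#'
#' @param phi Phi_PSII, dimensionless.
#' @param PPFD Incident photosynthetic photon flux density, umol m^-2 s^-1.
#' @param constants A [fluor_constants()] object.
#' @return J in umol e- m^-2 s^-1. Vectorised.
#' @examples
#' electron_transport_rate(0.25, 1800) # 209.25
#' @export
electron_transport_rate <- function(phi, PPFD, constants = fluor_constants()) {
  stopifnot(inherits(constants, "fluor_constants"))
  if (any(phi < 0) || any(PPFD < 0)) {
    abort("`phi` and `PPFD` must be non-negative.", class = "photolim_invalid_input")
  }
  phi * PPFD * constants$psii_fraction * constants$absorptance
}

#' CO2 compensation point (Gamma*) at leaf temperature
#'
#' Arrhenius temperature response of the photorespiratory CO2 compensation
#' point, with a 25 degC value of 42.75 umol mol^-1 and activation energy
#' 37 830 J mol^-1 (the standard tobacco-derived kinetics).
#'
#' @param T_leaf Leaf temperature, degC. Values outside -10..60 degC trigger a
#'   warning.
#' @param value_25 Gamma* at 25 degC, umol mol^-1.
#' @param delta_Ha Activation energy, J mol^-1.
#' @return Gamma* in umol mol^-1. Vectorised over `T_leaf`.
#' @examples
#' gamma_star_at_temperature(25) # 42.75
#' @export
gamma_star_at_temperature <- function(T_leaf, value_25 = 42.75, delta_Ha = 37830) {
  if (any(T_leaf < -10 | T_leaf > 60)) {
    warn("`T_leaf` outside the physiological range -10..60 degC.")
  }
  arrhenius(T_leaf, value_25, delta_Ha)
}

# Arrhenius scaling relative to 25 degC; R = 8.314 J mol^-1 K^-1.
arrhenius <- function(T_leaf, value_25, delta_Ha) {
  T_K <- T_leaf + 273.15
  value_25 * exp(delta_Ha * (T_K - 298.15) / (298.15 * 8.314 * T_K))
}

#' Stomatal conductance to CO2 from conductance to water vapour
#'
#' g_sc = g_sw / 1.6, using the binary diffusivity ratio of water vapour to
#' CO2 in air; boundary-layer conductance is assumed non-limiting (well-mixed
#' cuvette).
#'
#' @param g_sw Stomatal conductance to H2O, mol m^-2 s^-1, non-negative.
#' @return g_sc in mol m^-2 s^-1. Vectorised.
#' @export
stomatal_conductance_co2 <- function(g_sw) {
  if (any(g_sw < 0)) abort("`g_sw` must be non-negative.", class = "photolim_invalid_input")
  g_sw / 1.6
}

#' Chloroplastic CO2 and mesophyll conductance by the variable-J method
#'
#' Combines gas exchange with the fluorescence-derived electron transport rate
#' to estimate the chloroplastic CO2 mole fraction and mesophyll conductance:
#' \deqn{C_c = \Gamma^* [J + 8(A_N + R_d)] / [J - 4(A_N + R_d)]}
#' \deqn{g_m = A_N / (C_i - C_c)}
#'
#' @param A_N Net CO2 assimilation, umol m^-2 s^-1.
#' @param C_i Substomatal CO2 mole fraction, umol mol^-1.
#' @param J Electron transport rate, umol e- m^-2 s^-1.
#' @param R_d Day respiration (taken equal to measured dark respiration),
#'   umol m^-2 s^-1.
#' @param gamma_star Gamma* at the measurement temperature, umol mol^-1.
#' @return A tibble with columns `C_c`, `g_m` and `flag` (`"ok"`,
#'   `"infeasible_j"` when `J <= 4 (A_N + R_d)`, or `"nonpositive_ci_cc"` when
#'   `C_i - C_c <= 0` with positive assimilation; flagged rows carry `NA` for
#'   the undefined quantity). Vectorised over all arguments.
#' @examples
#' variable_j_gm(A_N = 15, C_i = 250, J = 120, R_d = 1, gamma_star = 40)
#' @export
variable_j_gm <- function(A_N, C_i, J, R_d, gamma_star) {
  n <- max(length(A_N), length(C_i), length(J), length(R_d), length(gamma_star))
  A_N <- rep_len(A_N, n); C_i <- rep_len(C_i, n); J <- rep_len(J, n)
  R_d <- rep_len(R_d, n); gamma_star <- rep_len(gamma_star, n)

  x <- A_N + R_d                       # carboxylation demand, umol m-2 s-1
  denom <- J - 4 * x
  flag <- rep("ok", n)
  flag[denom <= 0] <- "infeasible_j"

  C_c <- ifelse(denom > 0, gamma_star * (J + 8 * x) / denom, NA_real_)
  gap <- C_i - C_c
  g_m <- ifelse(denom > 0 & gap > 0, A_N / gap, NA_real_)
  # zero net flux with zero respiration: C_c = Gamma*, g_m = 0 by continuity
  zero_flux <- denom > 0 & A_N == 0 & R_d == 0
  g_m[zero_flux] <- 0
  bad_gap <- denom > 0 & gap <= 0 & A_N > 0
  flag[bad_gap] <- "nonpositive_ci_cc"
  tibble(C_c = C_c, g_m = g_m, flag = flag)
}

#' Sensitivity of estimated C_c to assimilation (Harley reliability criterion)
#'
#' Analytic derivative of the variable-J chloroplastic CO2 estimate with
#' respect to net assimilation at fixed J and R_d:
#' \deqn{dC_c/dA_N = 12 \Gamma^* J / [J - 4(A_N + R_d)]^2}
#' Estimates are conventionally accepted when this sensitivity lies between
#' 10 and 50 (mol mol^-1)/(mol m^-2 s^-1): below the window g_m barely
#' responds to the data, above it small assimilation errors dominate.
#'
#' @inheritParams variable_j_gm
#' @param low,high Inclusive reliability window bounds. Defaults 10 and 50.
#' @return A tibble with columns `dCc_dAN` and `reliable` (logical; `FALSE`
#'   with `dCc_dAN = Inf` when `J <= 4 (A_N + R_d)`). Vectorised.
#' @examples
#' harley_reliability(A_N = 15, J = 120, R_d = 1, gamma_star = 40)
#' @export
harley_reliability <- function(A_N, J, R_d, gamma_star, low = 10, high = 50) {
  x <- A_N + R_d
  denom <- J - 4 * x
  dCc_dAN <- ifelse(denom > 0, 12 * gamma_star * J / denom^2, Inf)
  tibble(dCc_dAN = dCc_dAN,
         reliable = is.finite(dCc_dAN) & dCc_dAN >= low & dCc_dAN <= high)
}

#' Calibration of PSII efficiency against gross CO2 quantum yield
#'
#' Under non-photorespiratory (low O2) conditions the quantum efficiency of
#' gross CO2 fixation is Phi_CO2 = (A_N + R_d)/PPFD and should be linearly
#' related to Phi_PSII across light levels. This fit is a validity check on
#' the fluorescence-based electron transport estimate; a curvilinear
#' relationship (quadratic term with |t| > 2) triggers a non-linearity
#' warning but no correction.
#'
#' @param data A data frame of low-O2 records with columns `F_s`, `F_m_prime`,
#'   `PPFD`, `A_N`, `R_d` (or precomputed `phi_psii` and `phi_co2`).
#' @return An object of class `phi_calibration`: a list with `slope`,
#'   `intercept`, `r_squared`, `n`, `nonlinear` and the underlying `fit`.
#'   Supports [tidy()] and [glance()].
#' @export
calibrate_phi_relationship <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("phi_psii", "phi_co2") %in% names(data))) {
    data <- data %>%
      mutate(phi_psii = phi_psii(.data$F_s, .data$F_m_prime),
             phi_co2 = (.data$A_N + .data$R_d) / .data$PPFD)
  }
  data <- data[complete.cases(data[, c("phi_psii", "phi_co2")]), , drop = FALSE]
  if (nrow(data) < 3) {
    abort("At least 3 records are required to calibrate the relationship.",
          class = "photolim_insufficient_data")
  }
  if (var(data$phi_co2) == 0) {
    abort("`phi_co2` is constant: degenerate calibration design.",
          class = "photolim_degenerate_design")
  }
  fit <- lm(phi_psii ~ phi_co2, data = data)
  # summary.lm warns on exactly collinear calibration points; the fit and
  # its coefficient table are still what we need
  coef_table <- suppressWarnings(summary(fit)$coefficients)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((data$phi_psii - mean(data$phi_psii))^2)
  nonlinear <- FALSE
  if (length(unique(data$phi_co2)) >= 3 && nrow(data) >= 4) {
    qfit <- lm(phi_psii ~ phi_co2 + I(phi_co2^2), data = data)
    tval <- suppressWarnings(summary(qfit)$coefficients)
    if ("I(phi_co2^2)" %in% rownames(tval) &&
        is.finite(tval["I(phi_co2^2)", "t value"]) &&
        abs(tval["I(phi_co2^2)", "t value"]) > 2) {
      nonlinear <- TRUE
      warn("Phi_PSII vs Phi_CO2 relationship appears non-linear (quadratic |t| > 2).")
    }
  }
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = nrow(data),
         nonlinear = nonlinear, fit = fit, coef_table = coef_table),
    class = "phi_calibration"
  )
}

#' @export
print.phi_calibration <- function(x, ...) {
  cat("Phi_PSII ~ Phi_CO2 calibration\n")
  cat(sprintf("  slope %.4f, intercept %.4f, r^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  if (x$nonlinear) cat("  warning: non-linear relationship detected\n")
  invisible(x)
}

#' Derive photosynthetic quantities from raw gas-exchange records
#'
#' The main gas-exchange verb: takes a table of combined gas-exchange and
#' fluorescence records and appends Phi_PSII, J, Gamma*, g_sc, C_c, g_m, the
#' Harley sensitivity and reliability flag, and an exclusion reason for
#' records where the variable-J inversion is infeasible. Nothing is dropped;
#' downstream group summaries use only rows with `reliable == TRUE` and
#' `exclusion_reason == "none"`.
#'
#' @param data Data frame with columns `leaf_id`, `treatment`, `day`, `A_N`,
#'   `g_sw`, `C_i`, `PPFD`, `T_leaf`, `F_s`, `F_m_prime`, `R_d`.
#' @param constants A [fluor_constants()] object.
#' @param harley_low,harley_high Reliability window bounds (inclusive).
#' @return The input tibble with columns `phi_psii`, `J`, `gamma_star`,
#'   `g_sc`, `C_c`, `g_m`, `dCc_dAN`, `reliable`, `exclusion_reason` appended.
#'   A message reports how many records were excluded.
#' @examples
#' sim <- simulate_study(seed = 1)
#' derived <- derive_gasex(sim$gasex)
#' @export
derive_gasex <- function(data, constants = fluor_constants(),
                         harley_low = 10, harley_high = 50) {
  required <- c("leaf_id", "treatment", "day", "A_N", "g_sw", "C_i", "PPFD",
                "T_leaf", "F_s", "F_m_prime", "R_d")
  check_columns(data, required, "gas-exchange")
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    return(mutate(data, phi_psii = double(), J = double(), gamma_star = double(),
                  g_sc = double(), C_c = double(), g_m = double(),
                  dCc_dAN = double(), reliable = logical(),
                  exclusion_reason = character()))
  }
  out <- data %>%
    mutate(
      phi_psii = phi_psii(.data$F_s, .data$F_m_prime),
      J = electron_transport_rate(.data$phi_psii, .data$PPFD, constants),
      gamma_star = gamma_star_at_temperature(.data$T_leaf),
      g_sc = stomatal_conductance_co2(.data$g_sw)
    )
  vj <- variable_j_gm(out$A_N, out$C_i, out$J, out$R_d, out$gamma_star)
  hr <- harley_reliability(out$A_N, out$J, out$R_d, out$gamma_star,
                           low = harley_low, high = harley_high)
  out <- out %>%
    mutate(C_c = vj$C_c, g_m = vj$g_m, dCc_dAN = hr$dCc_dAN,
           reliable = hr$reliable & vj$flag == "ok",
           exclusion_reason = ifelse(vj$flag == "ok", "none", vj$flag))
  n_excl <- sum(out$exclusion_reason != "none")
  if (n_excl > 0) {
    message(sprintf("derive_gasex: %d of %d records excluded (%s).",
                    n_excl, nrow(out),
                    paste(names(table(out$exclusion_reason[out$exclusion_reason != "none"])),
                          collapse = ", ")))
  }
  out
}
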