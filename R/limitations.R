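#' Same-day well-watered reference state
#'
#' Averages the reliable control records of one day into the reference state
#' used by the limitation partition: mean A_N, g_sc, g_m, ETR (J), C_c,
#' Gamma* and R_d. The well-watered controls define the attainable maximum on
#' each date (control assimilation drifts over a season, so a fixed
#' pre-drought baseline would conflate drift with stress).
#'
#' @param derived A derived gas-exchange tibble from [derive_gasex()]
#'   (controls only, or a mixed table from which `treatment == control` rows
#'   are taken).
#' @param day Measurement day to reference.
#' @param control Treatment label of the well-watered group. Default `"C"`.
#' @return A one-row tibble: `day`, `A_ref`, `g_sc_ref`, `g_m_ref`, `ETR_ref`,
#'   `C_c_ref`, `gamma_star_ref`, `R_d_ref`, `n_ref` (replicates used).
#' @export
daily_reference <- function(derived, day, control = "C") {
  check_columns(derived,
                c("treatment", "day", "A_N", "g_sc", "g_m", "J", "C_c",
                  "gamma_star", "R_d", "reliable", "exclusion_reason"),
                "derived gas-exchange")
  rows <- derived[derived$treatment == control & derived$day == day &
                    derived$reliable & derived$exclusion_reason == "none", ,
                  drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("No reliable control ('%s') records on day %s; no reference available.",
                  control, format(day)),
          class = "photolim_missing_reference")
  }
  tibble(
    day = day,
    A_ref = mean(rows$A_N), g_sc_ref = mean(rows$g_sc),
    g_m_ref = mean(rows$g_m), ETR_ref = mean(rows$J),
    C_c_ref = mean(rows$C_c), gamma_star_ref = mean(rows$gamma_star),
    R_d_ref = mean(rows$R_d), n_ref = nrow(rows)
  )
}

#' Sensitivity of RuBP-regeneration-limited assimilation to chloroplastic CO2
#'
#' Analytic derivative of A = ETR (C_c - Gamma*) / (4 C_c + 8 Gamma*) - R_d
#' with respect to C_c, evaluated at the reference state:
#' \deqn{dA/dC_c = 12\, ETR\, \Gamma^* / (4 C_c + 8 \Gamma^*)^2}
#' ETR stands in for carboxylation capacity: the two are tightly coupled in
#' the field and ETR is measurable on every date, unlike V_cmax.
#'
#' @param ETR_ref Reference electron transport rate, umol e- m^-2 s^-1.
#' @param C_c_ref Reference chloroplastic CO2, umol mol^-1, positive.
#' @param gamma_star_ref Reference Gamma*, umol mol^-1.
#' @return dA/dC_c in (umol m^-2 s^-1)/(umol mol^-1). Vectorised.
#' @export
dA_dCc <- function(ETR_ref, C_c_ref, gamma_star_ref) {
  if (any(C_c_ref <= 0)) abort("`C_c_ref` must be positive.", class = "photolim_invalid_input")
  12 * ETR_ref * gamma_star_ref / (4 * C_c_ref + 8 * gamma_star_ref)^2
}

#' Relative limitation coefficients at a reference state
#'
#' Grassi-Magnani-type weights partitioning the control of assimilation among
#' stomatal conductance, mesophyll conductance and biochemistry. With total
#' diffusive conductance g_tot = (1/g_sc + 1/g_m)^-1 and assimilation
#' sensitivity x = dA/dC_c at the reference:
#' \deqn{l_s = (g_{tot}/g_{sc}) \cdot x/(g_{tot}+x), \quad
#'       l_m = (g_{tot}/g_m) \cdot x/(g_{tot}+x), \quad
#'       l_b = g_{tot}/(g_{tot}+x)}
#' which sum to one exactly.
#'
#' @param ref A one-row reference tibble from [daily_reference()] (or any list
#'   with `g_sc_ref`, `g_m_ref`, `ETR_ref`, `C_c_ref`, `gamma_star_ref`).
#' @return A list with `l_s`, `l_m`, `l_b`, `g_tot`, `x`.
#' @export
relative_limitation_coefficients <- function(ref) {
  g_sc <- ref$g_sc_ref; g_m <- ref$g_m_ref
  if (any(g_sc <= 0) || any(g_m <= 0)) {
    abort("Reference conductances must be positive.", class = "photolim_invalid_input")
  }
  g_tot <- 1 / (1 / g_sc + 1 / g_m)
  x <- dA_dCc(ref$ETR_ref, ref$C_c_ref, ref$gamma_star_ref)
  list(l_s = (g_tot / g_sc) * x / (g_tot + x),
       l_m = (g_tot / g_m) * x / (g_tot + x),
       l_b = g_tot / (g_tot + x),
       g_tot = g_tot, x = x)
}

#' Partition the assimilation deficit of a stressed group
#'
#' First-order decomposition of the relative assimilation shortfall of a
#' stressed group against its same-day reference:
#' S_L = l_s (g_sc_ref - g_sc)/g_sc_ref, MC_L = l_m (g_m_ref - g_m)/g_m_ref,
#' B_L = l_b (ETR_ref - ETR)/ETR_ref, and T_L = S_L + MC_L + B_L. A stressed
#' value above its reference yields a negative component; components are
#' never clipped.
#'
#' @param stressed A one-row tibble / list of stressed group means with
#'   `day`, `treatment`, `g_sc`, `g_m`, `ETR`.
#' @param ref The same-day [daily_reference()] row.
#' @param eps Floor used for T_L when expressing components as fractions of
#'   the total (avoids 0/0 on full recovery). Default 1e-9.
#' @return A one-row tibble: `day`, `treatment`, `S_L`, `MC_L`, `B_L`, `T_L`
#'   (dimensionless fractions of reference assimilation) and
#'   `S_L_pct_of_TL`, `MC_L_pct_of_TL`, `B_L_pct_of_TL`.
#' @export
partition_limitations <- function(stressed, ref, eps = 1e-9) {
  if (!isTRUE(all.equal(as.numeric(stressed$day), as.numeric(ref$day)))) {
    abort(sprintf("Day mismatch: stressed day %s vs reference day %s.",
                  format(stressed$day), format(ref$day)),
          class = "photolim_day_mismatch")
  }
  co <- relative_limitation_coefficients(ref)
  S_L <- co$l_s * (ref$g_sc_ref - stressed$g_sc) / ref$g_sc_ref
  MC_L <- co$l_m * (ref$g_m_ref - stressed$g_m) / ref$g_m_ref
  B_L <- co$l_b * (ref$ETR_ref - stressed$ETR) / ref$ETR_ref
  T_L <- S_L + MC_L + B_L
  T_eff <- pmax(T_L, eps)
  tibble(day = stressed$day, treatment = stressed$treatment,
         S_L = S_L, MC_L = MC_L, B_L = B_L, T_L = T_L,
         S_L_pct_of_TL = 100 * S_L / T_eff,
         MC_L_pct_of_TL = 100 * MC_L / T_eff,
         B_L_pct_of_TL = 100 * B_L / T_eff)
}

#' Limitation analysis across days and treatments
#'
#' Runs the full partition over a derived gas-exchange table: for each
#' measurement day, averages the reliable control records into a reference
#' and partitions each stressed treatment's group means against it. Days
#' without a usable control reference are skipped with a warning (no
#' cross-day interpolation).
#'
#' @param derived Output of [derive_gasex()] containing control and stressed
#'   treatments.
#' @param control Control treatment label. Default `"C"`.
#' @param treatments Stressed treatment labels; defaults to every non-control
#'   treatment present.
#' @param per_leaf If `TRUE`, partition each leaf separately and average the
#'   partitions; the default (`FALSE`) partitions the group means.
#' @return A tibble of [partition_limitations()] rows, one per day x stressed
#'   treatment.
#' @examples
#' sim <- simulate_study(seed = 1)
#' lims <- limitation_analysis(derive_gasex(sim$gasex))
#' @export
limitation_analysis <- function(derived, control = "C", treatments = NULL,
                                per_leaf = FALSE) {
  check_columns(derived, c("treatment", "day", "g_sc", "g_m", "J",
                           "reliable", "exclusion_reason"),
                "derived gas-exchange")
  if (is.null(treatments)) {
    treatments <- setdiff(unique(derived$treatment), control)
  }
  usable <- derived[derived$reliable & derived$exclusion_reason == "none", ,
                    drop = FALSE]
  days <- sort(unique(usable$day[usable$treatment %in% treatments]))
  out <- list()
  for (d in days) {
    ref <- tryCatch(daily_reference(derived, d, control = control),
                    photolim_missing_reference = function(e) NULL)
    if (is.null(ref)) {
      warn(sprintf("No control reference on day %s; skipped.", format(d)))
      next
    }
    for (tr in treatments) {
      grp <- usable[usable$treatment == tr & usable$day == d, , drop = FALSE]
      if (nrow(grp) == 0) next
      if (per_leaf) {
        parts <- lapply(seq_len(nrow(grp)), function(i) {
          partition_limitations(
            list(day = d, treatment = tr, g_sc = grp$g_sc[i],
                 g_m = grp$g_m[i], ETR = grp$J[i]), ref)
        })
        part <- bind_rows(parts) %>%
          group_by(.data$day, .data$treatment) %>%
          summarise(across(c("S_L", "MC_L", "B_L", "T_L",
                             "S_L_pct_of_TL", "MC_L_pct_of_TL",
                             "B_L_pct_of_TL"), mean),
                    .groups = "drop")
      } else {
        part <- partition_limitations(
          list(day = d, treatment = tr, g_sc = mean(grp$g_sc),
               g_m = mean(grp$g_m), ETR = mean(grp$J)), ref)
      }
      out[[length(out) + 1]] <- part
    }
  }
  bind_rows(out)
}
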