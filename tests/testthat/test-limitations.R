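make_derived_control <- function(day, g_m = c(0.25, 0.27), J = c(118, 122),
                                 reliable = c(TRUE, TRUE)) {
  recs <- dplyr::bind_rows(lapply(seq_along(g_m), function(i) {
    oracle_gasex_record(g_sc = 0.125, g_m = g_m[i], J = J[i], R_d = 1.2,
                        leaf_id = paste0("C_", i), day = day)
  }))
  der <- derive_gasex(recs)
  der$reliable <- reliable
  der
}

test_that("daily reference averages reliable same-day controls", {
  one <- make_derived_control(4, g_m = 0.25, J = 120, reliable = TRUE)
  ref1 <- daily_reference(one, 4)
  expect_equal(ref1$g_m_ref, one$g_m)
  expect_equal(ref1$ETR_ref, 120, tolerance = 1e-12)
  expect_equal(ref1$n_ref, 1)

  two <- make_derived_control(4)
  ref2 <- daily_reference(two, 4)
  expect_equal(ref2$A_ref, mean(two$A_N))
  expect_equal(ref2$g_m_ref, mean(two$g_m))

  mixed <- make_derived_control(4, g_m = c(0.25, 0.27, 0.4),
                                J = c(118, 122, 120),
                                reliable = c(TRUE, TRUE, FALSE))
  ref3 <- daily_reference(mixed, 4)
  expect_equal(ref3$n_ref, 2)
  expect_equal(ref3$g_m_ref, mean(mixed$g_m[1:2]))

  expect_error(daily_reference(two, 99), class = "photolim_missing_reference")
})

test_that("assimilation sensitivity matches its closed form and scaling", {
  expect_equal(dA_dCc(120, 177.143, 40),
               12 * 120 * 40 / (4 * 177.143 + 8 * 40)^2)
  # matches a central finite difference of RuBP-limited A(C_c)
  a_of <- function(C_c, J, gs) J * (C_c - gs) / (4 * C_c + 8 * gs)
  for (cc in c(120, 180, 250)) {
    fd <- (a_of(cc + 1e-4, 120, 40) - a_of(cc - 1e-4, 120, 40)) / 2e-4
    expect_equal(dA_dCc(120, cc, 40), fd, tolerance = 1e-6)
  }
  expect_equal(dA_dCc(240, 177, 40), 2 * dA_dCc(120, 177, 40))
  expect_error(dA_dCc(120, -5, 40), class = "photolim_invalid_input")
})

test_that("limitation coefficients normalize, respect symmetry, and match direct evaluation", {
  set.seed(21)
  for (i in 1:200) {
    ref <- list(g_sc_ref = runif(1, 0.02, 0.3), g_m_ref = runif(1, 0.02, 0.5),
                ETR_ref = runif(1, 50, 200), C_c_ref = runif(1, 80, 300),
                gamma_star_ref = runif(1, 35, 60))
    co <- relative_limitation_coefficients(ref)
    expect_equal(co$l_s + co$l_m + co$l_b, 1, tolerance = 1e-12)
    expect_true(all(c(co$l_s, co$l_m, co$l_b) > 0))
  }

  sym <- relative_limitation_coefficients(
    list(g_sc_ref = 0.1, g_m_ref = 0.1, ETR_ref = 120, C_c_ref = 180,
         gamma_star_ref = 45))
  expect_equal(sym$l_s, sym$l_m)

  # direct evaluation of the coefficient formulas
  ref <- list(g_sc_ref = 0.125, g_m_ref = 0.2625, ETR_ref = 120,
              C_c_ref = 177, gamma_star_ref = 40)
  co <- relative_limitation_coefficients(ref)
  g_tot <- 1 / (1 / 0.125 + 1 / 0.2625)
  x <- 12 * 120 * 40 / (4 * 177 + 8 * 40)^2
  expect_equal(co$l_s, (g_tot / 0.125) * x / (g_tot + x))
  expect_equal(co$l_m, (g_tot / 0.2625) * x / (g_tot + x))
  expect_equal(co$l_b, g_tot / (g_tot + x))

  expect_error(
    relative_limitation_coefficients(
      list(g_sc_ref = 0, g_m_ref = 0.2, ETR_ref = 120, C_c_ref = 180,
           gamma_star_ref = 40)),
    class = "photolim_invalid_input")
})

test_that("partition vanishes at the reference and isolates single-factor changes", {
  ref <- tibble::tibble(day = 7, g_sc_ref = 0.125, g_m_ref = 0.2625,
                        ETR_ref = 120, C_c_ref = 200, gamma_star_ref = 55,
                        A_ref = 14, R_d_ref = 1.2, n_ref = 6)
  same <- list(day = 7, treatment = "S", g_sc = 0.125, g_m = 0.2625, ETR = 120)
  p0 <- partition_limitations(same, ref)
  expect_equal(p0$S_L, 0); expect_equal(p0$MC_L, 0)
  expect_equal(p0$B_L, 0); expect_equal(p0$T_L, 0)

  co <- relative_limitation_coefficients(ref)
  halved <- list(day = 7, treatment = "S", g_sc = 0.125, g_m = 0.2625 / 2,
                 ETR = 120)
  ph <- partition_limitations(halved, ref)
  expect_equal(ph$MC_L, co$l_m / 2)
  expect_equal(ph$S_L, 0); expect_equal(ph$B_L, 0)
  expect_equal(ph$T_L, ph$S_L + ph$MC_L + ph$B_L)

  # exceeding the reference yields a negative component, never clipped
  better <- list(day = 7, treatment = "S", g_sc = 0.15, g_m = 0.2625, ETR = 120)
  expect_lt(partition_limitations(better, ref)$S_L, 0)

  wrong_day <- list(day = 9, treatment = "S", g_sc = 0.1, g_m = 0.2, ETR = 100)
  expect_error(partition_limitations(wrong_day, ref),
               class = "photolim_day_mismatch")
})

test_that("total limitation approximates the forward-model assimilation decline", {
  g_sc0 <- 0.125; g_m0 <- 0.2625; J0 <- 120; R_d <- 1.2
  gs <- oracle_gamma_star(30)
  base <- oracle_steady_state_rubp(g_sc0, g_m0, J0, R_d, gs, 400)
  ref <- tibble::tibble(day = 1, g_sc_ref = g_sc0, g_m_ref = g_m0,
                        ETR_ref = J0, C_c_ref = base$C_c,
                        gamma_star_ref = gs, A_ref = base$A_N,
                        R_d_ref = R_d, n_ref = 1)
  cases <- list(c(0.95, 1, 1), c(1, 0.95, 1), c(1, 1, 0.95),
                c(0.95, 0.95, 0.95), c(0.92, 0.96, 0.98))
  errs <- vapply(cases, function(f) {
    pert <- oracle_steady_state_rubp(g_sc0 * f[1], g_m0 * f[2], J0 * f[3],
                                     R_d, gs, 400)
    true_decline <- (base$A_N - pert$A_N) / base$A_N
    part <- partition_limitations(
      list(day = 1, treatment = "S", g_sc = g_sc0 * f[1],
           g_m = g_m0 * f[2], ETR = J0 * f[3]), ref)
    abs(part$T_L - true_decline) / true_decline
  }, 0)
  expect_true(all(errs < 0.10))

  # first-order error grows with perturbation size
  sizes <- c(0.02, 0.05, 0.10, 0.20)
  err_by_size <- vapply(sizes, function(s) {
    f <- 1 - s
    pert <- oracle_steady_state_rubp(g_sc0 * f, g_m0 * f, J0 * f, R_d, gs, 400)
    true_decline <- (base$A_N - pert$A_N) / base$A_N
    part <- partition_limitations(
      list(day = 1, treatment = "S", g_sc = g_sc0 * f, g_m = g_m0 * f,
           ETR = J0 * f), ref)
    abs(part$T_L - true_decline)
  }, 0)
  expect_true(all(diff(err_by_size) > 0))
})

test_that("components respond monotonically to their own driver", {
  ref <- tibble::tibble(day = 1, g_sc_ref = 0.125, g_m_ref = 0.2625,
                        ETR_ref = 120, C_c_ref = 200, gamma_star_ref = 55,
                        A_ref = 14, R_d_ref = 1.2, n_ref = 6)
  gscs <- seq(0.05, 0.125, length.out = 5)
  S_L <- vapply(gscs, function(g) {
    partition_limitations(list(day = 1, treatment = "S", g_sc = g,
                               g_m = 0.2625, ETR = 120), ref)$S_L
  }, 0)
  expect_true(all(diff(S_L) < 0)) # S_L non-increasing in stressed g_sc

  gms <- seq(0.1, 0.2625, length.out = 5)
  MC_L <- vapply(gms, function(g) {
    partition_limitations(list(day = 1, treatment = "S", g_sc = 0.125,
                               g_m = g, ETR = 120), ref)$MC_L
  }, 0)
  expect_true(all(diff(MC_L) < 0))

  etrs <- seq(70, 120, length.out = 5)
  B_L <- vapply(etrs, function(e) {
    partition_limitations(list(day = 1, treatment = "S", g_sc = 0.125,
                               g_m = 0.2625, ETR = e), ref)$B_L
  }, 0)
  expect_true(all(diff(B_L) < 0))
})

test_that("limitation_analysis runs the partition across days and treatments", {
  sim <- simulate_study(seed = 3)
  derived <- suppressMessages(derive_gasex(sim$gasex))
  lims <- limitation_analysis(derived)
  expect_true(all(c("S", "SP") %in% lims$treatment))
  expect_equal(lims$T_L, lims$S_L + lims$MC_L + lims$B_L, tolerance = 1e-12)
  # pre-drought days show near-zero totals; peak drought shows strong ones
  s <- lims[lims$treatment == "S", ]
  expect_lt(abs(s$T_L[s$day == -2]), 0.1)
  expect_gt(s$T_L[s$day == 13], 0.3)
  # per-leaf averaging variant returns the same shape
  pl <- limitation_analysis(derived, per_leaf = TRUE)
  expect_equal(nrow(pl), nrow(lims))
})
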