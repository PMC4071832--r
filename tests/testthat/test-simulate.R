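test_that("forward steady state matches an independent root-finder", {
  gs25 <- oracle_gamma_star(25)
  p <- leaf_params(g_sc_true = 0.2, g_m_true = 0.2, J_true = 150,
                   V_cmax = 1e6, R_d = 1, T_leaf = 25)
  ss <- simulate_leaf_steady_state(p)
  oracle <- oracle_steady_state_rubp(0.2, 0.2, 150, 1, gs25, 400)
  expect_equal(ss$A_N, oracle$A_N, tolerance = 1e-8)
  expect_equal(ss$C_c, oracle$C_c, tolerance = 1e-8)
  expect_equal(ss$limiting_branch, "RuBP")
  # diffusion gap identity C_i - C_c = A (1/g_m) and C_a - C_i = A/g_sc
  expect_equal(ss$C_i - ss$C_c, ss$A_N / 0.2, tolerance = 1e-6)
  expect_equal(400 - ss$C_i, ss$A_N / 0.2, tolerance = 1e-6)
})

test_that("with no diffusion limitation C_c approaches ambient", {
  p <- leaf_params(g_sc_true = 500, g_m_true = 500, J_true = 150,
                   V_cmax = 1e6, R_d = 1, T_leaf = 25)
  ss <- simulate_leaf_steady_state(p)
  gs <- oracle_gamma_star(25)
  a_j_at_ca <- 150 * (400 - gs) / (4 * 400 + 8 * gs) - 1
  expect_equal(ss$C_c, 400, tolerance = 0.01)
  expect_equal(ss$A_N, a_j_at_ca, tolerance = 1e-3)
})

test_that("Rubisco-limited leaves are labelled and bias the variable-J inversion", {
  # low V_cmax forces the Rubisco branch
  p <- leaf_params(g_sc_true = 0.125, g_m_true = 0.25, J_true = 120,
                   V_cmax = 40, R_d = 1.2, T_leaf = 30)
  ss <- simulate_leaf_steady_state(p)
  expect_equal(ss$limiting_branch, "Rubisco")
  gs <- oracle_gamma_star(30)
  inv <- variable_j_gm(ss$A_N, ss$C_i, 120, 1.2, gs)
  # the RuBP-form inversion cannot recover the true g_m here: assimilation
  # sits below the RuBP curve, so the fluorescence-based C_c estimate is
  # pulled down toward Gamma* and g_m is biased low
  expect_equal(inv$flag, "ok")
  expect_lt(inv$C_c, ss$C_c)
  expect_lt(inv$g_m, 0.25 * 0.95)

  expect_error(
    simulate_leaf_steady_state(
      leaf_params(g_sc_true = 0.001, g_m_true = 0.001, J_true = 20,
                  V_cmax = 1e6, R_d = 15, T_leaf = 25)),
    class = "photolim_infeasible_parameters")
})

test_that("fluorescence back-calculation is the exact inverse of J", {
  fl <- fluorescence_from_J(209.25, 1800)
  expect_equal(fl$F_s, 1500)
  expect_equal(fluorescence_from_J(0, 1800)$F_s, 2000)
  set.seed(101)
  for (J in runif(10, 10, 800)) {
    fl <- fluorescence_from_J(J, 1800)
    phi <- phi_psii(fl$F_s, fl$F_m_prime)
    expect_equal(electron_transport_rate(phi, 1800), J, tolerance = 1e-9)
  }
  expect_error(fluorescence_from_J(900, 1800),
               class = "photolim_invalid_input") # implied Phi > 1
})

test_that("noise-free control time series are constant and runs are reproducible", {
  cfg <- sim_config(n_per_treatment = 2, leaf_sd = 0, cv_an = 0, cv_j = 0,
                    cv_gsw = 0, ct_sigma = 0)
  tc <- simulate_drought_timecourse(cfg, seed = 5)
  ctrl <- tc$gasex[tc$gasex$treatment == "C" & tc$gasex$leaf_id == "C_1", ]
  expect_equal(length(unique(round(ctrl$A_N, 10))), 1)
  expect_equal(length(unique(round(ctrl$g_sw, 10))), 1)

  a <- simulate_drought_timecourse(sim_config(n_per_treatment = 2), seed = 7)
  b <- simulate_drought_timecourse(sim_config(n_per_treatment = 2), seed = 7)
  expect_identical(a$gasex, b$gasex)
  expect_identical(a$truth, b$truth)

  s1 <- simulate_study(seed = 9)
  s2 <- simulate_study(seed = 9)
  expect_identical(s1$qpcr_plate, s2$qpcr_plate)
  expect_identical(s1$expression, s2$expression)
})

test_that("emitted records satisfy the gas-exchange preconditions", {
  sim <- simulate_study(seed = 13)
  g <- sim$gasex
  expect_true(all(g$g_sw >= 0))
  expect_true(all(g$PPFD >= 0))
  expect_true(all(g$F_m_prime >= g$F_s & g$F_s > 0))
  expect_true(all(g$C_i >= 0))
  # ground truth aligns one-to-one with records
  expect_equal(nrow(sim$truth), nrow(g))
  expect_identical(sim$truth$leaf_id, g$leaf_id)
  # water table covers every treatment x day
  expect_equal(nrow(sim$water), 3 * length(sim$config$days))
  expect_true(all(add_rwc(sim$water)$RWC <= 100))
})

test_that("the drought backbone reproduces the qualitative field ordering", {
  sim <- simulate_study(seed = 17)
  bb <- sim$backbone
  s <- bb[bb$treatment == "S", ]
  sp <- bb[bb$treatment == "SP", ]
  # REW below 0.3 within two days of withholding
  expect_lt(s$REW[s$day == 2], 0.31)
  # gas exchange responds before it fully recovers: stomatal factor at
  # 3 d after rewatering still well below control
  expect_lt(s$f_gs[s$day == 16], 0.7)
  # SP declines and recovers faster than S
  expect_lte(sp$REW[sp$day == 7], s$REW[s$day == 7])
  expect_gt(sp$f_gs[sp$day == 18], s$f_gs[s$day == 18])
  # electron transport declines less than stomatal conductance
  expect_gt(min(s$f_j), min(s$f_gs))
  # g_m collapse lags stomatal closure early in drought
  expect_gt(s$f_gm[s$day == 4], s$f_gs[s$day == 4])
})

test_that("SEM simulation honours the coefficients and standardization", {
  m <- model3_acyclic()
  # all-zero coefficients: variables mutually independent
  zero <- setNames(rep(0, 7), names(default_sem_coefficients()))
  d0 <- simulate_expression_sem(m, n = 4000, coefficients = zero, seed = 21)
  cm <- cor(d0)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.08)

  # chain with coefficient 0.8: marginal corr(X, Z) = 0.64
  chain <- causal_model("chain", c("X", "Y", "Z"),
                        list(c("X", "Y"), c("Y", "Z")))
  dc <- simulate_expression_sem(
    chain, n = 1e4, coefficients = c("X->Y" = 0.8, "Y->Z" = 0.8), seed = 22)
  expect_equal(cor(dc$X, dc$Z), 0.64, tolerance = 0.03)
  expect_equal(unname(apply(dc, 2, sd)), rep(1, 3), tolerance = 0.05)

  expect_error(simulate_expression_sem(chain, n = 10,
                                       coefficients = c("X->Y" = 0.8)),
               class = "photolim_invalid_input")
  expect_error(
    simulate_expression_sem(chain, n = 10,
                            coefficients = c("X->Y" = 0.8, "Y->Z" = 0.8,
                                             "X->Z" = 0.1)),
    class = "photolim_invalid_input")
  expect_error(
    simulate_expression_sem(chain, n = 10,
                            coefficients = c("X->Y" = 1.1, "Y->Z" = 0.5)),
    class = "photolim_invalid_input")

  # injected exogenous driver is standardized and drives descendants
  drv <- data.frame(X = 5 + 3 * rnorm(2000))
  di <- simulate_expression_sem(chain, n = 2000,
                                coefficients = c("X->Y" = 0.8, "Y->Z" = 0.8),
                                data = drv, seed = 23)
  expect_equal(mean(di$X), 0, tolerance = 1e-9)
  expect_equal(sd(di$X), 1, tolerance = 1e-9)
  expect_gt(cor(di$X, scale(drv$X)[, 1]), 0.999)
})

test_that("qPCR plate generator round-trips exactly without noise", {
  truth <- tibble::tibble(
    sample_id = rep(c("cal", "s1", "s2"), each = 3),
    gene = rep(c("OePIP1.1", "OePIP2.1", "CA"), 3),
    relative = c(1, 1, 1, 10, 0.5, 2, 0.1, 3, 1.7))
  plate <- simulate_qpcr_plate(truth, calibrator_sample = "cal", ct_sigma = 0)
  out <- relative_expression(plate, calibrator_sample = "cal")
  merged <- dplyr::left_join(out, truth, by = c("sample_id", "gene"))
  expect_equal(merged$relative.x, merged$relative.y, tolerance = 1e-9)

  p1 <- simulate_qpcr_plate(truth, calibrator_sample = "cal",
                            ct_sigma = 0.2, seed = 31)
  p2 <- simulate_qpcr_plate(truth, calibrator_sample = "cal",
                            ct_sigma = 0.2, seed = 31)
  expect_identical(p1, p2)
  expect_error(simulate_qpcr_plate(truth, calibrator_sample = "absent"),
               class = "photolim_missing_calibrator")
})
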