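#' Configuration of the synthetic drought-recovery study
#'
#' Collects the generator's parameters: design (treatments C = well-watered
#' control, S = droughted, SP = droughted + pruned; six trees each; a
#' measurement schedule spanning water withholding at day 0 and rewatering at
#' day 13), soil-water dynamics, stomatal and electron-transport responses,
#' the mesophyll:stomatal conductance coupling, noise levels and qPCR plate
#' parameters. Defaults emulate the study conditions: saturating light
#' (1800 umol m^-2 s^-1), 400 umol mol^-1 ambient CO2, field capacity 0.25
#' and wilting point 0.04 m^3 m^-3, and a g_m:g_sc ratio of 2.1.
#'
#' @param n_per_treatment Trees per treatment. Default 6.
#' @param days Measurement days relative to water withholding (day 0 = last
#'   irrigation); must include the rewatering day.
#' @param rewater_day Day irrigation resumes. Default 13.
#' @param g_sw_max Well-watered stomatal conductance to H2O, mol m^-2 s^-1.
#' @param j_max Well-watered electron transport rate, umol e- m^-2 s^-1.
#' @param vcmax_ratio V_cmax as a multiple of the leaf's J (1.3 keeps leaves
#'   RuBP-regeneration-limited except under extreme drought).
#' @param r_d Dark respiration, umol m^-2 s^-1.
#' @param t_leaf Leaf temperature, degC.
#' @param c_a Ambient CO2, umol mol^-1.
#' @param ppfd Incident light, umol m^-2 s^-1.
#' @param theta_min,theta_max Wilting-point and field-capacity soil water
#'   contents, m^3 m^-3.
#' @param rew_floor Minimum relative extractable water reached under full
#'   drought.
#' @param rew_k Named exponential depletion rates (d^-1) for S and SP
#'   (pruned trees deplete slightly faster here only through their smaller
#'   buffering; see the methods vignette).
#' @param rew_crit,gs_shape REW threshold and exponent of the saturating
#'   stomatal response f = min(1, (REW/rew_crit)^gs_shape).
#' @param gm_rew_crit,gm_shape REW threshold and exponent of the mesophyll
#'   conductance target h = min(1, (REW/gm_rew_crit)^gm_shape). The lower
#'   threshold and steeper exponent make g_m nearly insensitive to mild
#'   deficit but collapse under severe deficit.
#' @param tau_gm First-order time constant (d) with which g_m approaches its
#'   drought target: mesophyll conductance tracks leaf (not soil) water
#'   status, so its collapse lags stomatal closure by days and the mesophyll
#'   share of the total limitation grows as drought deepens.
#' @param tau_recovery Named first-order recovery time constants (d) of the
#'   stomatal factor for S and SP after rewatering; mesophyll conductance
#'   recovers twice as fast.
#' @param tau_j Time constant (d) of the lagged first-order electron
#'   transport response.
#' @param j_floor Fraction of well-watered J retained under complete
#'   stomatal closure.
#' @param gm_ratio Well-watered g_m:g_sc ratio (CO2 basis). Default 2.1.
#' @param control_drift Fractional day^-1 drift applied to every treatment's
#'   well-watered targets (0 = stationary controls).
#' @param leaf_sd Lognormal standard deviation of fixed leaf-to-leaf
#'   variation in conductance and electron transport.
#' @param cv_an,cv_j,cv_gsw Multiplicative Gaussian measurement noise CVs on
#'   assimilation, electron transport and stomatal conductance.
#' @param ct_sigma Gaussian Ct noise (cycles) on qPCR wells.
#' @param n_tech qPCR technical replicates per sample x gene.
#' @param n_expr_reps Expression sampling replicates per treatment x day.
#' @param sem_coefficients Standardized path coefficients of the expression
#'   model, a named numeric vector `"from->to"`.
#' @param stress_loading Standardized loading of drought stress on the
#'   exogenous aquaporin transcript (negative: expression-linked variables
#'   decline under stress).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_treatment = 6,
                       days = c(-2, 0, 2, 4, 7, 9, 11, 13,
                                14, 15, 16, 18, 20, 26, 34, 47),
                       rewater_day = 13,
                       g_sw_max = 0.20, j_max = 120, vcmax_ratio = 2,
                       r_d = 1.2, t_leaf = 30, c_a = 400, ppfd = 1800,
                       theta_min = 0.04, theta_max = 0.25,
                       rew_floor = 0.08, rew_k = c(S = 0.6, SP = 0.7),
                       rew_crit = 0.6, gs_shape = 0.9,
                       gm_rew_crit = 0.28, gm_shape = 2, tau_gm = 4,
                       tau_recovery = c(S = 6, SP = 3.5), tau_j = 2,
                       j_floor = 0.65,
                       gm_ratio = 2.1,
                       control_drift = 0,
                       leaf_sd = 0.08, cv_an = 0.02, cv_j = 0.02,
                       cv_gsw = 0.02,
                       ct_sigma = 0.15, n_tech = 3, n_expr_reps = 3,
                       sem_coefficients = default_sem_coefficients(),
                       stress_loading = -0.6) {
  if (!rewater_day %in% days && !any(days > rewater_day)) {
    abort("`days` must cover the rewatering day.", class = "photolim_invalid_input")
  }
  if (!all(c("S", "SP") %in% names(rew_k)) ||
      !all(c("S", "SP") %in% names(tau_recovery))) {
    abort("`rew_k` and `tau_recovery` need named entries for S and SP.",
          class = "photolim_invalid_input")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Default standardized path coefficients of the expression model
#'
#' Coefficients for the edges of [model3_acyclic()], named `"from->to"`.
#' @return Named numeric vector.
#' @export
default_sem_coefficients <- function() {
  c("PIP1->PIP2" = 0.5, "PIP1->gs" = 0.3, "PIP2->gs" = 0.4,
    "PIP2->gm" = 0.6, "gs->AN" = 0.45, "gm->AN" = 0.45, "AN->CA" = 0.6)
}

# Deterministic per-treatment backbone factors on a daily grid.
# Returns a tibble: treatment, day (grid), REW, f_gs (stomatal stress
# factor incl. recovery), f_gm (mesophyll factor), f_j (lagged
# electron-transport factor).
drought_backbone <- function(config) {
  grid <- seq(min(config$days), max(config$days), by = 1)

  # immediate drought response with first-order recovery after rewatering
  response_path <- function(REW, crit, shape, tau) {
    f <- pmin(1, (REW / crit)^shape)
    post <- grid > config$rewater_day
    if (any(post)) {
      f_end <- f[grid == config$rewater_day][1]
      f[post] <- 1 - (1 - f_end) * exp(-(grid[post] - config$rewater_day) / tau)
    }
    f
  }

  out <- list()
  for (tr in c("C", "S", "SP")) {
    if (tr == "C") {
      REW <- rep(1, length(grid))
      f_gs <- rep(1, length(grid))
      f_gm <- rep(1, length(grid))
    } else {
      k <- config$rew_k[[tr]]
      REW <- ifelse(grid <= 0, 1,
                    ifelse(grid <= config$rewater_day,
                           pmax(config$rew_floor, exp(-k * grid)), 1))
      tau <- config$tau_recovery[[tr]]
      f_gs <- response_path(REW, config$rew_crit, config$gs_shape, tau)
      # g_m lags drought severity (leaf water status) and recovers fast
      gm_target <- pmin(1, (REW / config$gm_rew_crit)^config$gm_shape)
      f_gm <- numeric(length(grid))
      f_gm[1] <- gm_target[1]
      step_d <- 1 - exp(-1 / config$tau_gm)
      step_r <- 1 - exp(-1 / (tau / 2))
      for (i in seq_along(grid)[-1]) {
        f_gm[i] <- if (grid[i] <= config$rewater_day) {
          f_gm[i - 1] + (gm_target[i] - f_gm[i - 1]) * step_d
        } else {
          f_gm[i - 1] + (1 - f_gm[i - 1]) * step_r
        }
      }
    }
    # electron transport tracks the stomatal factor with a first-order lag
    target <- config$j_floor + (1 - config$j_floor) * f_gs
    f_j <- numeric(length(grid))
    f_j[1] <- target[1]
    step <- 1 - exp(-1 / config$tau_j)
    for (i in seq_along(grid)[-1]) {
      f_j[i] <- f_j[i - 1] + (target[i] - f_j[i - 1]) * step
    }
    drift <- 1 + config$control_drift * (grid - min(grid))
    out[[tr]] <- tibble(treatment = tr, day = grid, REW = REW,
                        f_gs = f_gs * drift, f_gm = f_gm * drift,
                        f_j = f_j * drift)
  }
  bind_rows(out)
}

#' Simulate a drought-recovery gas-exchange time course
#'
#' Generates the leaf-level gas-exchange/fluorescence table, the soil and
#' leaf water-status table, and the aligned ground-truth table for a
#' three-treatment drought-then-rewatering experiment. Soil water depletes
#' exponentially during withholding and is replenished instantly at
#' rewatering; stomata follow a saturating function of relative extractable
#' water with first-order recovery; electron transport follows with a lag;
#' mesophyll conductance is coupled to stomatal conductance (ratio
#' `gm_ratio`) with an extra stress exponent. Each leaf's steady-state
#' assimilation comes from the forward FvCB model, then multiplicative
#' measurement noise is applied to A_N, J and g_sw.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for reproducibility.
#' @return A list with tibbles `gasex`, `water`, `truth` and the `backbone`
#'   factor table.
#' @export
simulate_drought_timecourse <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  bb <- drought_backbone(config)
  consts <- fluor_constants()
  j_cap <- 0.98 * config$ppfd * consts$psii_fraction * consts$absorptance

  gasex <- list(); truth <- list()
  for (tr in c("C", "S", "SP")) {
    bb_tr <- bb[bb$treatment == tr, , drop = FALSE]
    for (leaf in seq_len(config$n_per_treatment)) {
      leaf_id <- sprintf("%s_%d", tr, leaf)
      mult_g <- exp(rnorm(1, 0, config$leaf_sd))
      mult_j <- exp(rnorm(1, 0, config$leaf_sd))
      for (d in config$days) {
        row <- bb_tr[bb_tr$day == d, , drop = FALSE]
        g_sw_true <- config$g_sw_max * row$f_gs * mult_g
        g_sc_true <- g_sw_true / 1.6
        g_m_true <- config$gm_ratio * (config$g_sw_max / 1.6) *
          row$f_gm * mult_g
        J_true <- min(config$j_max * row$f_j * mult_j, j_cap)
        p <- leaf_params(g_sc_true = g_sc_true, g_m_true = g_m_true,
                         J_true = J_true, V_cmax = config$vcmax_ratio * J_true,
                         R_d = config$r_d, T_leaf = config$t_leaf,
                         C_a = config$c_a, PPFD = config$ppfd)
        ss <- simulate_leaf_steady_state(p)
        A_meas <- ss$A_N * (1 + config$cv_an * rnorm(1))
        g_sw_meas <- g_sw_true * (1 + config$cv_gsw * rnorm(1))
        C_i_meas <- config$c_a - A_meas / (g_sw_meas / 1.6)
        J_meas <- min(J_true * (1 + config$cv_j * rnorm(1)), j_cap)
        fl <- fluorescence_from_J(J_meas, config$ppfd, consts)
        gasex[[length(gasex) + 1]] <- tibble(
          leaf_id = leaf_id, treatment = tr, day = d,
          A_N = A_meas, g_sw = g_sw_meas, C_i = C_i_meas,
          PPFD = config$ppfd, T_leaf = config$t_leaf,
          F_s = fl$F_s, F_m_prime = fl$F_m_prime, R_d = config$r_d)
        truth[[length(truth) + 1]] <- tibble(
          leaf_id = leaf_id, treatment = tr, day = d,
          g_sc_true = g_sc_true, g_m_true = g_m_true, J_true = J_true,
          V_cmax = config$vcmax_ratio * J_true,
          A_N_true = ss$A_N, C_i_true = ss$C_i, C_c_true = ss$C_c,
          limiting_branch = ss$limiting_branch)
      }
    }
  }

  water <- bb %>%
    filter(.data$day %in% config$days) %>%
    mutate(theta = config$theta_min +
             .data$REW * (config$theta_max - config$theta_min),
           theta_min = config$theta_min, theta_max = config$theta_max,
           RWC_target = 98 - 55 * pmax(0, (0.45 - .data$REW) / 0.45)^1.6,
           dry_w = 0.4, turgid_w = 1.0,
           fresh_w = .data$dry_w +
             .data$RWC_target / 100 * (.data$turgid_w - .data$dry_w),
           psi = -0.5 - 6.5 * pmax(0, 1 - .data$REW)^3) %>%
    select("treatment", "day", "theta", "theta_min", "theta_max",
           "fresh_w", "dry_w", "turgid_w", "psi")

  list(gasex = bind_rows(gasex), water = water, truth = bind_rows(truth),
       backbone = bb)
}

#' Simulate data from a linear-Gaussian structural equation model
#'
#' Draws `n` observations from the causal model in topological order. With
#' `standardized = TRUE` (default) the given path coefficients are treated
#' as standardized: each vertex's residual variance is set so its marginal
#' variance is 1 given the implied covariance of its parents (an error is
#' raised if the coefficients demand more than unit explained variance).
#' Exogenous (parentless) vertices may be injected from `data`, in which
#' case they are standardized and treated as mutually independent drivers.
#'
#' @param model A validated [causal_model()].
#' @param n Number of observations.
#' @param coefficients Named numeric vector `"from->to"` of path
#'   coefficients covering every edge; defaults to
#'   [default_sem_coefficients()] for the fixture model and 0.5 per edge
#'   otherwise.
#' @param data Optional data frame supplying columns for exogenous vertices.
#' @param standardized Treat coefficients as standardized. Default `TRUE`.
#' @param seed Integer seed.
#' @return A tibble with one column per vertex and attribute
#'   `"coefficients"` carrying the truth.
#' @examples
#' d <- simulate_expression_sem(model3_acyclic(), n = 500, seed = 1)
#' @export
simulate_expression_sem <- function(model, n, coefficients = NULL,
                                    data = NULL, standardized = TRUE,
                                    seed = NULL) {
  model <- validate_dag(model)
  if (!is.null(seed)) set.seed(seed)
  edge_keys <- paste0(model$edges$from, "->", model$edges$to)
  if (is.null(coefficients)) {
    coefficients <- if (identical(model$name, "model3_acyclic")) {
      default_sem_coefficients()
    } else {
      setNames(rep(0.5, length(edge_keys)), edge_keys)
    }
  }
  missing_coef <- setdiff(edge_keys, names(coefficients))
  if (length(missing_coef) > 0) {
    abort(sprintf("Missing path coefficient%s for: %s.",
                  if (length(missing_coef) > 1) "s" else "",
                  paste(missing_coef, collapse = ", ")),
          class = "photolim_invalid_input")
  }
  extra_coef <- setdiff(names(coefficients), edge_keys)
  if (length(extra_coef) > 0) {
    abort(sprintf("Coefficient%s for non-edges: %s.",
                  if (length(extra_coef) > 1) "s" else "",
                  paste(extra_coef, collapse = ", ")),
          class = "photolim_invalid_input")
  }

  ord <- topological_order(model)
  X <- matrix(NA_real_, nrow = n, ncol = length(ord),
              dimnames = list(NULL, ord))
  # implied covariance bookkeeping for standardization
  Sigma <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  for (v in ord) {
    pa <- parents_of(model, v)
    if (length(pa) == 0) {
      if (!is.null(data) && v %in% names(data)) {
        col <- data[[v]]
        if (length(col) != n) {
          abort(sprintf("Injected column '%s' must have length n = %d.", v, n),
                class = "photolim_invalid_input")
        }
        X[, v] <- as.numeric(scale(col))
      } else {
        X[, v] <- rnorm(n)
      }
      Sigma[v, v] <- 1
    } else {
      b <- coefficients[paste0(pa, "->", v)]
      mean_part <- X[, pa, drop = FALSE] %*% b
      if (standardized) {
        expl <- as.numeric(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b)
        if (expl >= 1) {
          abort(sprintf("Standardized coefficients into '%s' imply explained variance %.3f >= 1.",
                        v, expl),
                class = "photolim_invalid_input")
        }
        resid_sd <- sqrt(1 - expl)
        Sigma[v, v] <- 1
      } else {
        resid_sd <- 1
        Sigma[v, v] <- as.numeric(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b) + 1
      }
      X[, v] <- mean_part + rnorm(n, 0, resid_sd)
      cov_vw <- Sigma[pa, , drop = FALSE]
      Sigma[v, ] <- Sigma[, v] <- as.numeric(t(b) %*% cov_vw)
      Sigma[v, v] <- if (standardized) 1 else
        as.numeric(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b) + 1
    }
  }
  out <- as_tibble(as.data.frame(X))[, model$vertices]
  attr(out, "coefficients") <- coefficients
  out
}

#' Simulate a qPCR plate with known relative expression
#'
#' Builds a plate table (standard dilution wells plus unknown wells) whose
#' recovered relative expression equals the requested truth in expectation:
#' each sample's housekeeping quantity is drawn around `hk_quantity`, the
#' target-gene quantity is `truth x housekeeping quantity`, and Cts follow
#' the per-gene standard curve with Gaussian noise `ct_sigma`.
#'
#' @param truth Tibble with columns `sample_id`, `gene`, `relative` (the
#'   requested relative expression; the calibrator sample should carry 1).
#' @param calibrator_sample Sample id of the calibrator (must appear in
#'   `truth`).
#' @param curve_params Optional tibble `gene`, `slope`, `intercept`; by
#'   default every gene (including the housekeeping gene) uses the perfect
#'   doubling slope -3.3219 and intercept 30.
#' @param housekeeping_gene Housekeeping gene name. Default `"ACTB"`.
#' @param hk_quantity Median housekeeping template quantity, ng. Default 10.
#' @param hk_cv Lognormal sd of between-sample housekeeping variation.
#'   Default 0 (fixed loading).
#' @param dilutions Standard quantities, ng. Default `c(1, 10, 50, 100)`.
#' @param ct_sigma Ct noise sd, cycles. Default 0.
#' @param n_tech Technical replicates per well group. Default 3.
#' @param seed Integer seed.
#' @return A plate tibble with columns `well_id`, `sample_id`, `gene`, `ct`,
#'   `role`, `standard_quantity`.
#' @export
simulate_qpcr_plate <- function(truth, calibrator_sample,
                                curve_params = NULL,
                                housekeeping_gene = "ACTB",
                                hk_quantity = 10, hk_cv = 0,
                                dilutions = c(1, 10, 50, 100),
                                ct_sigma = 0, n_tech = 3, seed = NULL) {
  check_columns(truth, c("sample_id", "gene", "relative"), "expression truth")
  if (!is.null(seed)) set.seed(seed)
  if (any(truth$relative <= 0)) {
    abort("Requested relative expression must be positive.",
          class = "photolim_invalid_input")
  }
  if (!calibrator_sample %in% truth$sample_id) {
    abort("`calibrator_sample` absent from `truth`.",
          class = "photolim_missing_calibrator")
  }
  genes <- c(unique(truth$gene), housekeeping_gene)
  if (is.null(curve_params)) {
    curve_params <- tibble(gene = genes, slope = -1 / log10(2), intercept = 30)
  }
  check_columns(curve_params, c("gene", "slope", "intercept"), "curve parameters")
  if (any(curve_params$slope >= 0)) {
    abort("Standard-curve slopes must be negative.", class = "photolim_invalid_input")
  }
  missing_genes <- setdiff(genes, curve_params$gene)
  if (length(missing_genes) > 0) {
    abort(sprintf("`curve_params` missing gene(s): %s.",
                  paste(missing_genes, collapse = ", ")),
          class = "photolim_invalid_input")
  }
  ct_of <- function(gene, q) {
    i <- match(gene, curve_params$gene)
    curve_params$slope[i] * log10(q) + curve_params$intercept[i]
  }

  samples <- unique(truth$sample_id)
  hk_q <- setNames(hk_quantity * exp(rnorm(length(samples), 0, hk_cv)), samples)

  wells <- list()
  add_wells <- function(sample_id, gene, q, role, std_q) {
    ct <- ct_of(gene, q) + rnorm(n_tech, 0, ct_sigma)
    wells[[length(wells) + 1]] <<- tibble(
      sample_id = sample_id, gene = gene, ct = ct, role = role,
      standard_quantity = std_q)
  }
  for (g in genes) {
    for (q in dilutions) add_wells(NA_character_, g, q, "standard", q)
  }
  for (i in seq_len(nrow(truth))) {
    s <- truth$sample_id[i]; g <- truth$gene[i]
    add_wells(s, g, truth$relative[i] * hk_q[[s]], "unknown", NA_real_)
  }
  for (s in samples) add_wells(s, housekeeping_gene, hk_q[[s]], "unknown", NA_real_)

  plate <- bind_rows(wells)
  plate %>% mutate(well_id = sprintf("W%03d", row_number())) %>%
    select("well_id", "sample_id", "gene", "ct", "role", "standard_quantity")
}

#' Simulate a complete synthetic drought-recovery study
#'
#' Runs the gas-exchange/water time-course generator, the expression
#' structural equation model (drought enters through the exogenous aquaporin
#' transcript) and the qPCR plate generator, and returns every table with
#' aligned ground truth so each pipeline stage can be validated against
#' known values.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed governing all randomness.
#' @return A list of class `photolim_study` with elements `gasex`, `water`,
#'   `expression`, `qpcr_plate`, `expression_truth`, `truth`, `backbone`,
#'   `calibrator_sample` and `config`.
#' @examples
#' sim <- simulate_study(seed = 42)
#' names(sim)
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- simulate_drought_timecourse(config)

  # expression sampling frame: n_expr_reps per treatment x day; stress
  # drives the exogenous transcript
  frame <- tc$backbone %>%
    filter(.data$day %in% config$days) %>%
    tidyr::uncount(config$n_expr_reps, .id = "rep") %>%
    mutate(sample_id = sprintf("%s_d%d_r%d", .data$treatment,
                               as.integer(.data$day), .data$rep))
  stress <- 1 - frame$f_gs
  stress_z <- if (stats::sd(stress) > 0) as.numeric(scale(stress)) else stress * 0
  a <- config$stress_loading
  pip1_driver <- a * stress_z + sqrt(max(0, 1 - a^2)) * rnorm(nrow(frame))

  model <- model3_acyclic()
  sem <- simulate_expression_sem(model, n = nrow(frame),
                                 coefficients = config$sem_coefficients,
                                 data = tibble(PIP1 = pip1_driver))
  expression <- dplyr::bind_cols(
    frame[, c("sample_id", "treatment", "day")], sem)

  # qPCR truth: transcript abundance on a positive scale, calibrator = the
  # first control sample of the first day
  calibrator <- expression$sample_id[expression$treatment == "C"][1]
  expr_long <- expression %>%
    tidyr::pivot_longer(c("PIP1", "PIP2", "CA"), names_to = "gene",
                        values_to = "z") %>%
    mutate(gene = c(PIP1 = "OePIP1.1", PIP2 = "OePIP2.1", CA = "CA")[.data$gene])
  cal_z <- expr_long %>% filter(.data$sample_id == calibrator) %>%
    select("gene", cal = "z")
  expression_truth <- expr_long %>%
    left_join(cal_z, by = "gene") %>%
    mutate(relative = exp(0.5 * (.data$z - .data$cal))) %>%
    select("sample_id", "treatment", "day", "gene", "relative")

  plate <- simulate_qpcr_plate(
    expression_truth[, c("sample_id", "gene", "relative")],
    calibrator_sample = calibrator, ct_sigma = config$ct_sigma,
    n_tech = config$n_tech)

  structure(
    list(gasex = tc$gasex, water = tc$water, expression = expression,
         qpcr_plate = plate, expression_truth = expression_truth,
         truth = tc$truth, backbone = tc$backbone,
         calibrator_sample = calibrator, config = config),
    class = "photolim_study")
}

#' @export
print.photolim_study <- function(x, ...) {
  cat("Synthetic drought-recovery study\n")
  cat(sprintf("  gas exchange: %d records (%d leaves x %d days)\n",
              nrow(x$gasex), length(unique(x$gasex$leaf_id)),
              length(unique(x$gasex$day))))
  cat(sprintf("  expression samples: %d; qPCR wells: %d\n",
              nrow(x$expression), nrow(x$qpcr_plate)))
  invisible(x)
}
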