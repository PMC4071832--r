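#' Partial Pearson correlation with Fisher-z test
#'
#' Estimates the correlation between `x` and `y` after removing the linear
#' effect of the conditioning variables (equivalently, the correlation of the
#' least-squares residuals of each on the conditioning set; computed here
#' from the inverse covariance submatrix, which is the same estimator). The
#' p-value uses the Fisher z transform: z = atanh(r) * sqrt(n - |S| - 3),
#' two-sided against a standard normal.
#'
#' @param data Data frame containing the variables; incomplete rows over the
#'   involved variables are dropped (complete-case analysis).
#' @param x,y Variable names.
#' @param conditioning_set Character vector of conditioning variable names
#'   (possibly empty).
#' @return A list with `r`, `p`, `n` and `statistic` (the z value).
#' @examples
#' d <- data.frame(a = rnorm(50), b = rnorm(50))
#' partial_correlation(d, "a", "b", character())
#' @export
partial_correlation <- function(data, x, y, conditioning_set = character()) {
  vars <- c(x, y, conditioning_set)
  check_columns(data, vars, "observation")
  if (x == y || x %in% conditioning_set || y %in% conditioning_set) {
    abort("`x`, `y` and the conditioning set must be distinct.",
          class = "photolim_invalid_input")
  }
  m <- as.matrix(data[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- length(conditioning_set)
  if (n <= k + 3) {
    abort(sprintf("Need n > |S| + 3 complete cases (have n = %d, |S| = %d).", n, k),
          class = "photolim_insufficient_data")
  }
  S <- stats::cov(m)
  if (any(diag(S) <= .Machine$double.eps * 100)) {
    abort("A variable has (near-)zero variance.", class = "photolim_zero_variance")
  }
  omega <- tryCatch(solve(S), error = function(e) {
    abort("Covariance matrix is singular (collinear variables).",
          class = "photolim_zero_variance")
  })
  r <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    abort("Residual variables are exactly collinear.",
          class = "photolim_zero_variance")
  }
  z <- atanh(r) * sqrt(n - k - 3)
  list(r = r, p = 2 * pnorm(-abs(z)), n = n, statistic = z)
}

#' Fisher's C combination of independence-test p-values
#'
#' C = -2 sum(log(p_i)). Under a model whose independence claims all hold,
#' C is chi-squared distributed with 2k degrees of freedom (k claims).
#' Zero p-values are floored at `eps` with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param eps Floor applied to p = 0. Default 1e-300.
#' @return Fisher's C (non-negative scalar).
#' @examples
#' fishers_c(c(0.5, 0.5)) # 2.7726
#' @export
fishers_c <- function(p_values, eps = 1e-300) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "photolim_invalid_input")
  }
  if (any(p_values == 0)) {
    warn(sprintf("Zero p-value(s) floored at %g before taking logs.", eps))
    p_values <- pmax(p_values, eps)
  }
  -2 * sum(log(p_values))
}

#' Model p-value from Fisher's C
#'
#' Upper-tail probability of the chi-squared distribution with `df` degrees
#' of freedom at `C`. Large p supports the model (no implied independence is
#' contradicted); small p rejects it.
#'
#' @param C Fisher's C statistic, non-negative.
#' @param df Degrees of freedom: a positive even integer, 2 x number of
#'   claims.
#' @return The model p-value in \[0, 1\].
#' @examples
#' model_pvalue(22.53, 16) # 0.1269
#' @export
model_pvalue <- function(C, df) {
  check_scalar_number(C, "C", lower = 0)
  if (!is.numeric(df) || length(df) != 1 || df <= 0 || df %% 2 != 0) {
    abort("`df` must be a positive even integer.", class = "photolim_invalid_input")
  }
  pchisq(C, df = df, lower.tail = FALSE)
}

#' Test a causal model against data by d-separation
#'
#' Enumerates the model's union basis set, tests each independence claim by
#' Fisher-z partial correlation, combines the claim p-values with Fisher's C,
#' and evaluates C against a chi-squared distribution with 2k degrees of
#' freedom. A saturated model (no missing edges) has no testable claims and
#' reports P = 1 with an `untestable` flag.
#'
#' @param model A validated [causal_model()].
#' @param data Wide data frame, one row per observation unit, one column per
#'   model vertex.
#' @param alpha Rejection level used for the `consistent` verdict.
#'   Default 0.05.
#' @return An object of class `dsep_result`: list with `model_name`, `claims`
#'   (tibble: `x`, `y`, `conditioning_set`, `r`, `p`, `n`), `C`, `df`, `P`,
#'   `n_obs`, `alpha`, `consistent`, `untestable` and `edge_correlations`
#'   (per-edge Pearson r). Supports [tidy()] and [glance()].
#' @examples
#' m <- model3_acyclic()
#' d <- simulate_expression_sem(m, n = 200, seed = 1)
#' test_causal_model(m, d)
#' @export
test_causal_model <- function(model, data, alpha = 0.05) {
  model <- validate_dag(model)
  check_columns(data, model$vertices, "observation")
  claims <- basis_set(model)
  n_obs <- sum(complete.cases(data[, model$vertices, drop = FALSE]))

  if (nrow(claims) == 0) {
    result <- list(model_name = model$name,
                   claims = mutate(claims, r = double(), p = double(), n = integer()),
                   C = 0, df = 0L, P = 1, n_obs = n_obs, alpha = alpha,
                   consistent = TRUE, untestable = TRUE,
                   edge_correlations = edge_correlations(model, data))
    return(structure(result, class = "dsep_result"))
  }

  tested <- purrr::pmap(claims, function(x, y, conditioning_set) {
    partial_correlation(data, x, y, conditioning_set)
  })
  claims <- claims %>%
    mutate(r = vapply(tested, `[[`, 0, "r"),
           p = vapply(tested, `[[`, 0, "p"),
           n = vapply(tested, `[[`, 0L, "n"))
  C <- fishers_c(claims$p)
  df <- 2L * nrow(claims)
  P <- model_pvalue(C, df)
  structure(
    list(model_name = model$name, claims = claims, C = C, df = df, P = P,
         n_obs = n_obs, alpha = alpha, consistent = P >= alpha,
         untestable = FALSE,
         edge_correlations = edge_correlations(model, data)),
    class = "dsep_result"
  )
}

# Pearson correlation along each model edge (the per-arrow annotations of a
# path diagram).
edge_correlations <- function(model, data) {
  if (nrow(model$edges) == 0) {
    return(tibble(from = character(), to = character(), r = double(),
                  p = double()))
  }
  rows <- purrr::pmap(model$edges, function(from, to) {
    pc <- partial_correlation(data, from, to, character())
    tibble(from = from, to = to, r = pc$r, p = pc$p)
  })
  bind_rows(rows)
}

#' @export
print.dsep_result <- function(x, ...) {
  cat(sprintf("d-separation test of model '%s'\n", x$model_name))
  cat(sprintf("  %d independence claims, n = %d\n", nrow(x$claims), x$n_obs))
  cat(sprintf("  Fisher's C = %.3f, df = %d, P = %.4f\n", x$C, x$df, x$P))
  if (x$untestable) {
    cat("  saturated model: untestable (P = 1 by convention)\n")
  } else {
    cat(sprintf("  %s with the data at alpha = %g\n",
                if (x$consistent) "consistent" else "inconsistent", x$alpha))
  }
  invisible(x)
}

#' Compare several causal models on shared data
#'
#' Tests each model by [test_causal_model()] and ranks the results by model
#' p-value (descending; higher P = fewer contradicted independencies), with
#' ties broken in favour of fewer edges (the more parsimonious model).
#'
#' @param models List of validated [causal_model()] objects (at least 2 to
#'   make a comparison; a single model yields a one-row table).
#' @param data Wide data frame covering every model's vertices.
#' @param alpha Rejection level. Default 0.05.
#' @return A tibble: `model`, `C`, `df`, `P`, `n_claims`, `n_edges`,
#'   `consistent`, `untestable`, ranked best first, with a `rank` column.
#' @export
compare_causal_models <- function(models, data, alpha = 0.05) {
  if (inherits(models, "causal_model")) models <- list(models)
  rows <- purrr::map(models, function(m) {
    res <- test_causal_model(m, data, alpha = alpha)
    tibble(model = res$model_name, C = res$C, df = res$df, P = res$P,
           n_claims = nrow(res$claims), n_edges = nrow(m$edges),
           consistent = res$consistent, untestable = res$untestable)
  })
  bind_rows(rows) %>%
    arrange(desc(.data$P), .data$n_edges) %>%
    mutate(rank = row_number())
}
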