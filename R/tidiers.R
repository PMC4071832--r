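#' @describeIn calibrate_phi_relationship Coefficient table of the
#'   calibration fit.
#' @param x A `phi_calibration` object.
#' @param ... Unused.
#' @export
tidy.phi_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(x$coef_table[, "Std. Error"]))
}

#' @describeIn calibrate_phi_relationship One-row model summary.
#' @export
glance.phi_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, nonlinear = x$nonlinear)
}

#' @describeIn fit_standard_curve Coefficient table of the standard curve.
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_standard_curve One-row curve summary with efficiency.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(gene = x$gene, slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, efficiency = x$efficiency, n = x$n)
}

#' @describeIn test_causal_model Per-claim tibble: variables, conditioning
#'   set (collapsed to a string), partial r and p-value.
#' @param x A `dsep_result` object.
#' @param ... Unused.
#' @export
tidy.dsep_result <- function(x, ...) {
  x$claims %>%
    mutate(conditioning_set = vapply(.data$conditioning_set,
                                     paste, "", collapse = ","))
}

#' @describeIn test_causal_model One-row model summary: C, df, P, n, verdict.
#' @export
glance.dsep_result <- function(x, ...) {
  tibble(model = x$model_name, C = x$C, df = x$df, P = x$P,
         n_obs = x$n_obs, consistent = x$consistent,
         untestable = x$untestable)
}

#' @describeIn causal_model Edge list as a tibble.
#' @param x A `causal_model` object.
#' @param ... Unused.
#' @export
tidy.causal_model <- function(x, ...) {
  x$edges
}
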