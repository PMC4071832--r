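#' Time-course plot of a derived gas-exchange variable
#'
#' Treatment-mean time course (with replicate points) of any derived column,
#' with the rewatering day marked.
#'
#' @param derived Output of [derive_gasex()].
#' @param var Column to plot (string). Default `"g_m"`.
#' @param rewater_day Day irrigation resumed. Default 13.
#' @param reliable_only Drop unreliable records first. Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(derived, var = "g_m", rewater_day = 13,
                            reliable_only = TRUE) {
  check_columns(derived, c("day", "treatment", var), "derived gas-exchange")
  if (reliable_only && "reliable" %in% names(derived)) {
    derived <- derived[derived$reliable, , drop = FALSE]
  }
  means <- derived %>%
    group_by(.data$treatment, .data$day) %>%
    summarise(value = mean(.data[[var]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$day, y = .data$value,
                               colour = .data$treatment)) +
    ggplot2::geom_vline(xintercept = rewater_day, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day (relative to water withholding)", y = var,
                  colour = "treatment") +
    ggplot2::theme_minimal()
}

#' Stacked-area plot of the limitation partition
#'
#' Shows S_L, MC_L and B_L through time for each stressed treatment.
#' Negative components (stressed value above reference) plot below zero.
#'
#' @param limitations Output of [limitation_analysis()].
#' @return A ggplot object.
#' @export
plot_limitations <- function(limitations) {
  check_columns(limitations, c("day", "treatment", "S_L", "MC_L", "B_L"),
                "limitation partition")
  long <- limitations %>%
    tidyr::pivot_longer(c("S_L", "MC_L", "B_L"), names_to = "component",
                        values_to = "value") %>%
    mutate(component = factor(.data$component, c("S_L", "MC_L", "B_L")))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$day, y = .data$value,
                               fill = .data$component)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "day (relative to water withholding)",
                  y = "limitation (fraction of reference A)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_standard_curve Dilution-series scatter with the fitted
#'   line.
#' @param object A `standard_curve` object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10(.data$standard_quantity),
                               y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(template quantity, ng)", y = "Ct",
      title = sprintf("Standard curve%s: slope %.3f, eff. %.3f",
                      if (!is.na(object$gene)) paste0(" (", object$gene, ")")
                      else "", object$slope, object$efficiency)) +
    ggplot2::theme_minimal()
}

#' @describeIn test_causal_model Per-claim p-value plot with the rejection
#'   level marked.
#' @param object A `dsep_result` object.
#' @export
autoplot.dsep_result <- function(object, ...) {
  claims <- tidy(object) %>%
    mutate(claim = paste0(.data$x, " _||_ ", .data$y, " | {",
                          .data$conditioning_set, "}"))
  ggplot2::ggplot(claims,
                  ggplot2::aes(x = .data$p, y = stats::reorder(.data$claim,
                                                               .data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::labs(
      x = "independence-claim p-value", y = NULL,
      title = sprintf("%s: C = %.2f, df = %d, P = %.3f",
                      object$model_name, object$C, object$df, object$P)) +
    ggplot2::theme_minimal()
}
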