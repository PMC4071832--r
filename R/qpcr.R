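#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Ct against log10(template quantity) over a
#' dilution series (the classic 1, 10, 50, 100 ng design). The slope of a
#' perfectly doubling reaction is -1/log10(2) = -3.3219 cycles per decade;
#' amplification efficiency is reported as 10^(-1/slope) - 1 and a warning is
#' emitted when it falls outside 0.9..1.1. Efficiency is reported for QC only:
#' the relative standard curve method interpolates every unknown on the same
#' curve, which subsumes the efficiency.
#'
#' @param standards Data frame of standard wells with columns `ct` and
#'   `standard_quantity` (ng); at least 3 distinct quantities are required.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`, `quantity_range`, `gene`
#'   (if a `gene` column is present and unique). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' std <- tibble::tibble(standard_quantity = c(1, 10, 50, 100),
#'                       ct = -3.3219 * log10(c(1, 10, 50, 100)) + 30)
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards) {
  check_columns(standards, c("ct", "standard_quantity"), "standards")
  standards <- standards[is.finite(standards$ct) &
                           is.finite(standards$standard_quantity), , drop = FALSE]
  if (any(standards$standard_quantity <= 0)) {
    abort("Standard quantities must be positive.", class = "photolim_invalid_input")
  }
  if (length(unique(standards$standard_quantity)) < 3) {
    abort("At least 3 distinct standard quantities are required.",
          class = "photolim_insufficient_data")
  }
  lq <- log10(standards$standard_quantity)
  fit <- lm(standards$ct ~ lq)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    abort("Standard-curve slope is non-negative: Ct must decrease with template quantity.",
          class = "photolim_invalid_curve")
  }
  # r^2 computed directly (summary.lm warns on exact dilution series)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$ct - mean(standards$ct))^2)
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency < 0.9 || efficiency > 1.1) {
    warn(sprintf("Amplification efficiency %.3f outside 0.9..1.1.", efficiency))
  }
  gene <- if ("gene" %in% names(standards) &&
              length(unique(standards$gene)) == 1) standards$gene[1] else NA_character_
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = r2, efficiency = efficiency,
         n = nrow(standards), quantity_range = range(standards$standard_quantity),
         gene = gene, data = as_tibble(standards[, c("standard_quantity", "ct")])),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve%s\n",
              if (!is.na(x$gene)) paste0(" [", x$gene, "]") else ""))
  cat(sprintf("  Ct = %.4f * log10(ng) + %.4f   (r^2 %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  efficiency %.3f\n", x$efficiency))
  invisible(x)
}

#' Interpolate template quantity from a standard curve
#'
#' Q = 10^((ct - intercept)/slope). Cts outside the fitted dilution range are
#' interpolated anyway but flagged as extrapolations.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param ct Observed Ct value(s).
#' @return A tibble with columns `ct`, `quantity` (ng) and `extrapolated`.
#' @examples
#' std <- tibble::tibble(standard_quantity = c(1, 10, 50, 100),
#'                       ct = -3.3219 * log10(c(1, 10, 50, 100)) + 30)
#' interpolate_quantity(fit_standard_curve(std), 26.678)
#' @export
interpolate_quantity <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  quantity <- 10^((ct - curve$intercept) / curve$slope)
  tibble(ct = ct, quantity = quantity,
         extrapolated = quantity < curve$quantity_range[1] |
           quantity > curve$quantity_range[2])
}

#' Relative gene expression by the relative standard curve method
#'
#' For each gene, fits a standard curve from that gene's dilution-series
#' wells, averages technical replicates on the Ct scale, interpolates each
#' unknown's template quantity, normalizes by the same sample's housekeeping
#' quantity, and scales by the calibrator sample's normalized value so the
#' calibrator's relative expression is exactly 1. Wells with Ct above
#' `ct_max` are treated as missing and flagged.
#'
#' @param plate Plate table with columns `well_id`, `sample_id`, `gene`,
#'   `ct`, `role` (`"standard"` or `"unknown"`) and `standard_quantity`
#'   (ng, required on standard wells).
#' @param housekeeping_gene Housekeeping gene name. Default `"ACTB"`.
#' @param calibrator_sample Sample id of the calibrator.
#' @param average_on Average technical replicates on the `"ct"` scale
#'   (manufacturer convention, default) or on the `"quantity"` scale.
#' @param ct_max Cts above this are flagged missing. Default 40.
#' @return A tibble with one row per sample x target gene: `sample_id`,
#'   `gene`, `quantity`, `hk_quantity`, `normalized`, `relative`, `flags`.
#' @export
relative_expression <- function(plate, housekeeping_gene = "ACTB",
                                calibrator_sample,
                                average_on = c("ct", "quantity"),
                                ct_max = 40) {
  check_columns(plate, c("well_id", "sample_id", "gene", "ct", "role"),
                "qPCR plate")
  average_on <- match.arg(average_on)
  plate <- as_tibble(plate)
  if (!housekeeping_gene %in% plate$gene) {
    abort(sprintf("Housekeeping gene '%s' absent from the plate.", housekeeping_gene),
          class = "photolim_missing_housekeeping")
  }

  standards <- plate[plate$role == "standard", , drop = FALSE]
  unknowns <- plate[plate$role == "unknown", , drop = FALSE]
  if (nrow(standards) > 0) check_columns(standards, "standard_quantity", "standards")

  curves <- standards %>%
    group_by(.data$gene) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(curve = purrr::map2(.data$data, .data$gene, function(d, g) {
      fit_standard_curve(mutate(d, gene = g))
    })) %>%
    select("gene", "curve")

  genes_needed <- unique(unknowns$gene)
  missing_curves <- setdiff(genes_needed, curves$gene)
  if (length(missing_curves) > 0) {
    abort(sprintf("No standard series for gene%s: %s.",
                  if (length(missing_curves) > 1) "s" else "",
                  paste(missing_curves, collapse = ", ")),
          class = "photolim_missing_standards")
  }

  flagged_missing <- unknowns$ct > ct_max
  unknowns <- mutate(unknowns, ct = ifelse(flagged_missing, NA_real_, .data$ct))

  quantify <- function(cts, gene) {
    curve <- curves$curve[[match(gene, curves$gene)]]
    if (average_on == "ct") {
      q <- interpolate_quantity(curve, mean(cts, na.rm = TRUE))
    } else {
      per_well <- interpolate_quantity(curve, cts)
      q <- tibble(quantity = mean(per_well$quantity, na.rm = TRUE),
                  extrapolated = any(per_well$extrapolated, na.rm = TRUE))
    }
    tibble(quantity = q$quantity, extrapolated = isTRUE(any(q$extrapolated)),
           any_missing = anyNA(cts))
  }

  quantities <- unknowns %>%
    group_by(.data$sample_id, .data$gene) %>%
    summarise(quantify(.data$ct, .data$gene[1]), .groups = "drop")

  hk <- quantities %>%
    filter(.data$gene == housekeeping_gene) %>%
    select("sample_id", hk_quantity = "quantity")
  targets <- quantities %>% filter(.data$gene != housekeeping_gene)

  no_hk <- setdiff(unique(targets$sample_id), hk$sample_id)
  if (length(no_hk) > 0) {
    abort(sprintf("Missing housekeeping wells for sample%s: %s.",
                  if (length(no_hk) > 1) "s" else "",
                  paste(no_hk, collapse = ", ")),
          class = "photolim_missing_housekeeping")
  }
  if (!calibrator_sample %in% targets$sample_id) {
    abort(sprintf("Calibrator sample '%s' has no target-gene wells.", calibrator_sample),
          class = "photolim_missing_calibrator")
  }

  out <- targets %>%
    left_join(hk, by = "sample_id") %>%
    mutate(normalized = .data$quantity / .data$hk_quantity)

  cal <- out %>% filter(.data$sample_id == calibrator_sample) %>%
    select("gene", cal_normalized = "normalized")
  missing_cal <- setdiff(unique(out$gene), cal$gene)
  if (length(missing_cal) > 0) {
    abort(sprintf("Calibrator sample '%s' missing for gene%s: %s.",
                  calibrator_sample, if (length(missing_cal) > 1) "s" else "",
                  paste(missing_cal, collapse = ", ")),
          class = "photolim_missing_calibrator")
  }

  out %>%
    left_join(cal, by = "gene") %>%
    mutate(relative = .data$normalized / .data$cal_normalized,
           flags = paste0(ifelse(.data$extrapolated, "extrapolated;", ""),
                          ifelse(.data$any_missing, "ct_missing;", ""))) %>%
    select("sample_id", "gene", "quantity", "hk_quantity", "normalized",
           "relative", "flags") %>%
    arrange(.data$gene, .data$sample_id)
}

#' Normalize a time series to its first date
#'
#' Divides every value by the mean of its group's first-date values — the
#' shared scaling applied to expression, stomatal conductance and mesophyll
#' conductance series before cross-variable comparison.
#'
#' @param data Long table with at least `day` and `value` columns.
#' @param value Name of the value column. Default `"value"`.
#' @param group Character vector of grouping columns (e.g.
#'   `c("treatment", "gene")`); scaling is per group. Default none.
#' @return The input tibble with a `value_rel_day0` column appended
#'   (named `<value>_rel_day0`).
#' @examples
#' d <- tibble::tibble(day = c(1, 5, 9), value = c(2, 4, 1))
#' normalize_to_first_date(d)
#' @export
normalize_to_first_date <- function(data, value = "value", group = character()) {
  check_columns(data, c("day", value, group), "series")
  out_col <- paste0(value, "_rel_day0")
  data <- as_tibble(data)
  scaled <- data %>%
    group_by(across(all_of(group))) %>%
    mutate("{out_col}" := {
      first_day <- min(.data$day)
      ref <- mean(.data[[value]][.data$day == first_day])
      if (!is.finite(ref) || ref == 0) {
        abort("First-date mean is zero or non-finite; cannot normalize.",
              class = "photolim_invalid_input")
      }
      .data[[value]] / ref
    }) %>%
    ungroup()
  scaled
}
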