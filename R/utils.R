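# Shared input validation helpers.

check_columns <- function(data, required, what) {
  if (!is.data.frame(data)) {
    abort(sprintf("%s input must be a data frame.", what),
          class = "photolim_invalid_input")
  }
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column%s: %s",
                  what, if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")),
          class = "photolim_missing_column")
  }
  invisible(data)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "photolim_invalid_input")
  }
  invisible(x)
}
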