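# Internal helpers: argument checks, scoped RNG, number formatting.

abort_input <- function(msg, class = "natzone_input_error") {
  rlang::abort(msg, class = c(class, "natzone_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort_input(sprintf(
      "`%s` must be a single number %s %s and <= %s (got: %s)",
      name, if (strict_lower) ">" else ">=", format(lower), format(upper),
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_nonneg_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort_input(sprintf("`%s` must be a numeric vector with no negative or missing values", name))
  }
  invisible(x)
}

# Evaluate `expr` under a private RNG stream; the caller's .Random.seed is
# untouched. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

# 15 significant digits: the serialization contract for all writers.
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- rlang::`%||%`
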