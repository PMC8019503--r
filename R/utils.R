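#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here use
#' conventional half-up rounding (e.g. 84.975 -> 84.98).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic number rendering for SQL and ADL text: integers without a
# decimal point, non-integers as plain decimal (never scientific).
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (!is.finite(v)) return(as.character(v))
    if (v == floor(v) && abs(v) < 1e15) {
      format(v, scientific = FALSE, trim = TRUE, nsmall = 0)
    } else {
      sub("0+$", "", format(v, scientific = FALSE, trim = TRUE, nsmall = 12))
    }
  }, character(1))
  out
}

# SQL identifier quoting (ANSI double quotes); names are taken verbatim.
quote_ident <- function(x) {
  paste0('"', gsub('"', '""', x), '"')
}

# SQL string literal quoting.
quote_literal <- function(x) {
  paste0("'", gsub("'", "''", x), "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dqr <- function(..., class, call. = FALSE) {
  stop(structure(
    class = c(class, "dqrgen_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
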