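#' Round half away from zero
#'
#' Registry reports print percentages rounded half away from zero (so
#' 86.55 prints as 86.6, -0.5 as -1), unlike [base::round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.25, -0.5), 0)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count ratio as a percentage
#'
#' The summary-statistic formatter used throughout the audit reports:
#' `100 * numerator / denominator`, rounded half away from zero to
#' `digits` decimal places (one decimal by default, matching the precision
#' registry audits conventionally print).
#'
#' @param numerator,denominator non-negative counts.
#' @param digits decimal places (use 0 where reports print integers).
#' @return numeric percentage; `NA` when the denominator is zero.
#' @export
#' @examples
#' format_pct(26932, 31118)  # 86.5
#' format_pct(2764, 4186, digits = 0)  # 66
format_pct <- function(numerator, denominator, digits = 1) {
  out <- ifelse(denominator == 0, NA_real_,
                round_half_away(100 * numerator / denominator, digits))
  as.numeric(out)
}

# ISO date parse that fails loudly with context, vectorised.
parse_iso_date <- function(x, field, line = NULL) {
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- is.na(x) | x == ""
  if (any(!ok)) {
    parsed <- as.Date(x[!ok], format = "%Y-%m-%d", optional = TRUE)
    bad <- is.na(parsed)
    if (any(bad)) {
      where <- if (!is.null(line)) sprintf(" (line %s)", paste(line[!ok][bad], collapse = ", ")) else ""
      stop(sprintf("unparseable date in field '%s': %s%s", field,
                   paste(unique(x[!ok][bad]), collapse = ", "), where),
           call. = FALSE)
    }
    out[!ok] <- parsed
  }
  out
}

# %||% for defaulting NULLs.
`%||%` <- function(a, b) if (is.null(a)) b else a

# min() that stays quiet and typed on empty input (dplyr probes summarise
# expressions on zero-row slices).
min_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) x[NA_integer_] else min(x)
}
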