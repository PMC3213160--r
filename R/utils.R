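#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Read a tab-separated table
#'
#' All pipeline TSV readers go through here: tolerates CRLF line endings and
#' comment lines starting with '#', never converts strings to factors.
#' @noRd
read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' @noRd
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a value is a single finite number, erroring with the field name
#' @noRd
check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("invalid configuration: '%s' must be a single finite number", field)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("invalid configuration: '%s' = %s is outside the allowed range %s%s, %s%s",
          field, format(x), if (strict_lower) "(" else "[", format(lower),
          format(upper), if (strict_upper) ")" else "]")
  if (integer && x != round(x))
    stopf("invalid configuration: '%s' must be an integer count", field)
  invisible(x)
}
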