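# Internal helpers: FAERS-style dates and small formatting utilities.

# FAERS dates are YYYYMMDD integers; partial entries (YYYYMM, YYYY) occur and
# must be preserved, never silently coerced to a day.

#' @noRd
date_status <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  digits <- grepl("^[0-9]+$", x)
  out[digits & nchar(x) == 8L] <- "full"
  out[digits & nchar(x) %in% c(4L, 6L)] <- "partial"
  out[!is.na(x) & nzchar(x) & !digits] <- "partial"
  out[is.na(x) | !nzchar(x)] <- "missing"
  out
}

#' @noRd
parse_full_date <- function(x) {
  x <- trimws(as.character(x))
  d <- rep(as.Date(NA), length(x))
  ok <- date_status(x) == "full"
  if (any(ok)) {
    parsed <- as.Date(x[ok], format = "%Y%m%d")
    d[ok] <- parsed
  }
  d
}

#' @noRd
date_to_int <- function(d) {
  out <- rep(NA_integer_, length(d))
  ok <- !is.na(d)
  out[ok] <- as.integer(format(d[ok], "%Y%m%d"))
  out
}

# Percent of a total, 1 decimal, the convention used in descriptive tables.
#' @noRd
pct1 <- function(count, total) {
  if (total == 0) return(rep(NA_real_, length(count)))
  round(100 * count / total, 1)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalized drug-name comparison: case-insensitive, whitespace-trimmed,
# inner whitespace collapsed.
#' @noRd
norm_name <- function(x) toupper(gsub("[[:space:]]+", " ", trimws(x)))

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
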