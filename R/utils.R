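# Missing-value dialect: accept "n/a", "NA" and "" on read; write "n/a".
.MISSING_TOKENS <- c("n/a", "NA", "")

.is_missing_token <- function(x) {
  is.na(x) | trimws(x) %in% .MISSING_TOKENS
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min)
    .stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min)
    .stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

# Parse a character column to numeric, reporting the 1-based data row of the
# first unparseable cell. Missing tokens become NA.
.parse_numeric_column <- function(x, column, path = NULL) {
  miss <- .is_missing_token(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad) > 0L) {
    where <- if (is.null(path)) "" else sprintf(" in '%s'", path)
    .stopf("cannot parse '%s' as a number in column '%s', row %d%s",
           x[bad[1L]], column, bad[1L], where)
  }
  out[miss] <- NA_real_
  out
}

.parse_logical_column <- function(x, column) {
  miss <- .is_missing_token(x)
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[low %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- which(!miss & is.na(out))
  if (length(bad) > 0L)
    .stopf("cannot interpret '%s' as a logical in column '%s', row %d",
           x[bad[1L]], column, bad[1L])
  out
}

.format_bids_cell <- function(x, digits = 6L) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "n/a",
                  formatC(x, digits = digits, format = "fg", flag = "#"))
    # formatC leaves trailing zeros/points; trim them for clean TSVs
    out <- sub("\\.$", "", sub("0+$", "", out))
    out[out == ""] <- "0"
    out
  } else if (is.logical(x)) {
    ifelse(is.na(x), "n/a", ifelse(x, "1", "0"))
  } else {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", "n/a", x)
  }
}

.modal_value <- function(x) {
  # Returns list(value, tied): the most frequent value, or tied = TRUE when
  # no strict majority mode exists.
  tab <- table(x)
  mx <- max(tab)
  winners <- names(tab)[tab == mx]
  list(value = winners[1L], tied = length(winners) > 1L)
}
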