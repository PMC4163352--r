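# internal validation helpers shared across modules

validate_series <- function(x, min_len = 1L, arg = deparse(substitute(x))) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  }
  x <- as.numeric(x)
  if (length(x) < min_len) {
    stop(sprintf("`%s` must have at least %d observations, got %d",
                 arg, min_len, length(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  x
}

validate_count <- function(k, min = 1L, arg = deparse(substitute(k))) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k != floor(k) ||
      k < min) {
    stop(sprintf("`%s` must be a single integer >= %d", arg, min),
         call. = FALSE)
  }
  as.integer(k)
}

# seed derived values must stay below .Machine$integer.max (2^31 - 1)
derive_seed <- function(base, offset) {
  as.integer((as.double(base) + as.double(offset)) %% 2147483647)
}

#' Read a univariate series from CSV
#'
#' Accepts either a two-column file with header `period,value` (period an
#' ISO date or integer index) or a single `value` column. UTF-8, comma
#' delimited, `.` decimal separator.
#'
#' @param path path to a CSV file.
#' @return a numeric vector with attribute `period` holding the period
#'   labels (if present).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) == 0L) stop("empty CSV: ", path, call. = FALSE)
  if ("value" %in% names(df)) {
    x <- as.numeric(df$value)
  } else {
    x <- as.numeric(df[[ncol(df)]])
  }
  x <- validate_series(x, min_len = 1L, arg = "value")
  if ("period" %in% names(df)) attr(x, "period") <- df$period
  x
}

#' Write a series (optionally with decomposition columns) to CSV
#'
#' @param x numeric series.
#' @param path output path.
#' @param low,high optional decomposition components of the same length;
#'   when given the output has columns `period,value,low,high`.
#' @param period optional period labels; defaults to `1:length(x)`.
#' @return invisibly, the path written.
#' @export
write_series <- function(x, path, low = NULL, high = NULL, period = NULL) {
  n <- length(x)
  if (is.null(period)) period <- seq_len(n)
  df <- data.frame(period = period, value = as.numeric(x))
  if (!is.null(low)) {
    stopifnot(length(low) == n, length(high) == n)
    df$low <- as.numeric(low)
    df$high <- as.numeric(high)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
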