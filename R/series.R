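#' Monthly consumer-price-index series
#'
#' A `cpi_series` is a monthly `ts` (frequency 12) of strictly positive index
#' levels on a gap-free calendar grid. It is the raw input of the pipeline:
#' annualized inflation is derived from it with [annualized_inflation()].
#'
#' @param values Numeric vector of index levels, all strictly positive.
#' @param start Start month as `c(year, month)`.
#' @return An object of class `c("cpi_series", "ts")`.
#' @seealso [read_cpi_csv()], [annualized_inflation()],
#'   [simulate_cpi_from_inflation()]
#' @export
#' @examples
#' cpi_series(rep(100, 24), start = c(2010, 1))
cpi_series <- function(values, start = c(2010, 1)) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("cpi_series needs at least one value")
  if (anyNA(values)) stop("index levels must not contain missing values")
  if (any(values <= 0)) stop("index levels must be strictly positive")
  structure(stats::ts(values, start = start, frequency = 12),
            class = c("cpi_series", "ts"))
}

#' Annualized inflation series
#'
#' An `inflation_series` holds year-over-year inflation rates as decimal
#' fractions (0.05 = 5%) on a monthly grid. Values must exceed -1 (an index
#' cannot lose more than all of its level in a year).
#'
#' @param values Numeric vector of inflation rates (decimal fractions > -1).
#' @param start Start month as `c(year, month)`.
#' @return An object of class `c("inflation_series", "ts")`.
#' @export
inflation_series <- function(values, start = c(2011, 1)) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("inflation_series needs at least one value")
  if (anyNA(values)) stop("inflation values must not contain missing values")
  if (any(values <= -1)) stop("inflation values must be > -1")
  structure(stats::ts(values, start = start, frequency = 12),
            class = c("inflation_series", "ts"))
}

# (year, month) pair for each point of a monthly ts
month_index <- function(x) {
  tt <- stats::time(x)
  yr <- floor(tt + 1e-7)
  mo <- round((tt - yr) * 12) + 1
  cbind(year = as.integer(yr), month = as.integer(mo))
}

#' Month labels ("YYYY-MM") of a monthly series
#'
#' @param x A monthly `ts` (e.g. `cpi_series` or `inflation_series`).
#' @return Character vector of ISO year-month labels.
#' @export
month_labels <- function(x) {
  ym <- month_index(x)
  sprintf("%04d-%02d", ym[, 1], ym[, 2])
}

parse_year_month <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]{4})[-/]([0-9]{1,2})([-/][0-9]{1,2})?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("cannot parse date value(s) as year-month: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  yr <- vapply(m, function(g) as.integer(g[2]), 1L)
  mo <- vapply(m, function(g) as.integer(g[3]), 1L)
  if (any(mo < 1 | mo > 12)) stop("month outside 1..12 in date column")
  cbind(year = yr, month = mo)
}

#' Read a monthly index series from CSV
#'
#' Reads an INEGI-style monthly price-index table: one header row, a
#' year-month column (ISO `"YYYY-MM"` or `"YYYY-MM-DD"`) and one or more
#' numeric index columns (wide multi-product files are supported by naming
#' the product column). Rows may be unordered; the result is sorted by month.
#' Missing months, duplicated months and non-positive index levels are hard
#' errors — no imputation is attempted.
#'
#' @param path Path to the CSV file.
#' @param date_column Name of the year-month column.
#' @param value_column Name of the index-level column to read.
#' @return A [cpi_series()].
#' @export
read_cpi_csv <- function(path, date_column = "date", value_column = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(date_column, value_column)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found; available: ",
           paste(names(df), collapse = ", "))
    }
  }
  ym <- parse_year_month(df[[date_column]])
  key <- ym[, "year"] * 12L + (ym[, "month"] - 1L)
  ord <- order(key)
  key <- key[ord]
  vals <- suppressWarnings(as.numeric(df[[value_column]][ord]))
  if (anyNA(vals)) stop("non-numeric or missing index values in '", value_column, "'")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate month %04d-%02d in '%s'", d %/% 12L, d %% 12L + 1L, path))
  }
  gaps <- which(diff(key) != 1L)
  if (length(gaps) > 0L) {
    miss <- key[gaps[1]] + 1L
    stop(sprintf("missing month %04d-%02d in '%s'", miss %/% 12L, miss %% 12L + 1L, path))
  }
  if (any(vals <= 0)) stop("non-positive index value in '", value_column, "'")
  cpi_series(vals, start = c(key[1] %/% 12L, key[1] %% 12L + 1L))
}

#' Annualized (year-over-year) inflation of an index series
#'
#' Computes `pi_t = p_t / p_{t-12} - 1` for every month with a 12-month-old
#' counterpart, so the result starts exactly one year after the index does
#' and is 12 observations shorter.
#'
#' @param cpi A [cpi_series()] of length at least 13.
#' @return An [inflation_series()] of decimal inflation rates.
#' @export
#' @examples
#' cpi <- cpi_series(100 * 1.05^(seq_len(36) / 12), start = c(2010, 1))
#' annualized_inflation(cpi)  # constant 5% a year
annualized_inflation <- function(cpi) {
  if (!inherits(cpi, "cpi_series")) cpi <- cpi_series(cpi)
  p <- as.numeric(cpi)
  n <- length(p)
  if (n < 13L) stop("need at least 13 monthly index values, got ", n)
  pi_t <- p[13:n] / p[1:(n - 12L)] - 1
  ym <- month_index(cpi)[13L, ]
  inflation_series(pi_t, start = c(ym[["year"]], ym[["month"]]))
}

#' Descriptive statistics of an inflation series
#'
#' Mean, sample standard deviation, range, moment skewness (g1) and Pearson
#' kurtosis (so a normal sample gives values near 3, not 0). All location
#' statistics are in decimal-fraction inflation units. For a constant series
#' the standard deviation is 0, skewness is reported as 0 by convention and
#' kurtosis as `NA` (it is 0/0).
#'
#' @param x An [inflation_series()] or numeric vector, length >= 2.
#' @return A one-row `data.frame` with columns `mean`, `sd`, `min`, `max`,
#'   `skewness`, `kurtosis`.
#' @export
descriptive_stats <- function(x) {
  v <- as.numeric(x)
  if (length(v) < 2L) stop("need at least 2 observations for descriptive stats")
  if (stats::sd(v) == 0) {
    skew <- 0
    kurt <- NA_real_
  } else {
    skew <- e1071::skewness(v, type = 1)
    kurt <- e1071::kurtosis(v, type = 1) + 3  # Pearson convention
  }
  data.frame(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
             skewness = skew, kurtosis = kurt)
}

#' Write an inflation series to CSV
#'
#' Two columns: `date` ("YYYY-MM") and `inflation_decimal`.
#'
#' @param x An [inflation_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inflation_csv <- function(x, path) {
  df <- data.frame(date = month_labels(x), inflation_decimal = as.numeric(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an inflation series from CSV
#'
#' Counterpart of [write_inflation_csv()]; the same gap/duplicate checks as
#' [read_cpi_csv()] apply, but values only need to exceed -1.
#'
#' @inheritParams read_cpi_csv
#' @return An [inflation_series()].
#' @export
read_inflation_csv <- function(path, date_column = "date",
                               value_column = "inflation_decimal") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(date_column, value_column)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found; available: ",
           paste(names(df), collapse = ", "))
    }
  }
  ym <- parse_year_month(df[[date_column]])
  key <- ym[, "year"] * 12L + (ym[, "month"] - 1L)
  ord <- order(key)
  key <- key[ord]
  vals <- suppressWarnings(as.numeric(df[[value_column]][ord]))
  if (anyNA(vals)) stop("non-numeric or missing values in '", value_column, "'")
  if (anyDuplicated(key)) stop("duplicate month in '", path, "'")
  if (any(diff(key) != 1L)) stop("missing month in '", path, "'")
  inflation_series(vals, start = c(key[1] %/% 12L, key[1] %% 12L + 1L))
}

#' @export
print.cpi_series <- function(x, ...) {
  cat(sprintf("<cpi_series> %d months, %s .. %s\n", length(x),
              month_labels(x)[1], month_labels(x)[length(x)]))
  print(stats::ts(as.numeric(x), start = stats::start(x), frequency = 12), ...)
  invisible(x)
}

#' @export
print.inflation_series <- function(x, ...) {
  cat(sprintf("<inflation_series> %d months, %s .. %s (decimal fractions)\n",
              length(x), month_labels(x)[1], month_labels(x)[length(x)]))
  print(stats::ts(as.numeric(x), start = stats::start(x), frequency = 12), ...)
  invisible(x)
}
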