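#' Monthly monitoring time series
#'
#' Constructs a validated monitoring series: one variable (phytoplankton or
#' zooplankton abundance, or water temperature) observed at monthly time
#' steps, possibly with missing values (`NA`) and with winter gaps, i.e.
#' calendar months that were never sampled. Samples are sorted into calendar
#' order; duplicate (year, month) pairs are an error. Abundance variables
#' must be strictly positive wherever observed, because they appear in
#' denominators of the model inversion; temperature may take any real value.
#'
#' @param year integer calendar years.
#' @param month integer months, 1--12.
#' @param value numeric values; `NA` marks a missing observation.
#' @param lake identifier of the water body.
#' @param variable one of `"phytoplankton"`, `"zooplankton"`, `"temperature"`.
#' @param units free-text units (e.g. `"mg/l"`, `"degC"`).
#' @return An object of class `monitoring_series`: a data frame with columns
#'   `year`, `month`, `value` and attributes `lake`, `variable`, `units`.
#' @examples
#' monitoring_series(2001, 5:9, c(1.2, NA, 0.8, 1.5, 1.1),
#'                   lake = "demo", variable = "phytoplankton")
#' @export
monitoring_series <- function(year, month, value,
                              lake = "unknown",
                              variable = c("phytoplankton", "zooplankton",
                                           "temperature"),
                              units = "") {
  variable <- match.arg(variable)
  n <- max(length(year), length(month), length(value))
  year <- as.integer(rep_len(year, n))
  month <- as.integer(rep_len(month, n))
  value <- as.numeric(rep_len(value, n))
  if (anyNA(year) || anyNA(month))
    stop("year and month must be complete integers", call. = FALSE)
  if (any(month < 1L | month > 12L))
    stop("month must be in 1..12", call. = FALSE)
  mi <- month_index(year, month)
  if (anyDuplicated(mi))
    stop("duplicate (year, month) pair in series", call. = FALSE)
  o <- order(mi)
  year <- year[o]; month <- month[o]; value <- value[o]
  if (variable != "temperature" && any(value <= 0, na.rm = TRUE))
    stop(sprintf("%s abundance must be > 0 where observed", variable),
         call. = FALSE)
  structure(
    data.frame(year = year, month = month, value = value),
    lake = lake, variable = variable, units = units,
    class = c("monitoring_series", "data.frame"))
}

# linear month index: consecutive calendar months differ by exactly 1
month_index <- function(year, month) year * 12L + month

series_variable <- function(x) attr(x, "variable", exact = TRUE)
series_lake <- function(x) attr(x, "lake", exact = TRUE)

#' Read a monitoring series from CSV
#'
#' Expects a header `year,month,value`; empty cells or a literal `NA`
#' (case-insensitive) mark missing observations. Rows are sorted into
#' calendar order; duplicates and non-positive abundances are rejected.
#'
#' @param path path to a CSV file.
#' @inheritParams monitoring_series
#' @return A [monitoring_series()].
#' @export
read_series <- function(path, lake = "unknown",
                        variable = c("phytoplankton", "zooplankton",
                                     "temperature"),
                        units = "") {
  variable <- match.arg(variable)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(), strip.white = TRUE)
  need <- c("year", "month", "value")
  if (!all(need %in% names(raw)))
    stop("CSV must have header columns year, month, value: ", path,
         call. = FALSE)
  parse_num <- function(s, col) {
    miss <- s == "" | toupper(s) == "NA"
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & !miss)
    if (length(bad))
      stop(sprintf("unparseable %s at data row %d of %s", col, bad[1], path),
           call. = FALSE)
    v
  }
  year <- parse_num(raw$year, "year")
  month <- parse_num(raw$month, "month")
  if (anyNA(year) || anyNA(month))
    stop("year/month cells must not be missing: ", path, call. = FALSE)
  value <- parse_num(raw$value, "value")
  monitoring_series(year, month, value, lake = lake, variable = variable,
                    units = units)
}

#' Write a monitoring or derived series to CSV
#'
#' Round-trips with [read_series()]: values, missing flags (`NA` cells) and
#' order are preserved. Derived series gain a `run_id` column identifying
#' the season run each value belongs to.
#'
#' @param x a `monitoring_series` or `derived_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Season runs of a monthly series
#'
#' A season run is a maximal block of consecutive calendar months present in
#' the record. Runs are separated by gaps of one calendar month or more
#' (typically the unsampled winter). Every sample belongs to exactly one run.
#'
#' @param x a `monitoring_series` (or any data frame with `year`, `month`).
#' @return A data frame with columns `run_id`, `start`, `end` (1-based sample
#'   positions, inclusive) and `length`.
#' @examples
#' x <- monitoring_series(rep(2001:2002, each = 3), rep(5:7, 2), 1:6,
#'                        variable = "temperature")
#' season_runs(x)
#' @export
season_runs <- function(x) {
  if (nrow(x) == 0L) stop("empty series", call. = FALSE)
  mi <- month_index(x$year, x$month)
  new_run <- c(TRUE, diff(mi) != 1L)
  run_id <- cumsum(new_run)
  start <- which(new_run)
  end <- c(start[-1] - 1L, length(mi))
  data.frame(run_id = seq_along(start), start = start, end = end,
             length = end - start + 1L)
}

# per-sample run id vector
run_ids <- function(x) {
  r <- season_runs(x)
  rep.int(r$run_id, r$length)
}

#' Align two monthly series on their common timestamps
#'
#' Restricts both series to the (year, month) pairs present in both, in
#' calendar order. Downstream phase comparison requires a shared timeline.
#'
#' @param a,b `monitoring_series` objects.
#' @return A list with elements `a` and `b`, equal-length aligned series.
#' @export
align_series <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty series", call. = FALSE)
  mi_a <- month_index(a$year, a$month)
  mi_b <- month_index(b$year, b$month)
  common <- intersect(mi_a, mi_b)
  if (length(common) == 0L)
    stop("series have no common (year, month) timestamps", call. = FALSE)
  keep_attrs <- function(x, idx) {
    out <- x[idx, , drop = FALSE]
    rownames(out) <- NULL
    attributes(out) <- c(attributes(out)[c("names", "row.names")],
                         attributes(x)[c("lake", "variable", "units")],
                         list(class = class(x)))
    out
  }
  list(a = keep_attrs(a, match(common, mi_a)),
       b = keep_attrs(b, match(common, mi_b)))
}

#' @export
print.monitoring_series <- function(x, ...) {
  cat(sprintf("Monitoring series: %s, lake %s (%d samples, %d missing, %d season runs)\n",
              series_variable(x), series_lake(x), nrow(x),
              sum(is.na(x$value)), nrow(season_runs(x))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.monitoring_series <- function(x, ...,
                                   xlab = "sample index",
                                   ylab = series_variable(x),
                                   type = "o", pch = 16, cex = 0.6) {
  idx <- seq_len(nrow(x))
  rid <- run_ids(x)
  graphics::plot(idx, x$value, type = "n", xlab = xlab, ylab = ylab, ...)
  for (r in unique(rid)) {
    sel <- rid == r
    graphics::lines(idx[sel], x$value[sel], type = type, pch = pch, cex = cex)
  }
  invisible(x)
}
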