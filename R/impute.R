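#' Season-split missing-value imputation
#'
#' Fills missing values by splitting the monthly series into calendar-month
#' slices (all Mays form one sub-series, all Junes another, ...) and
#' interpolating linearly across years within each slice. A missing value
#' before the first or after the last observation of its slice is filled
#' with that nearest observed value (constant extrapolation). Observed
#' values are never modified, so the operation is idempotent, and every
#' imputed value lies within the observed range of its own month slice.
#'
#' This is the standard season-split reading of interpolation-based
#' imputation for monthly monitoring data: the seasonal cycle is so strong
#' that interpolating within a calendar month across years is far safer than
#' interpolating across adjacent months.
#'
#' @param x a `monitoring_series`, possibly with `NA` values.
#' @return The same series with all `NA` values filled.
#' @examples
#' x <- monitoring_series(2001:2003, 6, c(4, NA, 6), variable = "temperature")
#' impute_seasonal(x)$value  # June of 2002 becomes 5
#' @export
impute_seasonal <- function(x) {
  stopifnot(inherits(x, "monitoring_series"))
  if (!anyNA(x$value)) return(x)
  val <- x$value
  for (m in sort(unique(x$month[is.na(val)]))) {
    sel <- which(x$month == m)
    obs <- !is.na(val[sel])
    if (!any(obs))
      stop(sprintf("cannot impute: all values missing for calendar month %d", m),
           call. = FALSE)
    if (sum(obs) == 1L) {
      val[sel][!obs] <- val[sel][obs]
    } else {
      # x-axis is calendar year within the slice; rule = 2 gives the
      # nearest-observed-value edge fill
      val[sel][!obs] <- stats::approx(x$year[sel][obs], val[sel][obs],
                                      xout = x$year[sel][!obs],
                                      rule = 2)$y
    }
  }
  x$value <- val
  x
}
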