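#' Prey-predator model constants
#'
#' The discrete prey-predator model behind the inversion has two constants:
#' `alpha`, the intensity of the decline in predator (zooplankton) abundance
#' unrelated to trophic interactions, in month^-1; and `beta`, the efficiency
#' of converting consumed prey (phytoplankton) into predator abundance.
#' Trophic-transfer efficiency arguments (Lindeman's 10 % law) put `beta`
#' near 0.1; `alpha` values consistent with lake monitoring lie in [0, 20].
#' Both bounds are validation defaults and configurable.
#'
#' @param alpha predator decline intensity, month^-1; must lie in
#'   `[0, alpha_max]`.
#' @param beta prey-to-predator conversion efficiency, dimensionless, > 0.
#' @param alpha_max upper validation bound for `alpha` (default 20).
#' @return An object of class `kdd_params`.
#' @export
kdd_params <- function(alpha, beta = 0.1, alpha_max = 20) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > alpha_max)
    stop(sprintf("alpha must be a single value in [0, %g]", alpha_max),
         call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("beta must be a single positive value", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "kdd_params")
}

#' @export
print.kdd_params <- function(x, ...) {
  cat(sprintf("KDD model constants: alpha = %g month^-1, beta = %g\n",
              x$alpha, x$beta))
  invisible(x)
}

# shared validation for the two inversions; returns the valid step indices
# (those whose successor lies in the same season run) and run ids
check_inversion_inputs <- function(P, Z) {
  if (nrow(P) != nrow(Z) ||
      !all(P$year == Z$year & P$month == Z$month))
    stop("P and Z must be aligned on identical (year, month) timelines",
         call. = FALSE)
  if (anyNA(P$value) || anyNA(Z$value))
    stop("P and Z must be fully observed (impute first)", call. = FALSE)
  rid <- run_ids(P)
  n <- nrow(P)
  valid <- which(seq_len(n) < n & rid == c(rid[-1], NA_integer_)[seq_len(n)])
  list(valid = valid, rid = rid)
}

new_derived_series <- function(P, valid, rid, value, variable, params) {
  structure(
    data.frame(year = P$year[valid], month = P$month[valid],
               value = value, run_id = rid[valid]),
    lake = series_lake(P), variable = variable,
    alpha = params$alpha, beta = params$beta,
    class = c("derived_series", "data.frame"))
}

#' Recover the phytoplankton growth-rate series by model inversion
#'
#' Inverts the discrete prey-predator model
#' \deqn{\Delta P(n)/P(n) = G(n) - f(n)Z(n), \quad
#'       \Delta Z(n)/Z(n) = \beta f(n) P(n) - \alpha}
#' for the intrinsic prey growth rate, giving
#' \deqn{G(n) = \frac{\beta\,\Delta P(n) + \Delta Z(n) + \alpha Z(n)}
#'                   {\beta\,P(n)}}
#' with \eqn{\Delta P(n) = P(n+1) - P(n)} and
#' \eqn{\Delta Z(n) = Z(n+1) - Z(n)} over one-month steps. The monitoring
#' series are inserted directly into the model equations, so the unknown
#' functional term is obtained as a time series rather than assumed
#' analytically. Steps that straddle a winter gap (the last sample of each
#' season run) carry no derived value: the time step between the end of one
#' season and the beginning of the next is excluded, not bridged. G(n) may
#' be negative; no clipping is applied.
#'
#' @param P phytoplankton `monitoring_series`, fully observed, all values > 0.
#' @param Z zooplankton `monitoring_series`, aligned with `P`.
#' @param params a [kdd_params()] object.
#' @return A `derived_series` (data frame with `year`, `month`, `value`,
#'   `run_id`) holding G(n) on the valid within-season index set.
#' @examples
#' P <- monitoring_series(2001, 5:6, c(10, 12), variable = "phytoplankton")
#' Z <- monitoring_series(2001, 5:6, c(5, 5), variable = "zooplankton")
#' growth_rate(P, Z, kdd_params(alpha = 0, beta = 0.1))$value  # 0.2
#' @export
growth_rate <- function(P, Z, params) {
  stopifnot(inherits(params, "kdd_params"))
  chk <- check_inversion_inputs(P, Z)
  if (any(P$value <= 0))
    stop("all P(n) must be > 0 (they divide the inversion)", call. = FALSE)
  v <- chk$valid
  dP <- P$value[v + 1L] - P$value[v]
  dZ <- Z$value[v + 1L] - Z$value[v]
  g <- (params$beta * dP + dZ + params$alpha * Z$value[v]) /
    (params$beta * P$value[v])
  new_derived_series(P, v, chk$rid, g, "G", params)
}

#' Recover the trophic-function series by model inversion
#'
#' Rearranges the predator equation of the discrete prey-predator model to
#' \deqn{f(n) = \frac{\Delta Z(n)/Z(n) + \alpha}{\beta\,P(n)}}
#' giving the predation-intensity function on the same valid within-season
#' index set as [growth_rate()].
#'
#' @inheritParams growth_rate
#' @return A `derived_series` holding f(n).
#' @export
trophic_function <- function(P, Z, params) {
  stopifnot(inherits(params, "kdd_params"))
  chk <- check_inversion_inputs(P, Z)
  if (any(P$value <= 0))
    stop("all P(n) must be > 0", call. = FALSE)
  if (any(Z$value <= 0))
    stop("all Z(n) must be > 0 (they divide the trophic inversion)",
         call. = FALSE)
  v <- chk$valid
  dZ <- Z$value[v + 1L] - Z$value[v]
  f <- (dZ / Z$value[v] + params$alpha) / (params$beta * P$value[v])
  new_derived_series(P, v, chk$rid, f, "f", params)
}

#' @export
print.derived_series <- function(x, ...) {
  cat(sprintf(
    "Derived series %s(n): %d valid steps in %d season runs (alpha = %g, beta = %g)\n",
    series_variable(x), nrow(x), length(unique(x$run_id)),
    attr(x, "alpha"), attr(x, "beta")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.derived_series <- function(x, ...,
                                xlab = "step n",
                                ylab = paste0(series_variable(x), "(n)")) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$value, type = "n", xlab = xlab, ylab = ylab, ...)
  for (r in unique(x$run_id)) {
    sel <- x$run_id == r
    graphics::lines(idx[sel], x$value[sel], type = "o", pch = 16, cex = 0.6)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
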