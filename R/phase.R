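#' Detect oscillation maxima
#'
#' A sample `i` is a maximum iff `x[i] > x[i-1]` and `x[i] >= x[i+1]`; on a
#' plateau the first plateau index wins, and endpoints are never maxima.
#' This is the simplest deterministic rule; it is stated explicitly so that
#' reproduction differences are attributable to it.
#'
#' @param x numeric sequence, length >= 3.
#' @return Integer indices of the maxima, increasing.
#' @examples
#' detect_maxima(c(0, 1, 0, 2, 0))  # 2, 4
#' @export
detect_maxima <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  i <- 2:(length(x) - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

#' Phase-series constructor
#'
#' Low-level constructor for an unwrapped phase series on an integer index
#' domain; normally produced by [phase()].
#'
#' @param index integer sample indices on which the phase is defined.
#' @param phi unwrapped phase in radians at each index.
#' @param maxima indices of the detected maxima (may be empty for manually
#'   built series).
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(index, phi, maxima = integer()) {
  stopifnot(length(index) == length(phi))
  structure(list(index = as.integer(index), phi = as.numeric(phi),
                 maxima = as.integer(maxima)),
            class = "phase_series")
}

#' Oscillation phase from detected maxima
#'
#' Between consecutive maxima \eqn{t_k \le t \le t_{k+1}} the unwrapped
#' phase is
#' \deqn{\varphi(t) = 2\pi\left(m + \frac{t - t_k}{t_{k+1} - t_k}\right)}
#' where \eqn{m} counts completed cycles from 0 at the first maximum. The
#' phase is defined only on the index interval spanned by the first and last
#' maxima, advances exactly \eqn{2\pi} per maximum-to-maximum cycle, and is
#' linear in the sample index between maxima. The sample index is treated as
#' equally spaced time (one month per step within a season; concatenated
#' runs), matching the step-number axes of the monitoring record.
#'
#' @param x numeric sequence.
#' @param maxima maxima indices; defaults to [detect_maxima()] on `x`.
#' @return A [phase_series()] on `[min(maxima), max(maxima)]`.
#' @examples
#' ph <- phase(rep(c(0, 1), 6))
#' ph$phi[ph$index %in% ph$maxima] / (2 * pi)  # 0, 1, 2, ...
#' @export
phase <- function(x, maxima = detect_maxima(x)) {
  if (length(maxima) < 2L)
    stop("phase undefined: fewer than 2 maxima detected", call. = FALSE)
  idx <- maxima[1L]:maxima[length(maxima)]
  phi <- stats::approx(maxima, 2 * pi * (seq_along(maxima) - 1L),
                       xout = idx)$y
  phase_series(idx, phi, maxima)
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series: %d maxima, domain [%d, %d], %.2f cycles\n",
              length(x$maxima), min(x$index), max(x$index),
              (max(x$phi) - min(x$phi)) / (2 * pi)))
  invisible(x)
}

#' Phase-locking index of two phase series
#'
#' The phase-locking index is the modulus of the mean unit phasor of the
#' phase differences,
#' \deqn{PLI = \left|\frac{1}{N}\sum_{j=0}^{N-1} e^{i\Delta\varphi(j)}\right|}
#' over the N indices common to both phase domains. PLI lies in [0, 1]:
#' 0 for uniformly distributed phase differences (no synchronization), 1 iff
#' the phase difference is constant modulo \eqn{2\pi} (strict phase
#' synchronization). The difference of unwrapped phases is used directly;
#' the phasor makes any modular reduction immaterial.
#'
#' @param phi_a,phi_b [phase_series()] objects.
#' @return A list with elements `pli` and `n_points`.
#' @examples
#' a <- phase_series(1:4, c(0, 1, 2, 3))
#' pli(a, a)$pli  # 1
#' @export
pli <- function(phi_a, phi_b) {
  stopifnot(inherits(phi_a, "phase_series"), inherits(phi_b, "phase_series"))
  common <- intersect(phi_a$index, phi_b$index)
  if (length(common) == 0L)
    stop("synchronization undefined: phase domains do not overlap",
         call. = FALSE)
  dphi <- phi_a$phi[match(common, phi_a$index)] -
    phi_b$phi[match(common, phi_b$index)]
  list(pli = Mod(mean(exp(1i * dphi))), n_points = length(common))
}

#' Phase-locking index of two raw sequences
#'
#' Convenience composition: detect maxima on each sequence, build the
#' between-maxima interpolated phases, and compute the phase-locking index
#' on the common phase domain.
#'
#' @param a,b numeric sequences on a shared sample-index timeline.
#' @return A list with elements `pli` and `n_points`.
#' @export
pli_pipeline <- function(a, b) {
  pli(phase(a), phase(b))
}

#' Shuffle-surrogate significance test for phase locking
#'
#' Computes the observed phase-locking index of `a` and `b`, then builds a
#' null distribution by randomly shuffling the values of the series
#' (`n_surrogates` times) and re-running the full pipeline — maxima
#' detection, phase interpolation, PLI — on each shuffled pair. Shuffling
#' destroys the temporal ordering and hence any real phase relation while
#' preserving the value distribution; chance alignments keep the surrogate
#' PLIs above zero. The significance is the percentage of surrogate PLIs
#' strictly below the observed PLI; `p >= 95` is conventionally read as
#' phase-synchronized. Surrogates on which a phase cannot be defined (fewer
#' than 2 maxima after shuffling) are re-drawn and counted in `n_redraws`.
#' With a fixed `seed` the result is bit-reproducible.
#'
#' @param a,b numeric sequences on a shared sample-index timeline.
#' @param n_surrogates number of shuffled surrogate pairs (default 1000).
#' @param seed RNG seed; `NULL` leaves the global RNG state in charge.
#' @param shuffle `"both"` (default) shuffles both series independently in
#'   each surrogate; `"first"` shuffles only `a` and keeps `b` fixed.
#' @return An object of class `pli_test` with fields `pli`, `n_points`,
#'   `surrogate_plis`, `significance` (percent), `n_surrogates`, `n_redraws`,
#'   `seed`, `shuffle`.
#' @examples
#' x <- sin(2 * pi * (1:48) / 12)
#' st <- surrogate_test(x, x, n_surrogates = 99, seed = 1)
#' st$significance
#' @export
surrogate_test <- function(a, b, n_surrogates = 1000, seed = NULL,
                           shuffle = c("both", "first")) {
  shuffle <- match.arg(shuffle)
  obs <- pli_pipeline(a, b)
  if (!is.null(seed)) set.seed(seed)
  phi_b_fixed <- if (shuffle == "first") phase(b)
  surr <- numeric(n_surrogates)
  redraws <- 0L
  for (k in seq_len(n_surrogates)) {
    repeat {
      res <- tryCatch({
        phi_a <- phase(sample(a))
        phi_b <- if (shuffle == "both") phase(sample(b)) else phi_b_fixed
        pli(phi_a, phi_b)$pli
      }, error = function(e) NULL)
      if (!is.null(res)) break
      redraws <- redraws + 1L
    }
    surr[k] <- res
  }
  structure(list(
    pli = obs$pli, n_points = obs$n_points,
    surrogate_plis = surr,
    significance = 100 * sum(surr < obs$pli) / n_surrogates,
    n_surrogates = n_surrogates, n_redraws = redraws,
    seed = seed, shuffle = shuffle),
    class = "pli_test")
}

#' @export
print.pli_test <- function(x, ...) {
  cat("\tPhase-locking index with shuffle-surrogate test\n\n")
  cat(sprintf("PLI = %.4f over N = %d common indices\n", x$pli, x$n_points))
  cat(sprintf("significance p = %.1f%% (%d surrogates, shuffle = %s%s)\n",
              x$significance, x$n_surrogates, x$shuffle,
              if (x$n_redraws > 0) sprintf(", %d re-draws", x$n_redraws)
              else ""))
  cat(sprintf("surrogate PLI: min %.4f, median %.4f, max %.4f\n",
              min(x$surrogate_plis), stats::median(x$surrogate_plis),
              max(x$surrogate_plis)))
  cat(if (x$significance >= 95)
    "verdict: phase-synchronized (p >= 95%)\n"
    else "verdict: not phase-synchronized (p < 95%)\n")
  invisible(x)
}

#' @export
summary.pli_test <- function(object, ...) {
  c(pli = object$pli, n_points = object$n_points,
    p = object$significance,
    surrogate_median = stats::median(object$surrogate_plis))
}

#' @export
plot.pli_test <- function(x, ..., breaks = 30,
                          main = "Surrogate PLI distribution",
                          xlab = "PLI") {
  graphics::hist(x$surrogate_plis, breaks = breaks, main = main,
                 xlab = xlab, ...)
  graphics::abline(v = x$pli, lwd = 2)
  graphics::mtext(sprintf("observed PLI = %.3f, p = %.1f%%",
                          x$pli, x$significance), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Thin wrapper around the standard non-parametric (Spearman) correlation
#' with a two-sided p-value, used alongside the phase analysis to check for
#' monotone amplitude association.
#'
#' @param a,b equal-length numeric sequences, length >= 3, non-constant.
#' @return A list with elements `rho` and `p_value`.
#' @export
rank_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need two equal-length sequences of length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
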