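# Replication kinetics: Boltzmann sigmoid fits and bulk flow-cytometry
# replication measures.

#' Fit a Boltzmann sigmoid
#'
#' Least-squares fit of `y = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))`, the
#' standard model for a locus's replicated fraction (or copy number) through
#' a synchronized S phase. `x0` is the midpoint — the median replication
#' time Trep when `x` is time. The model has two sign-equivalent
#' parameterizations (swapping the plateaus and negating `dx` gives the
#' same curve); the fit is canonicalised post-fit to `dx > 0`, so `A1` is
#' always the plateau approached at small `x` and the curve is
#' non-decreasing exactly when `A1 < A2` (rising replication data: `A1`
#' near 1, `A2` near 2).
#'
#' Initialisation: `A1` and `A2` at the observed extremes oriented by the
#' sign of the overall trend, `x0` at the point closest to mid-range,
#' `dx = (range of x)/10`. Fitting uses Levenberg-Marquardt least squares.
#'
#' @param x,y numeric vectors (>= 5 points; y must span a nonzero range).
#' @return A list of class `boltzmann_fit` with elements `A1`, `A2`, `x0`,
#'   `dx`, `rss`, `converged`, and `fitted`.
#' @examples
#' x <- seq(0, 60, 2)
#' y <- 2 + (1 - 2) / (1 + exp((x - 30) / -4))
#' fit_boltzmann(x, y)$x0
#' @export
fit_boltzmann <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need >= 5 points")
  yr <- diff(range(y))
  if (yr < 1e-9 * max(abs(mean(y)), 1e-12)) {
    stop("degenerate data: y is flat")
  }
  rising <- y[which.max(x)] >= y[which.min(x)]
  start <- list(
    A1 = if (rising) min(y) else max(y),
    A2 = if (rising) max(y) else min(y),
    x0 = x[which.min(abs(y - (min(y) + max(y)) / 2))],
    dx = diff(range(x)) / 10
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e))
  )
  cf <- as.list(stats::coef(fit))
  # collapse the sign-equivalent parameterization to dx > 0, so A1 is the
  # plateau approached at x -> -Inf
  if (cf$dx < 0) {
    cf <- list(A1 = cf$A2, A2 = cf$A1, x0 = cf$x0, dx = -cf$dx)
  }
  structure(list(
    A1 = cf$A1, A2 = cf$A2, x0 = cf$x0, dx = cf$dx,
    rss = sum(stats::resid(fit)^2),
    converged = fit$convInfo$isConv %||% TRUE,
    fitted = boltzmann_curve(x, cf$A1, cf$A2, cf$x0, cf$dx)
  ), class = "boltzmann_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a Boltzmann sigmoid
#'
#' @param x positions/times at which to evaluate.
#' @param A1,A2,x0,dx sigmoid parameters (see [fit_boltzmann()]).
#' @return Numeric vector of curve values.
#' @export
boltzmann_curve <- function(x, A1, A2, x0, dx) {
  A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
}

#' Median replication time of a fitted locus
#'
#' Returns the sigmoid midpoint `x0`, the time at which half the population
#' has replicated the locus (Trep). Invariant under affine rescaling of the
#' y axis.
#'
#' @param fit a converged [fit_boltzmann()] result.
#' @return Trep in the units of `x`.
#' @export
trep_of <- function(fit) {
  if (!inherits(fit, "boltzmann_fit")) stop("not a boltzmann_fit")
  if (!isTRUE(fit$converged)) stop("fit did not converge; Trep undefined")
  fit$x0
}

#' Bulk genome replication from flow-cytometry medians
#'
#' Normalizes per-sample median (or mean) DNA-content signals to the
#' arrested (G1) sample and stretches the observed dynamic range linearly
#' onto the 1..2 copy scale (linear contrast stretching), so that
#' `fraction_replicated = stretched - 1` runs from exactly 0 to exactly 1
#' across the course. A Boltzmann sigmoid is fitted over (time, stretched)
#' and attached for interpolation.
#'
#' @param time numeric vector of sample times (minutes after release).
#' @param median_signal per-sample DNA-content medians, same length.
#' @param arrested_signal signal of the arrested (G1) reference sample.
#' @param sample_id optional sample labels.
#' @return A data frame with `sample_id`, `time`, `median_signal`,
#'   `stretched`, `fraction_replicated`, plus the fit in
#'   `attr(, "boltzmann")` (NULL if the course is too short to fit).
#' @examples
#' bulk_replication_from_fc(c(0, 10, 20, 30), c(100, 100, 150, 200), 100)
#' @export
bulk_replication_from_fc <- function(time, median_signal, arrested_signal,
                                     sample_id = NULL) {
  if (arrested_signal <= 0) stop("arrested_signal must be positive")
  stopifnot(length(time) == length(median_signal))
  norm <- median_signal / arrested_signal
  rng <- range(norm)
  if (diff(rng) <= 0) stop("zero dynamic range after normalization")
  stretched <- 1 + (norm - rng[1]) / (rng[2] - rng[1])
  out <- data.frame(
    sample_id = if (is.null(sample_id)) paste0("t", time) else sample_id,
    time = time, median_signal = median_signal,
    stretched = stretched, fraction_replicated = stretched - 1,
    stringsAsFactors = FALSE
  )
  fit <- if (length(time) >= 5) {
    tryCatch(fit_boltzmann(time, stretched), error = function(e) NULL)
  }
  attr(out, "boltzmann") <- fit
  out
}

#' Select the sample closest to a target bulk-replication fraction
#'
#' Picks the sample whose replicated fraction is nearest the target (e.g.
#' 0.55 for a mid-S sample). The fitted Boltzmann curve is used when
#' available, otherwise the observed stretched fractions; ties break toward
#' the earlier time.
#'
#' @param bulk output of [bulk_replication_from_fc()].
#' @param target_fraction desired replicated fraction in 0..1.
#' @return The selected `sample_id`.
#' @export
select_sample_by_replication <- function(bulk, target_fraction) {
  if (nrow(bulk) == 0) stop("empty bulk series")
  fit <- attr(bulk, "boltzmann")
  frac <- if (!is.null(fit)) {
    boltzmann_curve(bulk$time, fit$A1, fit$A2, fit$x0, fit$dx) - 1
  } else {
    bulk$fraction_replicated
  }
  dev <- abs(frac - target_fraction)
  bulk$sample_id[order(dev, bulk$time)][1]
}
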