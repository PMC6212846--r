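# Poisson quantification of droplet digital PCR wells.
#
# A well partitions the template into ~20,000 droplets of ~1 nl; end-point
# PCR scores each droplet positive or negative. The positive fraction p
# estimates the mean occupancy lambda (copies per droplet) through
# lambda = -log(1 - p), and concentration = lambda / droplet volume.

#' Construct a droplet-count record
#'
#' One ddPCR well: the number of positive droplets out of the total, for a
#' given probe, sample and replicate, at a known droplet volume.
#'
#' @param probe_id,sample_id,replicate_id identifiers (coerced to character).
#' @param n_positive number of positive droplets.
#' @param n_total total number of accepted droplets (> 0).
#' @param droplet_volume_nl droplet volume in nanolitres (default 1).
#' @return A one-row data frame of class `droplet_count`.
#' @examples
#' droplet_count("ARS607.L2", "S1", "r1", 12642, 20000)
#' @export
droplet_count <- function(probe_id, sample_id = "sample", replicate_id = "r1",
                          n_positive, n_total, droplet_volume_nl = 1) {
  n <- max(length(probe_id), length(sample_id), length(replicate_id),
           length(n_positive), length(n_total), length(droplet_volume_nl))
  probe_id <- rep_len(probe_id, n); sample_id <- rep_len(sample_id, n)
  replicate_id <- rep_len(replicate_id, n)
  n_positive <- rep_len(n_positive, n); n_total <- rep_len(n_total, n)
  droplet_volume_nl <- rep_len(droplet_volume_nl, n)
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_positive < 0 | n_positive > n_total)) {
    stop("n_positive must satisfy 0 <= n_positive <= n_total")
  }
  if (any(droplet_volume_nl <= 0)) stop("droplet_volume_nl must be positive")
  out <- data.frame(
    probe_id = as.character(probe_id),
    sample_id = as.character(sample_id),
    replicate_id = as.character(replicate_id),
    n_positive = as.numeric(n_positive),
    n_total = as.numeric(n_total),
    droplet_volume_nl = as.numeric(droplet_volume_nl),
    stringsAsFactors = FALSE
  )
  class(out) <- c("droplet_count", class(out))
  out
}

#' Estimate template concentration from a droplet count
#'
#' Inverts the Poisson partitioning model: with positive fraction
#' `p = n_positive / n_total`, the mean occupancy is
#' `lambda = -log(1 - p)` copies per droplet and the concentration is
#' `lambda / v` with `v` the droplet volume in microlitres. The confidence
#' interval is the delta-method interval of [concentration_ci()] and the
#' CV is the analytic [cv_of_estimator()] value at the estimated occupancy.
#'
#' Saturated wells (all droplets positive) are unquantifiable and raise an
#' error: the sample must be diluted and re-run.
#'
#' @param count a `droplet_count` row (or data frame with the same columns).
#' @param level confidence level for the per-well interval.
#' @return A data frame with columns `probe_id`, `sample_id`, `replicate_id`,
#'   `occupancy_lambda` (copies/droplet), `concentration`, `ci_low`,
#'   `ci_high` (copies/microlitre) and `cv`.
#' @examples
#' estimate_concentration(droplet_count("p", n_positive = 12642, n_total = 20000))
#' @export
estimate_concentration <- function(count, level = 0.95) {
  p <- count$n_positive / count$n_total
  if (any(p >= 1)) {
    stop("saturated well (all droplets positive): concentration is ",
         "unquantifiable; dilute the sample")
  }
  lambda <- -log1p(-p)
  vol_ul <- count$droplet_volume_nl * 1e-3
  conc <- lambda / vol_ul
  ci <- concentration_ci_values(p, count$n_total, vol_ul, level)
  cv <- ifelse(lambda > 0,
               sqrt(p / ((1 - p) * count$n_total)) / lambda, NA_real_)
  data.frame(
    probe_id = count$probe_id,
    sample_id = count$sample_id,
    replicate_id = count$replicate_id,
    occupancy_lambda = lambda,
    concentration = conc,
    ci_low = ci$low,
    ci_high = ci$high,
    cv = cv,
    stringsAsFactors = FALSE
  )
}

# shared delta-method interval on the lambda scale, converted to copies/ul
concentration_ci_values <- function(p, n_total, vol_ul, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd_lambda <- sqrt(p / ((1 - p) * n_total))
  lambda <- -log1p(-p)
  list(low = pmax(0, (lambda - z * sd_lambda)) / vol_ul,
       high = (lambda + z * sd_lambda) / vol_ul)
}

#' Per-well confidence interval for a droplet-based concentration
#'
#' Delta-method interval: `sd(lambda_hat) = sqrt(p / (n (1 - p)))` with
#' normal quantiles, symmetric about the estimate and clipped at zero,
#' reported in copies per microlitre.
#'
#' @inheritParams estimate_concentration
#' @return A data frame with `concentration`, `ci_low`, `ci_high`,
#'   `half_width_lambda` (half-width on the copies/droplet scale).
#' @export
concentration_ci <- function(count, level = 0.95) {
  if (any(count$n_positive <= 0) || any(count$n_positive >= count$n_total)) {
    stop("concentration_ci requires 0 < n_positive < n_total")
  }
  p <- count$n_positive / count$n_total
  vol_ul <- count$droplet_volume_nl * 1e-3
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd_lambda <- sqrt(p / ((1 - p) * count$n_total))
  ci <- concentration_ci_values(p, count$n_total, vol_ul, level)
  data.frame(
    concentration = -log1p(-p) / vol_ul,
    ci_low = ci$low,
    ci_high = ci$high,
    half_width_lambda = z * sd_lambda
  )
}

#' Replicate-based mean concentration and confidence interval
#'
#' Mean over technical replicates with a Student-t interval on n - 1
#' degrees of freedom, the convention used for replicate error bars
#' (two replicates are allowed and use t with 1 df).
#'
#' @param concentrations numeric vector of per-replicate concentrations
#'   (copies/microlitre), or a data frame from [estimate_concentration()]
#'   with a `concentration` column.
#' @param level confidence level.
#' @return A one-row data frame with `mean`, `ci_low`, `ci_high`, `n`, `sem`.
#' @examples
#' replicate_ci(c(990, 1000, 1010))
#' @export
replicate_ci <- function(concentrations, level = 0.95) {
  x <- if (is.data.frame(concentrations)) concentrations$concentration
       else concentrations
  n <- length(x)
  if (n < 2) {
    stop("need >= 2 replicates; use concentration_ci for a single well")
  }
  m <- mean(x)
  sem <- stats::sd(x) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  data.frame(mean = m, ci_low = m - tq * sem, ci_high = m + tq * sem,
             n = n, sem = sem)
}

#' Pool technical-replicate wells before Poisson correction
#'
#' Sums positive and total droplet counts across wells of the same probe,
#' sample and droplet volume, so the pooled well is quantified as one large
#' partition set. Source replicate ids are retained in `replicate_id`.
#'
#' @param counts a `droplet_count` data frame with >= 1 row.
#' @return A one-row `droplet_count`.
#' @export
merge_technical_replicates <- function(counts) {
  if (nrow(counts) == 0) stop("no wells to merge")
  if (length(unique(counts$probe_id)) != 1 ||
      length(unique(counts$sample_id)) != 1 ||
      length(unique(counts$droplet_volume_nl)) != 1) {
    stop("wells must share probe, sample and droplet volume")
  }
  droplet_count(
    probe_id = counts$probe_id[1],
    sample_id = counts$sample_id[1],
    replicate_id = paste(counts$replicate_id, collapse = "+"),
    n_positive = sum(counts$n_positive),
    n_total = sum(counts$n_total),
    droplet_volume_nl = counts$droplet_volume_nl[1]
  )
}

#' Analytic coefficient of variation of the occupancy estimator
#'
#' Delta-method CV of `lambda_hat = -log(1 - p_hat)` for a well of
#' `n_droplets` droplets at true occupancy `lambda`:
#' `cv = sqrt(p / ((1 - p) n)) / lambda` with `p = 1 - exp(-lambda)`.
#' The CV is U-shaped in lambda: subsampling error dominates at low
#' occupancy and partitioning error at high occupancy, with a minimum at
#' intermediate occupancy (~1.6 copies/droplet).
#'
#' @param occupancy_lambda true mean copies per droplet (> 0); vectorised.
#' @param n_droplets droplets per well.
#' @return CV as a dimensionless fraction.
#' @examples
#' cv_of_estimator(1, 20000)     # ~0.93%
#' cv_of_estimator(0.11, 20000)  # ~2.2%, the low end of the usable range
#' @export
cv_of_estimator <- function(occupancy_lambda, n_droplets = 20000) {
  if (any(occupancy_lambda <= 0)) stop("occupancy_lambda must be positive")
  if (any(n_droplets <= 0)) stop("n_droplets must be positive")
  p <- -expm1(-occupancy_lambda)
  sqrt(p / ((1 - p) * n_droplets)) / occupancy_lambda
}
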