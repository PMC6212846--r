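# Sort-seq: relative copy number from binned replicating / non-replicating
# read counts, unit-range adjustment, smoothing and comparison with probes.

#' Assemble binned replicating/non-replicating counts
#'
#' @param chrom,start,end per-bin interval (0-based half-open; uniform
#'   width within a profile).
#' @param rep,nonRep read counts per bin from the replicating and the
#'   non-replicating sample.
#' @return A data frame of class `binned_counts`.
#' @export
binned_counts <- function(chrom, start, end, rep, nonRep) {
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), rep = as.numeric(rep),
                    nonRep = as.numeric(nonRep), stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("start must be < end")
  if (any(out$rep < 0) || any(out$nonRep < 0)) stop("counts must be >= 0")
  class(out) <- c("binned_counts", class(out))
  out
}

#' Depth-normalized per-bin replication ratio
#'
#' For each bin, `r = (rep / nonRep) * (nonRepSum / repSum)`, where the sums
#' run over included bins; the ratio is invariant to the global sequencing
#' depth of either sample. Bins whose non-replicating count falls below
#' `min_nonrep` reads are excluded (their ratios would be dominated by
#' shot noise or undefined) and recorded with a reason.
#'
#' @param counts a [binned_counts()] data frame.
#' @param min_nonrep minimum non-replicating reads for a bin to be included.
#' @return A data frame with the bin columns plus `raw_ratio`; excluded bins
#'   in `attr(, "excluded")`; totals in `attr(, "sums")`.
#' @export
compute_ratio <- function(counts, min_nonrep = 1) {
  keep <- counts$nonRep >= min_nonrep
  if (!any(keep)) stop("all bins excluded (non-replicating counts too low)")
  excluded <- counts[!keep, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(excluded)) excluded$reason <- sprintf("nonRep < %g", min_nonrep)
  inc <- counts[keep, , drop = FALSE]
  rep_sum <- sum(inc$rep)
  nonrep_sum <- sum(inc$nonRep)
  inc$raw_ratio <- (inc$rep / inc$nonRep) * (nonrep_sum / rep_sum)
  out <- inc
  attr(out, "excluded") <- excluded
  attr(out, "sums") <- c(repSum = rep_sum, nonRepSum = nonrep_sum)
  class(out) <- c("ratio_profile", "data.frame")
  out
}

#' Adjust a ratio profile onto the 1..2 replication range
#'
#' Replication copy number lies between 1 and 2, but the depth-normalized
#' ratio is centred on its genome-wide mean; a single multiplicative factor
#' `f` is chosen to minimize the summed exceedance outside the range:
#' `f* = argmin_f sum_i [max(0, 1 - f r_i) + max(0, f r_i - 2)]`.
#'
#' The objective is convex and piecewise linear in `f` with breakpoints at
#' `1 / r_i` and `2 / r_i`, so it is minimized exactly by enumerating the
#' breakpoints; when the minimizing set is an interval, the factor closest
#' to 1 is returned (in particular `f = 1` whenever the profile is already
#' within range).
#'
#' @param profile output of [compute_ratio()] (or a data frame with a
#'   `raw_ratio` column).
#' @return The profile with an `adjusted_ratio` column; the factor in
#'   `attr(, "adjustment_factor")` and the attained objective in
#'   `attr(, "objective")`.
#' @export
adjust_to_unit_range <- function(profile) {
  r <- profile$raw_ratio
  r <- r[is.finite(r) & r > 0]
  if (length(r) == 0) stop("no usable ratios")
  obj <- function(f) sum(pmax(0, 1 - f * r) + pmax(0, f * r - 2))
  breaks <- sort(unique(c(1 / r, 2 / r)))
  vals <- vapply(breaks, obj, numeric(1))
  vmin <- min(vals)
  cand <- breaks[vals <= vmin + 1e-12 * (1 + vmin)]
  # minimizers of a convex piecewise-linear objective form an interval
  # between adjacent breakpoints; pick the admissible f closest to 1
  f <- if (min(cand) <= 1 && max(cand) >= 1 && obj(1) <= vmin + 1e-12 * (1 + vmin)) {
    1
  } else {
    cand[which.min(abs(log(cand)))]
  }
  out <- profile
  out$adjusted_ratio <- out$raw_ratio * f
  attr(out, "adjustment_factor") <- f
  attr(out, "objective") <- obj(f)
  out
}

#' Smooth a per-bin profile within chromosomes
#'
#' Smooths the (adjusted) ratio along each chromosome independently — never
#' across chromosome boundaries — using either a cubic smoothing spline
#' (smoothing parameter chosen by generalized cross-validation unless
#' given) or LOESS local regression.
#'
#' @param profile a data frame with `chrom`, `start`, `end` and the value
#'   column named by `value_col`.
#' @param method `"spline"` or `"loess"`.
#' @param span_or_spar LOESS span (default 0.1) or spline `spar`
#'   (default NULL = GCV).
#' @param value_col column to smooth (default `adjusted_ratio`, falling
#'   back to `raw_ratio`).
#' @param min_bins chromosomes with fewer bins are passed through
#'   unsmoothed, with a warning.
#' @return The profile with a `smoothed` column; method and parameter in
#'   attributes.
#' @export
smooth_profile <- function(profile, method = c("spline", "loess"),
                           span_or_spar = NULL,
                           value_col = NULL, min_bins = 10) {
  method <- match.arg(method)
  if (is.null(value_col)) {
    value_col <- if ("adjusted_ratio" %in% names(profile)) "adjusted_ratio"
                 else "raw_ratio"
  }
  out <- profile
  out$smoothed <- NA_real_
  for (chr in unique(profile$chrom)) {
    i <- which(profile$chrom == chr)
    mid <- (profile$start[i] + profile$end[i]) / 2
    y <- profile[[value_col]][i]
    if (length(i) < min_bins) {
      warning("chromosome ", chr, " has fewer than ", min_bins,
              " bins; returned unsmoothed")
      out$smoothed[i] <- y
    } else if (diff(range(y)) == 0) {
      out$smoothed[i] <- y
    } else if (method == "spline") {
      fit <- if (is.null(span_or_spar)) stats::smooth.spline(mid, y)
             else stats::smooth.spline(mid, y, spar = span_or_spar)
      out$smoothed[i] <- stats::predict(fit, mid)$y
    } else {
      span <- span_or_spar %||% 0.1
      fit <- stats::loess(y ~ mid, span = span, degree = 2,
                          family = "gaussian")
      out$smoothed[i] <- stats::predict(fit, mid)
    }
  }
  attr(out, "smoothing") <- list(method = method,
                                 parameter = span_or_spar %||% "GCV/0.1")
  out
}

#' Extract profile values at ddPCR probe locations
#'
#' Returns, for each probe, the profile value of the overlapping bin; when
#' a probe straddles exactly two bins, the unweighted mean of the two is
#' used (and the unweighted mean with a warning for > 2 bins). Probes with
#' no overlapping bin get `NA`.
#'
#' @param profile a binned profile data frame with `chrom`, `start`, `end`
#'   and the value column named by `value_col`.
#' @param probes a [probe_spec()].
#' @param value_col which column to extract (default `smoothed`, falling
#'   back to `adjusted_ratio` then `raw_ratio`).
#' @return Named numeric vector, one value per probe.
#' @export
extract_probe_windows <- function(profile, probes, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- intersect(c("smoothed", "adjusted_ratio", "raw_ratio"),
                           names(profile))[1]
    if (is.na(value_col)) stop("no value column found in profile")
  }
  bins <- GenomicRanges::GRanges(
    profile$chrom,
    IRanges::IRanges(start = profile$start + 1L, end = profile$end)
  )
  pr <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(start = probes$start + 1L, end = probes$end)
  )
  hits <- GenomicRanges::findOverlaps(pr, bins)
  vals <- rep(NA_real_, nrow(probes))
  for (i in seq_len(nrow(probes))) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(j) == 0) next
    if (length(j) > 2) {
      warning("probe ", probes$probe_id[i], " overlaps ", length(j),
              " bins; using their unweighted mean")
    }
    vals[i] <- mean(profile[[value_col]][j])
  }
  stats::setNames(vals, probes$probe_id)
}

#' Linear comparison of two per-probe copy-number measurements
#'
#' Ordinary least squares of `y` on `x` over the shared, non-missing
#' probes, reporting the slope, intercept, R-squared and adjusted
#' R-squared (`1 - (1 - R2)(n - 1)/(n - 2)`), e.g. for comparing
#' sequencing-derived with ddPCR-derived relative copy numbers.
#'
#' @param x,y named numeric vectors (probe id -> value).
#' @return A list with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `n`.
#' @export
compare_profiles <- function(x, y) {
  shared <- intersect(names(x), names(y))
  xv <- x[shared]; yv <- y[shared]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need >= 3 shared probes with values")
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       adj_r_squared = s$adj.r.squared,
       n = length(xv))
}
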