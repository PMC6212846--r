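# Relative copy number and inter-sample comparison.
#
# In replicating material the per-locus DNA abundance lies between 1
# (unreplicated) and 2 (fully replicated) per haploid copy; normalizations
# here put per-probe concentrations on that scale and make samples with
# different dynamic ranges comparable through the replication index.

#' Define a set of ddPCR probes
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom,start,end genomic interval (0-based half-open).
#' @param copies_per_haploid integer copy number of the amplicon per haploid
#'   genome (1 for unique loci, 2/3 for duplicated/triplicated loci).
#' @param role one of `"target"`, `"early_control"`, `"late_control"`.
#' @param allele_tag optional allele label (`NA` = pan-allelic).
#' @return A data frame of class `probe_spec`.
#' @export
probe_spec <- function(probe_id, chrom = "chr1", start = 0L, end = 100L,
                       copies_per_haploid = 1L, role = "target",
                       allele_tag = NA_character_) {
  if (anyDuplicated(probe_id)) stop("duplicate probe_id")
  out <- data.frame(
    probe_id = as.character(probe_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    copies_per_haploid = as.integer(copies_per_haploid),
    role = as.character(role), allele_tag = as.character(allele_tag),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("start must be < end")
  if (any(out$copies_per_haploid < 1)) stop("copies_per_haploid must be >= 1")
  if (!all(out$role %in% c("target", "early_control", "late_control"))) {
    stop("role must be target, early_control or late_control")
  }
  class(out) <- c("probe_spec", class(out))
  out
}

#' Copy-adjusted baseline normalization
#'
#' Converts per-probe concentrations to relative copy number against the
#' mean concentration of all probes after adjusting each for its per-haploid
#' copy number: `baseline = mean(c_i / k_i)` and `value_i = c_i / baseline`.
#' Values are deliberately not divided by `k_i`, so duplicated and
#' triplicated probes read 2 and 3 in non-replicating material while unique
#' probes read 1 (or 1 to 2 in S-phase material). Confidence limits, when
#' supplied, are scaled by the same baseline.
#'
#' @param concentrations named numeric vector of concentrations
#'   (names = probe ids), or a data frame with `probe_id` and
#'   `concentration` (optionally `ci_low`, `ci_high`).
#' @param probes a [probe_spec()] covering every probe.
#' @return A data frame with `probe_id`, `value`, `ci_low`, `ci_high`.
#' @examples
#' pr <- probe_spec(c("u1", "u2", "d", "t"), copies_per_haploid = c(1, 1, 2, 3),
#'                  start = c(0, 200, 400, 600), end = c(100, 300, 500, 700))
#' baseline_normalize(c(u1 = 10, u2 = 10, d = 20, t = 30), pr)
#' @export
baseline_normalize <- function(concentrations, probes) {
  if (is.data.frame(concentrations)) {
    conc <- stats::setNames(concentrations$concentration,
                            concentrations$probe_id)
    lo <- if ("ci_low" %in% names(concentrations))
      stats::setNames(concentrations$ci_low, concentrations$probe_id)
    hi <- if ("ci_high" %in% names(concentrations))
      stats::setNames(concentrations$ci_high, concentrations$probe_id)
  } else {
    conc <- concentrations
    lo <- hi <- NULL
  }
  if (length(conc) == 0) stop("no concentrations supplied")
  if (any(conc <= 0)) stop("concentrations must be positive")
  missing <- setdiff(probes$probe_id, names(conc))
  if (length(missing)) {
    stop("no concentration for probe(s): ", paste(missing, collapse = ", "))
  }
  k <- stats::setNames(probes$copies_per_haploid, probes$probe_id)
  ids <- probes$probe_id
  baseline <- mean(conc[ids] / k[ids])
  data.frame(
    probe_id = ids,
    value = unname(conc[ids] / baseline),
    ci_low = if (!is.null(lo)) unname(lo[ids] / baseline) else NA_real_,
    ci_high = if (!is.null(hi)) unname(hi[ids] / baseline) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Early/late control-probe concentration ratio
#'
#' Ratio of the early-control to the late-control concentration at one time
#' point. In a synchronized course the ratio starts near 1 in G1, rises
#' towards 2 while only the early locus replicates, peaks near mid-S and
#' returns to 1 in G2.
#'
#' @param concentrations named numeric vector (probe id -> concentration)
#'   for one sample, containing both control probes.
#' @param early,late probe ids of the early and late controls.
#' @return The ratio (numeric scalar).
#' @export
control_ratio <- function(concentrations, early, late) {
  if (!early %in% names(concentrations) || !late %in% names(concentrations)) {
    stop("control probe missing from sample")
  }
  if (concentrations[[late]] <= 0) stop("late-control concentration is zero")
  concentrations[[early]] / concentrations[[late]]
}

#' Locate the early/late normalization switch point in a time course
#'
#' Returns the index of the time point with the maximum control ratio (the
#' mid-S point at which the early control has finished replicating and the
#' late control is about to start). Ties break toward the earlier sample.
#'
#' @param course a list of named concentration vectors, ordered by time.
#' @inheritParams control_ratio
#' @return A list with `index`, `ratios` and `degenerate` (TRUE when all
#'   ratios are equal, e.g. a course that never entered S phase).
#' @export
find_switch_point <- function(course, early, late) {
  if (length(course) < 3) stop("need >= 3 time points")
  ratios <- vapply(course, control_ratio, numeric(1), early = early,
                   late = late)
  list(index = which.max(ratios), ratios = unname(ratios),
       degenerate = diff(range(ratios)) < .Machine$double.eps^0.5)
}

#' Dual normalization of a synchronized time course
#'
#' Early-S samples (index <= switch) are normalized to the late control,
#' which has not begun to replicate; late-S samples (index > switch) are
#' normalized to the early control, which has finished replicating, with a
#' ploidy adjustment (x2 by default) because the finished early control
#' itself stands at copy number 2.
#'
#' @param course a list of named concentration vectors ordered by time.
#' @param switch sample index from [find_switch_point()] (or user-chosen).
#' @inheritParams control_ratio
#' @param ploidy_factor replicated copy number of the early control
#'   (default 2; adjust for non-unique control amplicons).
#' @return A data frame with `time_index`, `probe_id`, `value`.
#' @export
dual_normalize <- function(course, switch, early, late, ploidy_factor = 2) {
  res <- lapply(seq_along(course), function(i) {
    conc <- course[[i]]
    if (!early %in% names(conc) || !late %in% names(conc)) {
      stop("control probe missing at time point ", i)
    }
    value <- if (i <= switch) conc / conc[[late]]
             else ploidy_factor * conc / conc[[early]]
    data.frame(time_index = i, probe_id = names(conc),
               value = unname(value), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Replication index
#'
#' The affine rescaling of a probe's S-phase concentration that maps the
#' early control to 0 and the late control to 1:
#' `RI = (c_early - c_probe) / (c_early - c_late)`. Because the map is
#' affine in concentration, the index is invariant under a multiplicative
#' rescaling of all three values, so samples with different dynamic ranges
#' (e.g. different sorted-gate purities) are directly comparable. Values
#' slightly outside 0..1 indicate probes replicating earlier/later than the
#' respective control.
#'
#' @param c_probe,c_early,c_late concentrations (or copy-number values) of
#'   the probe and the early and late controls; vectorised over `c_probe`.
#' @return Numeric replication index.
#' @examples
#' replication_index(c_probe = 1500, c_early = 2000, c_late = 1000)  # 0.5
#' @export
replication_index <- function(c_probe, c_early, c_late) {
  if (any(c_early <= c_late)) {
    stop("degenerate controls: the early control must be more replicated ",
         "(higher concentration) than the late control")
  }
  (c_early - c_probe) / (c_early - c_late)
}

#' Allele-specific replication delay
#'
#' Compares allele-specific probes at the same heterozygous locus within a
#' single sorted S-phase sample. A mutant/wild-type concentration ratio
#' below 1 indicates delayed replication of the mutant allele. Significance
#' is assessed on replicate concentrations by one-way ANOVA with Tukey HSD.
#'
#' @param wildtype,mutant numeric vectors of replicate concentrations for
#'   the wild-type and mutant allele probes.
#' @param alpha significance threshold for the reported flag.
#' @return A list with `ratio` (mean mutant / mean wild type), `p_adj`
#'   (Tukey-adjusted p), and `significant`.
#' @export
allele_delay <- function(wildtype, mutant, alpha = 0.05) {
  tab <- list(wt = wildtype, mut = mutant)
  tk <- tukey_hsd(tab)
  list(ratio = mean(mutant) / mean(wildtype),
       p_adj = tk$p_adj[1],
       significant = tk$p_adj[1] <= alpha)
}
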