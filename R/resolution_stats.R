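# Probe-resolution statistics: one-way ANOVA, Tukey HSD, and the arithmetic
# of distinguishable copy-number states.

# coerce a replicate table (named list of numeric vectors, or a long data
# frame with probe_id/value) into a long data frame with a factor group
as_replicate_table <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("probe_id", "value") %in% names(table)))
    df <- data.frame(group = factor(table$probe_id,
                                    levels = unique(table$probe_id)),
                     value = table$value)
  } else {
    df <- data.frame(
      group = factor(rep(names(table), lengths(table)),
                     levels = names(table)),
      value = unlist(table, use.names = FALSE)
    )
  }
  if (nlevels(df$group) < 2) stop("need >= 2 groups")
  if (any(tabulate(df$group) < 2)) stop("every group needs >= 2 replicates")
  df
}

#' One-way ANOVA over probe replicate measurements
#'
#' Classical between/within variance decomposition across probes, on
#' technical-replicate concentrations (or normalized copy numbers). The
#' fully degenerate case — all groups identical constants — returns
#' `F = 0`, `p = 1` rather than 0/0.
#'
#' @param table a named list `probe_id -> numeric replicate vector` (each
#'   >= 2 values), or a long data frame with `probe_id` and `value`.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(table) {
  df <- as_replicate_table(table)
  if (stats::var(df$value) <= 0) {  # identical constants: nothing to test
    return(list(F = 0, p = 1, df_between = nlevels(df$group) - 1,
                df_within = nrow(df) - nlevels(df$group)))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(Fv)) {  # zero within- and between-variance
    Fv <- 0; p <- 1
  }
  list(F = Fv, p = p, df_between = an[["Df"]][1], df_within = an[["Df"]][2])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-adjusted pairwise p-values after one-way ANOVA
#' (Tukey-Kramer for unequal replicate counts), with significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @inheritParams one_way_anova
#' @return A data frame with `group1`, `group2`, `diff`, `ci_low`,
#'   `ci_high`, `p_adj`, `stars`.
#' @export
tukey_hsd <- function(table) {
  df <- as_replicate_table(table)
  if (stats::var(df$value) == 0) {  # identical constants: nothing to test
    pairs <- utils::combn(levels(df$group), 2)
    return(data.frame(group1 = pairs[1, ], group2 = pairs[2, ], diff = 0,
                      ci_low = 0, ci_high = 0, p_adj = 1, stars = "",
                      stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(nm, `[`, "", 2),
    group2 = vapply(nm, `[`, "", 1),
    diff = -tk[, "diff"],
    ci_low = -tk[, "upr"],
    ci_high = -tk[, "lwr"],
    p_adj = tk[, "p adj"],
    stars = stars_for(tk[, "p adj"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

stars_for <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Count significant copy-number states along ordered probes
#'
#' Probes are ordered by genomic position; the sequence is cut at every
#' adjacent pair whose Tukey-adjusted p-value is at or below `alpha`, and
#' the number of resulting segments is the count of statistically distinct
#' states: `1 + number of significant adjacent pairs`. It never exceeds the
#' number of probes.
#'
#' @param probe_order character vector of probe ids in genomic order.
#' @param tukey output of [tukey_hsd()] covering the adjacent pairs.
#' @param alpha significance threshold (default 0.05).
#' @return Integer number of states.
#' @export
count_significant_states <- function(probe_order, tukey, alpha = 0.05) {
  n <- length(probe_order)
  if (n < 2) return(n)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  padj <- stats::setNames(tukey$p_adj, key(tukey$group1, tukey$group2))
  cuts <- 0L
  for (i in seq_len(n - 1)) {
    k <- key(probe_order[i], probe_order[i + 1])
    if (!k %in% names(padj)) stop("missing Tukey result for adjacent pair ",
                                  probe_order[i], " / ", probe_order[i + 1])
    if (padj[[k]] <= alpha) cuts <- cuts + 1L
  }
  1L + cuts
}

#' Theoretical number of distinguishable replication states
#'
#' On the 1..2 relative copy-number scale, with a minimal statistically
#' detectable difference `d`, `floor((2 - 1) / d)` states can be told
#' apart (e.g. `d = 0.07` gives 14).
#'
#' @param min_detectable_difference `d`, in copy-number units, in (0, 1].
#' @return Integer number of states.
#' @export
theoretical_states <- function(min_detectable_difference) {
  d <- min_detectable_difference
  if (length(d) != 1 || !is.finite(d) || d <= 0 || d > 1) {
    stop("min_detectable_difference must be in (0, 1]")
  }
  as.integer(floor(1 / d))
}

#' Minimal detectable copy-number difference by Monte-Carlo power analysis
#'
#' Finds, by bisection, the smallest mean difference between two probes —
#' each measured with `n_replicates` technical replicates at coefficient of
#' variation `cv` around the middle of the 1..2 copy scale — that a Tukey
#' HSD comparison detects at level `alpha` with the target power. Seeded
#' and reproducible.
#'
#' @param cv coefficient of variation of one replicate measurement.
#' @param n_replicates technical replicates per probe.
#' @param alpha significance threshold.
#' @param power target detection probability.
#' @param n_sims Monte-Carlo simulations per bisection step.
#' @param seed RNG seed.
#' @return The minimal difference, in copy-number units.
#' @export
min_detectable_difference <- function(cv, n_replicates = 3, alpha = 0.05,
                                      power = 0.8, n_sims = 2000, seed = 1) {
  if (cv <= 0) stop("cv must be positive")
  if (n_replicates < 2) stop("need >= 2 replicates")
  level <- 1.5                     # mid-scale copy number
  sd <- cv * level
  n <- n_replicates
  df <- 2 * n - 2
  # two balanced groups: the Tukey-adjusted p is the studentized-range
  # tail P(q(2, df) >= |mean gap| / sqrt(MSE/n)), identical to what
  # tukey_hsd() reports; evaluated vectorised over simulated tables
  power_at <- function(delta) {
    a <- matrix(stats::rnorm(n * n_sims, level, sd), n)
    b <- matrix(stats::rnorm(n * n_sims, level + delta, sd), n)
    ma <- colMeans(a); mb <- colMeans(b)
    mse <- (colSums((a - rep(ma, each = n))^2) +
            colSums((b - rep(mb, each = n))^2)) / df
    q <- abs(ma - mb) / sqrt(mse / n)
    p <- stats::ptukey(q, nmeans = 2, df = df, lower.tail = FALSE)
    mean(p <= alpha)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lo <- 0
  hi <- sd  # start at one replicate SD and expand until powered
  tries <- 0
  while (power_at(hi) < power) {
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 20) stop("bisection bounds did not converge")
  }
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (power_at(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
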