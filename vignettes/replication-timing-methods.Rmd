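---
title: "Measuring DNA replication timing by droplet digital PCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DNA replication timing by droplet digital PCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliddpcr)
```

## The measurement

During S phase every locus doubles from one to two copies per haploid
genome, and it does so at a characteristic time. In a population of
replicating cells the *relative copy number* of a locus — its DNA
abundance scaled so unreplicated DNA reads 1 and fully replicated DNA
reads 2 — is therefore a proxy for its replication timing: early loci sit
near 2 in mid-S material, late loci near 1.

Droplet digital PCR (ddPCR) measures absolute template concentration
precisely enough to resolve that scale. A reaction is partitioned into
roughly 20,000 droplets of about 1 nl; after end-point PCR each droplet is
positive or negative. With positive fraction $\hat p$, the mean occupancy
(copies per droplet) is the Poisson inversion

$$\hat\lambda = -\ln(1 - \hat p),$$

and concentration is $\hat\lambda / v$ with $v$ the droplet volume in
microlitres. `estimate_concentration()` implements this, and
`cv_of_estimator()` the delta-method error model

$$\mathrm{CV}(\hat\lambda) = \frac{1}{\lambda}
  \sqrt{\frac{p}{(1-p)\,n}}, \qquad p = 1 - e^{-\lambda},$$

which is U-shaped in $\lambda$: subsampling error dominates dilute
reactions, partitioning error concentrated ones, with a minimum near
$\lambda \approx 1.6$. Between occupancies 0.11 and 5.73 copies/droplet
the CV stays below 2.5%, and near 1–2 copies/droplet (1000–2000
copies/µl at 1 nl) it is about 1% — small enough that both ends of the
1–2 replication scale fit in one dilution.

### Uncertainty conventions

Two interval types are deliberately kept apart. The per-well interval
(`concentration_ci()`) is the delta-method normal interval on
$\hat\lambda$, clipped at zero — a partitioning-statistics statement about
a single well. The replicate interval (`replicate_ci()`) is a Student-t
interval (df = n − 1) over technical replicates, the convention used for
plotted error bars; two replicates are allowed and get t with 1 df.
Whether published error bars used t or normal quantiles is generally not
stated, so both are available; t is the default for replicates because it
is the honest choice at n = 2–3.

## From concentrations to copy numbers

**Baseline normalization** (`baseline_normalize()`) divides each probe's
concentration by the mean of copy-adjusted concentrations,
$\bar c = \mathrm{mean}_i(c_i / k_i)$, where $k_i$ is the probe's
per-haploid copy number. Values are *not* divided by $k_i$, so in
non-replicating material unique, duplicated and triplicated probes read
1, 2 and 3 — a built-in integer control for the whole chain.

**Dual normalization** (`dual_normalize()`) makes a synchronized
arrest–release course comparable across time points, where every locus
eventually doubles. Early-S samples are normalized to a late control that
has not begun replicating; samples after the switch point are normalized
to an early control that has finished, multiplied by its replicated copy
number (2 by default, configurable for non-unique controls). The switch
point (`find_switch_point()`) is the argmax of the early/late control
concentration ratio, which rises from ~1 in G1 toward 2 at mid-S and
falls back to 1 in G2; ties break toward the earlier sample and a
degeneracy flag marks monotone courses.

**Replication index** (`replication_index()`) is the affine map sending
the early control to 0 and the late control to 1:

$$\mathrm{RI} = \frac{c_\mathrm{early} - c_\mathrm{probe}}
                     {c_\mathrm{early} - c_\mathrm{late}}.$$

The published description defines the index in terms of $T_{rep}$ values
rather than writing a copy-number formula; this linear form is adopted
here as the unique affine map with those anchor points. Because it is
invariant under multiplicative rescaling of all three concentrations, it
cancels the sample-to-sample dynamic-range differences that FACS gate
purity induces, which is what makes multi-strain screens comparable.
Values slightly outside [0, 1] are legitimate (probes earlier or later
than the controls) and are not clipped. For loci measured with two
flanking probes, per-probe indices are reported and averaged afterwards
(the default; averaging concentrations first is also possible).

## Replication kinetics

`fit_boltzmann()` fits the Boltzmann sigmoid

$$y(x) = A_2 + \frac{A_1 - A_2}{1 + e^{(x - x_0)/dx}}$$

by Levenberg–Marquardt least squares, with $T_{rep} = x_0$ the
half-replication midpoint (`trep_of()`). The model has two equivalent
parameterizations (swap plateaus, negate $dx$); fits are canonicalised to
$dx > 0$, making $A_1$ the plateau approached at small $x$ and the curve
non-decreasing exactly when $A_1 < A_2$. Initialisation uses the observed
extremes, the mid-range crossing for $x_0$, and $dx_0 =$ range$(x)/10$.
Flat series (range below $10^{-9}\,|\bar y|$) raise a degenerate-data
error rather than returning an arbitrary midpoint.

Bulk replication from flow cytometry
(`bulk_replication_from_fc()`) normalizes per-sample DNA-signal medians
(or means — both columns are accepted, medians preferred) to the arrested
sample and linearly stretches the observed range onto [1, 2], so the
replicated fraction runs from exactly 0 to exactly 1 across the course.
The stretch uses the observed min/max by design; a single outlier sample
therefore sets an endpoint, which is the main caveat of the method and
the reason the fitted Boltzmann curve (attached to the result) is used
for sample selection (`select_sample_by_replication()`).

## Sort-seq ratios

`compute_ratio()` implements the depth-normalized per-bin ratio
$r = (\mathrm{rep}/\mathrm{nonRep}) \times
(\mathrm{nonRepSum}/\mathrm{repSum})$, excluding bins whose
non-replicating count falls below a threshold (default 1 read) and
summing depths over included bins only. The ratio is invariant to the
global depth of either sample.

`adjust_to_unit_range()` rescales the profile onto the biological [1, 2]
range by a single multiplicative factor minimizing the summed exceedance
$\sum_i \max(0, 1 - f r_i) + \max(0, f r_i - 2)$. The published
description states only that the adjustment "minimizes the sum of ratio
values outside of the one to two range"; the functional form (one
multiplicative factor, linear exceedance penalty) is this package's
reading of it, chosen because the ratio formula already fixes genome-wide
mean scaling. The objective is convex and piecewise linear in $f$, so it
is minimized exactly by enumerating its breakpoints $1/r_i$ and $2/r_i$;
when a whole interval of factors attains the minimum (e.g. a profile that
fits strictly inside the range), the factor closest to 1 is returned,
making the operation idempotent. Note the factor is then only determined
up to that interval: rescaling a clean profile by 0.5 is undone by a
factor within a percent or two of 2, not exactly 2.

Smoothing (`smooth_profile()`) is strictly per-chromosome — never across
boundaries — with either a cubic smoothing spline (parameter by
generalized cross-validation unless given) or LOESS (default span 0.1).
Probe readout (`extract_probe_windows()`) takes the overlapping bin's
value, averaging (unweighted) when a probe straddles two bins, as in the
published comparison procedure; probes with no bin return `NA` rather
than failing the batch. `compare_profiles()` reports OLS slope,
intercept and adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-2)$.

## Resolution statistics

`one_way_anova()` and `tukey_hsd()` wrap the classical decomposition and
the studentized-range post hoc test (Tukey–Kramer under unequal
replication), with stars at 0.05/0.01/0.001. Fully degenerate tables
(identical constants) return F = 0, p = 1 rather than 0/0.
`count_significant_states()` counts distinguishable copy-number states by
cutting the genomically ordered probe sequence at every adjacent pair
with adjusted p ≤ α: states = 1 + cuts. The published count of "eight
states" does not specify its counting rule; the adjacent-pair cut rule is
the one implemented and documented. `theoretical_states(d)` is the
arithmetic $\lfloor (2-1)/d \rfloor$, giving 14 at the empirically
observed d = 0.07.

`min_detectable_difference()` inverts the power question by bisection:
the smallest mean difference between two probes (each with n technical
replicates at a given CV, centred mid-scale at copy number 1.5) that a
Tukey comparison detects at level α with the target power. For two
balanced groups the Tukey-adjusted p is the studentized-range tail
probability, evaluated vectorised over simulated tables; at CV 1% and
three replicates the answer is ≈ 0.05 copy-number units, comfortably
within the 0.07 resolution observed empirically.

## The synthetic-data generator

All tests and analyses run on synthetic data with the statistical
structure the pipeline assumes:

- **Timing landscape** (`replication_model()`, `trep_profile()`):
  origins with positions, firing times and efficiencies, constant fork
  speed; $t_{rep}(x) = \min_i (t_i + |x - o_i|/v)$ when all origins fire,
  otherwise the population median over seeded per-cell origin-activity
  draws (conditioned on at least one active origin per cell). This
  nearest-origin kinematics is the minimal model producing the
  early/late/passive vocabulary; it omits stochastic firing-time
  variance, origin interference and rate-limiting factors, so passing
  tests show pipeline correctness, not biological realism of the
  landscape. Fork speed defaults to 1.5 kb/min, a typical budding-yeast
  figure.
- **Populations** (`population_synchronized()`, `population_sorted_s()`,
  `population_asynchronous()`): synchronized cells get Gaussian per-cell
  S-entry jitter (default SD 3 min — a fixture choice, as published data
  do not quantify synchrony dispersion); sorted S gates mix
  uniform-progression S cells with G1/G2 contaminants (defaults 5% each,
  reflecting realistic gate purity) and renormalize so the
  latest-replicating evaluated position reads 1; asynchronous cultures
  with S fraction $f_S$ span exactly $[1, 1 + f_S]$ before G2 dilution —
  20% S cells give the 1-to-1.2 dynamic range expected on theory. Where a
  simulation mixes models sharing one cell population (allele pairs,
  mutant screens), the S progression is normalized over the genome-wide
  timing range on a 1 kb grid, not over the probe positions.
- **Droplets** (`simulate_droplets()`): positives are
  Binomial$(n, 1 - e^{-\lambda})$ at $\lambda =$ concentration × volume.
  Default 20,000 droplets/well and 1 nl volume; 1 nl keeps the
  copies/droplet ↔ copies/µl correspondence simple (0.11 copies/droplet
  = 110 copies/µl) even though instruments nominally partition ~0.85 nl —
  both are configurable. Saturated wells error; callers must dilute.
- **Sequencing counts** (`simulate_sortseq_counts()`): negative binomial
  with mean ∝ copy number × depth; the default size parameter is derived
  from the calibration CV = 5% at 1000 reads/bin via
  $1/\mu + 1/\mathrm{size} = \mathrm{CV}^2$ (size ≈ 667); size = ∞ gives
  the Poisson floor (3.2% at 1000 reads).

Every generator is deterministic given its seed, drawn through a local
RNG stream that does not disturb the caller's.

## Problem sizes and numerical choices

The shipped analyses and tests use 2,000 simulated wells for Monte-Carlo
CV estimates, 500 one-kilobase bins at ~1000 reads/bin for sort-seq
recovery, 3 technical replicates of 20,000 droplets for ddPCR fixtures,
2-minute sampling with 3-minute synchrony jitter for time courses, and
2,000 simulations per bisection step in the power analysis — sizes at
which the Monte-Carlo error is a small fraction of each tolerance being
tested. Base concentration defaults to 1000 copies/µl (occupancy 1 at
1 nl), the middle of the minimal-error range.

## Known limitations

- The unit-range adjustment's functional form is a reimplementation
  decision, not a verbatim port of the published script.
- Sorted-gate and asynchronous population models treat S-phase
  progression as uniform; real gates have DNA-dye dispersion that
  underrepresents early/late S cells beyond simple G1/G2 contamination.
- The landscape model cannot capture inter-origin interference or
  checkpoint effects; recovered $T_{rep}$ values are internally
  consistent with the injected landscape, nothing more.
- No mappability/GC correction is applied to binned counts; inputs are
  assumed pre-filtered.
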