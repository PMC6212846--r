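# Synthetic replication-timing data.
#
# A minimal origin-firing model generates the inputs the pipeline consumes:
# a replication-timing landscape trep(x) from origins with firing times and
# a constant fork speed; population copy-number profiles for synchronized,
# FACS-sorted and asynchronous cultures; Poisson droplet partitioning; and
# overdispersed binned sequencing counts.

# run expr under a local, seeded RNG stream without disturbing the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Define a replication-timing model
#'
#' Origins at known positions fire at known times (minutes from S-phase
#' entry) with given efficiencies; forks progress at a constant speed. The
#' locus replication time trep(x) is the (population-median) first arrival
#' of a fork or origin firing at x.
#'
#' @param chrom_length chromosome length in bp.
#' @param origin_position numeric vector of origin positions (bp, within
#'   the chromosome).
#' @param firing_time firing times in minutes (same length).
#' @param efficiency per-origin firing probabilities in (0, 1] (default 1).
#' @param fork_speed fork speed in kb/min (default 1.5, a typical budding
#'   yeast value).
#' @param chrom chromosome name.
#' @return A list of class `replication_model`.
#' @export
replication_model <- function(chrom_length, origin_position, firing_time,
                              efficiency = 1, fork_speed = 1.5,
                              chrom = "chrS") {
  if (length(origin_position) == 0) stop("need >= 1 origin")
  stopifnot(length(firing_time) == length(origin_position))
  efficiency <- rep_len(efficiency, length(origin_position))
  if (any(origin_position < 0 | origin_position >= chrom_length)) {
    stop("origin positions must lie within [0, chrom_length)")
  }
  if (fork_speed <= 0) stop("fork_speed must be positive")
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("efficiency must be in (0, 1]")
  }
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 origins = data.frame(position = origin_position,
                                      firing_time = firing_time,
                                      efficiency = efficiency),
                 fork_speed = fork_speed),
            class = "replication_model")
}

#' Replication-time landscape of a model
#'
#' With all efficiencies 1, `trep(x) = min_i(t_i + |x - o_i| / v)` — the
#' first fork to arrive wins. With partial efficiencies, per-cell origin
#' activity is sampled (conditional on at least one active origin) and the
#' population median replication time over `n_cells` cells is returned.
#'
#' @param model a [replication_model()].
#' @param positions bp positions at which to evaluate.
#' @param n_cells cells to sample when efficiencies < 1.
#' @param seed RNG seed for efficiency sampling.
#' @return trep in minutes, one value per position.
#' @examples
#' m <- replication_model(200e3, 100e3, firing_time = 10, fork_speed = 1)
#' trep_profile(m, 105e3)  # 10 + 5 kb / 1 kb/min = 15
#' @export
trep_profile <- function(model, positions, n_cells = 1000, seed = 1) {
  o <- model$origins
  v_bp <- model$fork_speed * 1000
  arrival <- vapply(seq_len(nrow(o)), function(i) {
    o$firing_time[i] + abs(positions - o$position[i]) / v_bp
  }, numeric(length(positions)))
  arrival <- matrix(arrival, nrow = length(positions))
  if (all(o$efficiency >= 1)) {
    return(apply(arrival, 1, min))
  }
  with_seed(seed, {
    k <- nrow(o)
    treps <- matrix(NA_real_, n_cells, length(positions))
    for (cell in seq_len(n_cells)) {
      active <- stats::runif(k) <= o$efficiency
      while (!any(active)) active <- stats::runif(k) <= o$efficiency
      treps[cell, ] <- if (sum(active) == 1) arrival[, active]
                       else apply(arrival[, active, drop = FALSE], 1, min)
    }
    apply(treps, 2, stats::median)
  })
}

#' Population models for copy-number profiles
#'
#' `population_synchronized`: all cells enter S phase at time 0 with
#' per-cell Gaussian entry jitter `entry_sd`; the profile is evaluated at
#' `time` minutes after release. `population_sorted_s`: an S-phase FACS
#' gate in which S cells are uniform over normalized S progression, with
#' stated fractions of contaminating G1 and G2 cells. The defaults (5%
#' each) reflect realistic gate purity. `population_asynchronous`: a cycling
#' culture with an S-phase fraction `s_fraction` and optional G2 fraction.
#'
#' @param time minutes after release (synchronized mode).
#' @param entry_sd per-cell S-entry jitter, minutes (SD).
#' @param g1_contamination,g2_contamination contaminating fractions in the
#'   sorted S gate.
#' @param s_fraction,g2_fraction population fractions in the asynchronous
#'   mode (the remainder is G1).
#' @return A list of class `population_model`.
#' @name population_model
NULL

#' @rdname population_model
#' @export
population_synchronized <- function(time, entry_sd = 3) {
  stopifnot(time >= 0, entry_sd >= 0)
  structure(list(mode = "synchronized", time = time, entry_sd = entry_sd),
            class = "population_model")
}

#' @rdname population_model
#' @export
population_sorted_s <- function(g1_contamination = 0.05,
                                g2_contamination = 0.05) {
  stopifnot(g1_contamination >= 0, g2_contamination >= 0,
            g1_contamination + g2_contamination < 1)
  structure(list(mode = "sorted_S", g1 = g1_contamination,
                 g2 = g2_contamination),
            class = "population_model")
}

#' @rdname population_model
#' @export
population_asynchronous <- function(s_fraction, g2_fraction = 0) {
  stopifnot(s_fraction >= 0, s_fraction <= 1, g2_fraction >= 0,
            s_fraction + g2_fraction <= 1)
  structure(list(mode = "asynchronous", s_fraction = s_fraction,
                 g2_fraction = g2_fraction),
            class = "population_model")
}

# genome-wide trep range of one or more models sharing a chromosome,
# evaluated on a 1 kb grid augmented with the origin positions (the global
# minimum always sits at the earliest origin)
genome_trep_range <- function(models) {
  if (inherits(models, "replication_model")) models <- list(models)
  range(unlist(lapply(models, function(m) {
    grid <- unique(c(seq(0, m$chrom_length - 1, by = 1000),
                     m$origins$position))
    range(trep_profile(m, grid))
  })))
}

# expected copies at given trep values for a population, with the S
# progression normalized over the supplied trep range
copies_from_trep <- function(trep, population, t_range = range(trep)) {
  if (population$mode == "synchronized") {
    p <- if (population$entry_sd == 0) as.numeric(trep <= population$time)
         else stats::pnorm((population$time - trep) / population$entry_sd)
    return(1 + p)
  }
  # fraction of S cells (uniform over normalized S progression) that have
  # passed trep(x); earliest locus -> 1, latest -> 0
  q <- if (diff(t_range) == 0) rep(1, length(trep))
       else pmin(1, pmax(0, (t_range[2] - trep) / (t_range[2] - t_range[1])))
  if (population$mode == "sorted_S") {
    g1 <- population$g1; g2 <- population$g2
    raw <- (1 - g1 - g2) * (1 + q) + g1 * 1 + g2 * 2
    raw / (1 + g2)  # latest-replicating position reads exactly 1
  } else {
    fs <- population$s_fraction; g2 <- population$g2_fraction
    1 + fs * q + g2
  }
}

#' Expected relative copy number along a chromosome
#'
#' Combines a replication-timing landscape with a population model:
#' synchronized populations give `1 + Phi((t - trep(x)) / sigma)`; sorted
#' S-phase gates mix uniform-progression S cells with G1/G2 contaminants
#' and are renormalized so the latest-replicating position reads 1; an
#' asynchronous culture with S fraction `f_S` spans the dynamic range
#' `1` to `1 + f_S` (before G2 dilution), e.g. 1 to 1.2 at 20% S cells.
#'
#' @param model a [replication_model()].
#' @param population a population model (see [population_synchronized()]).
#' @param positions bp positions to evaluate.
#' @param seed RNG seed (used only when origin efficiencies < 1).
#' @return Expected relative copy number per position, in `[1, 2]`.
#' @export
copy_number_profile <- function(model, population, positions, seed = 1) {
  trep <- trep_profile(model, positions, seed = seed)
  copies_from_trep(trep, population)
}

#' Simulate droplet partitioning of a template
#'
#' Poisson partitioning at the given droplet volume: the expected occupancy
#' is `lambda = concentration x volume`, and the number of positive
#' droplets is Binomial(`n_droplets`, `1 - exp(-lambda)`).
#'
#' @param concentration template concentration, copies/microlitre (>= 0).
#' @param n_droplets droplets per well.
#' @param droplet_volume_nl droplet volume, nanolitres.
#' @param probe_id,sample_id,replicate_id labels for the emitted well.
#' @param seed RNG seed (NULL = use the current RNG stream).
#' @return A one-row [droplet_count()].
#' @export
simulate_droplets <- function(concentration, n_droplets = 20000,
                              droplet_volume_nl = 1, probe_id = "probe",
                              sample_id = "sample", replicate_id = "r1",
                              seed = NULL) {
  if (concentration < 0) stop("concentration must be >= 0")
  if (n_droplets <= 0 || droplet_volume_nl <= 0) {
    stop("droplet number and volume must be positive")
  }
  lambda <- concentration * droplet_volume_nl * 1e-3
  p <- -expm1(-lambda)
  n_pos <- with_seed(seed, stats::rbinom(1, n_droplets, p))
  droplet_count(probe_id, sample_id, replicate_id, n_pos, n_droplets,
                droplet_volume_nl)
}

#' Simulate a full ddPCR experiment over a probe panel
#'
#' Each probe's target concentration is
#' `base_concentration x copy_number x copies_per_haploid`; independent
#' wells are drawn per technical replicate and emitted as droplet-count
#' rows. A warning is issued when any probe's occupancy exceeds 6
#' copies/droplet (outside the quantifiable range; dilute).
#'
#' @param copy_numbers named numeric vector, probe id -> relative copy
#'   number (1..2 scale, or integer copy ratios for non-replicating DNA).
#' @param probes a [probe_spec()] giving `copies_per_haploid` per probe.
#' @param base_concentration copies/microlitre corresponding to copy
#'   number 1 on a unique probe (default 1000, the middle of the
#'   minimal-error range).
#' @param n_replicates technical replicates per probe.
#' @param n_droplets droplets per well.
#' @param droplet_volume_nl droplet volume, nanolitres.
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return A `droplet_count` data frame, one row per probe x replicate.
#' @export
simulate_ddpcr_experiment <- function(copy_numbers, probes,
                                      base_concentration = 1000,
                                      n_replicates = 3, n_droplets = 20000,
                                      droplet_volume_nl = 1,
                                      sample_id = "sample", seed = NULL) {
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive")
  k <- stats::setNames(probes$copies_per_haploid, probes$probe_id)
  ids <- probes$probe_id
  conc <- base_concentration * copy_numbers[ids] * k[ids]
  lambda <- conc * droplet_volume_nl * 1e-3
  if (any(lambda > 6)) {
    warning("occupancy exceeds 6 copies/droplet for some probes; ",
            "outside the quantifiable range, consider diluting")
  }
  with_seed(seed, {
    rows <- lapply(seq_along(ids), function(i) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        simulate_droplets(conc[[i]], n_droplets, droplet_volume_nl,
                          probe_id = ids[i], sample_id = sample_id,
                          replicate_id = paste0("r", r))
      }))
    })
    do.call(rbind, rows)
  })
}

#' Simulate binned sort-seq counts
#'
#' Draws negative-binomial read counts for a replicating sample (mean
#' proportional to copy number x depth) and a non-replicating sample (mean
#' = depth). The default dispersion is calibrated so the count CV is ~5%
#' at 1000 reads/bin (`1/mean + 1/size = 0.05^2`, i.e. size ~667);
#' `size = Inf` gives pure Poisson counts (CV ~3.2% at 1000 reads).
#'
#' @param copy_numbers per-bin relative copy numbers.
#' @param mean_depth mean reads per bin in the non-replicating sample.
#' @param size negative-binomial size (dispersion) parameter; `NULL`
#'   derives it from `target_cv` at 1000 reads/bin; `Inf` = Poisson.
#' @param target_cv calibration CV at mean 1000 (default 0.05).
#' @param bin_width bin width in bp.
#' @param chrom chromosome name(s), recycled over bins.
#' @param seed RNG seed.
#' @return A [binned_counts()] data frame.
#' @export
simulate_sortseq_counts <- function(copy_numbers, mean_depth = 1000,
                                    size = NULL, target_cv = 0.05,
                                    bin_width = 1000, chrom = "chrS",
                                    seed = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  n <- length(copy_numbers)
  if (is.null(size)) {
    if (target_cv^2 <= 1 / 1000) stop("target_cv below the Poisson floor")
    size <- 1 / (target_cv^2 - 1 / 1000)
  }
  draw <- function(mu) {
    if (is.infinite(size)) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = size)
  }
  with_seed(seed, {
    rep_counts <- draw(mean_depth * copy_numbers)
    nonrep_counts <- draw(rep(mean_depth, n))
    start <- (seq_len(n) - 1L) * bin_width
    binned_counts(rep_len(chrom, n), start, start + bin_width,
                  rep_counts, nonrep_counts)
  })
}

#' Simulate an allele-specific ddPCR experiment
#'
#' Two haplotypes with different origin sets share one cell population.
#' Allele-specific probes (allele_tag `"A"` or `"B"`) draw their
#' concentration from their haplotype's expected copy number at the probe
#' midpoint; pan-allelic probes (tag `NA`) sum both haplotypes. The S
#' progression is normalized over the combined trep range of both
#' haplotypes, as both reside in the same cells.
#'
#' @param haplotypeA,haplotypeB [replication_model()]s with the same
#'   chromosome length and fork speed.
#' @param population a population model (typically [population_sorted_s()]).
#' @param probes a [probe_spec()] with `allele_tag` in `"A"`, `"B"` or `NA`.
#' @param base_concentration copies/microlitre per unreplicated haploid copy.
#' @param n_replicates,n_droplets,droplet_volume_nl well parameters.
#' @param seed RNG seed.
#' @return A `droplet_count` data frame.
#' @export
simulate_allele_experiment <- function(haplotypeA, haplotypeB, population,
                                       probes, base_concentration = 500,
                                       n_replicates = 3, n_droplets = 20000,
                                       droplet_volume_nl = 1, seed = NULL) {
  if (haplotypeA$chrom_length != haplotypeB$chrom_length ||
      haplotypeA$fork_speed != haplotypeB$fork_speed) {
    stop("haplotypes must share chromosome length and fork speed")
  }
  if (!all(probes$allele_tag %in% c("A", "B", NA_character_))) {
    stop("allele_tag must be \"A\", \"B\" or NA (pan-allelic)")
  }
  mid <- (probes$start + probes$end) / 2
  trepA <- trep_profile(haplotypeA, mid)
  trepB <- trep_profile(haplotypeB, mid)
  # both haplotypes sit in the same cells: one shared S progression,
  # normalized over the genome-wide timing range of the two
  t_range <- genome_trep_range(list(haplotypeA, haplotypeB))
  cnA <- copies_from_trep(trepA, population, t_range)
  cnB <- copies_from_trep(trepB, population, t_range)
  conc <- ifelse(is.na(probes$allele_tag),
                 base_concentration * (cnA + cnB),
                 base_concentration * ifelse(probes$allele_tag == "A",
                                             cnA, cnB))
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        simulate_droplets(conc[i], n_droplets, droplet_volume_nl,
                          probe_id = probes$probe_id[i],
                          sample_id = "S_sorted",
                          replicate_id = paste0("r", r))
      }))
    }))
  })
}

#' Simulate a replication-timing mutant screen
#'
#' For each strain, the firing time of the origin nearest the target locus
#' is delayed by the strain's injected delay, an independent sorted
#' S-phase sample is drawn with a randomized gate purity (so strains have
#' different dynamic ranges, exercising the invariance of the replication
#' index), and droplet counts are emitted for all probes.
#'
#' @param model the wild-type [replication_model()].
#' @param probes a [probe_spec()]; must include one `early_control` and one
#'   `late_control` probe.
#' @param target_position bp position of the screened locus.
#' @param delays named numeric vector, strain -> delay in minutes (include
#'   a 0 entry for wild type).
#' @param base_concentration,n_replicates,n_droplets,droplet_volume_nl
#'   well parameters.
#' @param contamination_range range of the per-strain G1/G2 gate
#'   contamination fractions (drawn uniformly, seeded).
#' @param seed RNG seed.
#' @return A `droplet_count` data frame with strains as `sample_id`.
#' @export
simulate_screen <- function(model, probes, target_position, delays,
                            base_concentration = 1000, n_replicates = 3,
                            n_droplets = 20000, droplet_volume_nl = 1,
                            contamination_range = c(0.02, 0.12),
                            seed = NULL) {
  if (any(delays < 0)) stop("delays must be >= 0")
  if (is.null(names(delays))) stop("delays must be named by strain")
  mid <- (probes$start + probes$end) / 2
  target_origin <- which.min(abs(model$origins$position - target_position))
  with_seed(seed, {
    do.call(rbind, lapply(names(delays), function(strain) {
      m <- model
      m$origins$firing_time[target_origin] <-
        m$origins$firing_time[target_origin] + delays[[strain]]
      pop <- population_sorted_s(
        g1_contamination = stats::runif(1, contamination_range[1],
                                        contamination_range[2]),
        g2_contamination = stats::runif(1, contamination_range[1],
                                        contamination_range[2])
      )
      cn <- copies_from_trep(trep_profile(m, mid), pop,
                             t_range = genome_trep_range(m))
      do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
        do.call(rbind, lapply(seq_len(n_replicates), function(r) {
          simulate_droplets(base_concentration * cn[i], n_droplets,
                            droplet_volume_nl,
                            probe_id = probes$probe_id[i],
                            sample_id = strain,
                            replicate_id = paste0("r", r))
        }))
      }))
    }))
  })
}
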