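# Shared fixtures: small replication landscapes and probe panels used
# across the module tests.

# single left-end origin: trep increases linearly along the chromosome,
# giving an evenly spread copy-number gradient in sorted-S material
gradient_model <- function(chrom_length = 500e3, firing_time = 10,
                           fork_speed = 1.5) {
  replication_model(chrom_length, 0, firing_time, fork_speed = fork_speed)
}

# early + late origin pair on a 400 kb chromosome, with control probes
# flanked by two target probes near the mid origin
screen_fixture <- function() {
  list(
    model = replication_model(400e3, c(5e3, 100e3, 395e3), c(5, 12, 38),
                              fork_speed = 1.5),
    probes = probe_spec(
      c("tgtL", "tgtR", "early", "late"),
      start = c(95e3, 105e3, 5e3, 395e3),
      end = c(95.2e3, 105.2e3, 5.2e3, 395.2e3),
      role = c("target", "target", "early_control", "late_control")
    ),
    target_position = 100e3
  )
}

# integer-copy panel: unique, duplicated and triplicated amplicons
integer_copy_probes <- function() {
  probe_spec(c("unique1", "unique2", "dup", "trip"),
             start = c(0, 200, 400, 600), end = c(100, 300, 500, 700),
             copies_per_haploid = c(1L, 1L, 2L, 3L))
}

# Monte-Carlo CV of the occupancy estimator over nw simulated wells
mc_estimator_cv <- function(lambda, nw = 2000, n_droplets = 20000, seed = 1) {
  wells <- with_test_seed(seed, {
    do.call(rbind, lapply(seq_len(nw), function(i) {
      simulate_droplets(lambda * 1000, n_droplets = n_droplets,
                        droplet_volume_nl = 1, replicate_id = paste0("w", i))
    }))
  })
  est <- estimate_concentration(wells)
  stats::sd(est$concentration) / mean(est$concentration)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
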