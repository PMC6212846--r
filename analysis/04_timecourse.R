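#!/usr/bin/env Rscript
# Replication kinetics through a synchronized arrest-release time course.
#
# The concentration ratio of an early- to a late-replicating control probe
# rises from ~1 in G1 toward 2 at mid-S and falls back to 1 in G2; its
# maximum marks the switch point for dual normalization (late control
# before the switch, ploidy-adjusted early control after). Boltzmann fits
# to each dual-normalized probe series give per-locus Trep.

suppressMessages(library(repliddpcr))
seed <- 4
dir.create("results", showWarnings = FALSE)

# landscape: one early and one late origin; probes spread between controls
model <- replication_model(300e3, c(9e3, 291e3), c(8, 50), fork_speed = 3)
probe_pos <- c(early_ctrl = 9e3, ars_like = 60e3, cen_like = 105e3,
               mid_late = 150e3, late_ctrl = 291e3)
probes <- probe_spec(names(probe_pos), start = probe_pos,
                     end = probe_pos + 200)
mid <- (probes$start + probes$end) / 2
trep_true <- trep_profile(model, mid)

times <- seq(0, 80, 2)
sigma <- 3  # per-cell S-entry jitter, minutes
course <- lapply(times, function(t) {
  cn <- copy_number_profile(model, population_synchronized(t, sigma), mid)
  droplets <- simulate_ddpcr_experiment(
    setNames(cn, probes$probe_id), probes, base_concentration = 1000,
    n_replicates = 2, sample_id = paste0("t", t), seed = seed * 1000 + t)
  est <- estimate_concentration(droplets)
  tapply(est$concentration, est$probe_id, mean)[probes$probe_id]
})

ratios <- vapply(course, control_ratio, numeric(1),
                 early = "early_ctrl", late = "late_ctrl")
sw <- find_switch_point(course, "early_ctrl", "late_ctrl")
dn <- dual_normalize(course, sw$index, "early_ctrl", "late_ctrl")

fits <- lapply(probes$probe_id, function(p)
  fit_boltzmann(times, dn$value[dn$probe_id == p]))
trep_hat <- vapply(fits, trep_of, numeric(1))

out <- data.frame(probe_id = probes$probe_id, position = mid,
                  trep_true = trep_true, trep_fit = signif(trep_hat, 4),
                  abs_error_min = signif(abs(trep_hat - trep_true), 3))
write.table(out, "results/timecourse_trep.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(time = times, control_ratio = signif(ratios, 5)),
            "results/timecourse_control_ratio.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_provenance("results/timecourse.provenance.json",
                 config = list(seed = seed, sigma_min = sigma,
                               sampling_min = 2, n_replicates = 2))

cat(sprintf("Peak control ratio %.2f at %d min (switch sample index %d)\n",
            max(ratios), times[sw$index], sw$index))
cat("Per-probe Trep from Boltzmann fits to dual-normalized series:\n")
print(out, row.names = FALSE)
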