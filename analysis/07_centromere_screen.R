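#!/usr/bin/env Rscript
# Screening trans-acting mutants for delayed replication at a target locus.
#
# Each strain is an independently sorted S-phase sample with its own gate
# purity, hence its own copy-number dynamic range; the replication index
# (early control -> 0, late control -> 1) removes that nuisance and makes
# the strains directly comparable. Injected firing-time delays at the
# target-proximal origin must come back as monotonically increasing
# replication indices at the two flanking probes.

suppressMessages(library(repliddpcr))
seed <- 7
dir.create("results", showWarnings = FALSE)

model <- replication_model(400e3, c(5e3, 100e3, 395e3), c(5, 12, 38),
                           fork_speed = 1.5)
probes <- probe_spec(
  c("target_left", "target_right", "early_ctrl", "late_ctrl"),
  start = c(95e3, 105e3, 5e3, 395e3) - c(0, 0, 0, 0.4e3),
  end = c(95.2e3, 105.2e3, 5.2e3, 395e3),
  role = c("target", "target", "early_control", "late_control")
)
delays <- c(wt = 0, nkp_like = 0, ctf_like_1 = 4, ctf_like_2 = 7,
            mcm_like = 10, dbf4_tag_like = 14)

droplets <- simulate_screen(model, probes, target_position = 100e3,
                            delays = delays, seed = seed)
est <- estimate_concentration(droplets)

out <- do.call(rbind, lapply(names(delays), function(strain) {
  e <- est[est$sample_id == strain, ]
  cm <- tapply(e$concentration, e$probe_id, mean)
  ri <- replication_index(cm[c("target_left", "target_right")],
                          cm[["early_ctrl"]], cm[["late_ctrl"]])
  data.frame(strain = strain, injected_delay_min = delays[[strain]],
             dynamic_range = signif(cm[["early_ctrl"]] / cm[["late_ctrl"]], 4),
             ri_left = signif(ri[1], 4), ri_right = signif(ri[2], 4),
             ri_mean = signif(mean(ri), 4))
}))
write.table(out, "results/screen_replication_index.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_provenance("results/screen.provenance.json",
                 config = list(seed = seed, n_replicates = 3,
                               target_position = 100e3))

cat("Replication indices per strain (0 = early control, 1 = late control):\n")
print(out, row.names = FALSE)
cat(sprintf("\nSpearman(RI, injected delay) = %.3f\n",
            cor(out$ri_mean, out$injected_delay_min, method = "spearman")))
cat("Strains with delayed target replication stand out despite different\n")
cat("dynamic ranges across sorted samples.\n")
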