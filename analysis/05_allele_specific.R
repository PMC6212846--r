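#!/usr/bin/env Rscript
# Allele-specific replication timing in a heterozygous diploid.
#
# A diploid heterozygous for an origin-inactivating mutation is an
# internally controlled system: allele-specific probes at the same locus
# share every condition, and the mutant/wild-type concentration ratio in
# sorted S-phase DNA reads out the replication delay directly. An origin
# flanked by an early neighbour is partially rescued by passive
# replication; an isolated origin shows the full delay.

suppressMessages(library(repliddpcr))
seed <- 5
dir.create("results", showWarnings = FALSE)

loci <- list(
  # locus with a close early neighbour origin (passive rescue expected)
  flanked = list(
    A = replication_model(400e3, c(100e3, 115e3, 395e3), c(8, 8, 30)),
    B = replication_model(400e3, c(115e3, 395e3), c(8, 30))
  ),
  # isolated origin: passive fork must travel from the late origin
  isolated = list(
    A = replication_model(400e3, c(200e3, 395e3), c(8, 30)),
    B = replication_model(400e3, 395e3, 30)
  )
)
positions <- c(flanked = 100e3, isolated = 200e3)

rows <- lapply(names(loci), function(locus) {
  pos <- positions[[locus]]
  probes <- probe_spec(
    paste0(locus, c("_wt", "_mut", "_pan")),
    start = rep(pos, 3), end = rep(pos + 200, 3),
    allele_tag = c("A", "B", NA)
  )
  dr <- simulate_allele_experiment(loci[[locus]]$A, loci[[locus]]$B,
                                   population_sorted_s(), probes,
                                   seed = seed + match(locus, names(loci)))
  est <- estimate_concentration(dr)
  conc <- function(p) est$concentration[est$probe_id == p]
  d <- allele_delay(conc(paste0(locus, "_wt")), conc(paste0(locus, "_mut")))
  data.frame(locus = locus,
             wt_conc = signif(mean(conc(paste0(locus, "_wt"))), 5),
             mut_conc = signif(mean(conc(paste0(locus, "_mut"))), 5),
             pan_conc = signif(mean(conc(paste0(locus, "_pan"))), 5),
             mut_wt_ratio = signif(d$ratio, 4),
             p_adj = signif(d$p_adj, 3),
             significant = d$significant)
})
out <- do.call(rbind, rows)
write.table(out, "results/allele_delays.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_provenance("results/allele_delays.provenance.json",
                 config = list(seed = seed, n_replicates = 3))

cat("Allele-specific replication delays (sorted S-phase sample):\n")
print(out, row.names = FALSE)
cat(sprintf("\nIsolated origin delay (1 - ratio): %.3f; flanked: %.3f — the\n",
            1 - out$mut_wt_ratio[out$locus == "isolated"],
            1 - out$mut_wt_ratio[out$locus == "flanked"]))
cat("early neighbour origin passively replicates the mutated allele and\n")
cat("cushions its delay.\n")
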