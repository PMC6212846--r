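#!/usr/bin/env Rscript
# Error model of droplet-digital quantification.
#
# Maps the analytic CV of the Poisson-corrected concentration estimator
# across occupancies and confirms it by Monte-Carlo simulation of droplet
# partitioning. Finding: the CV stays below 2.5% across a ~50-fold
# concentration range (0.11-5.73 copies/droplet, i.e. 110-5730 copies/ul
# at 1 nl droplets) and bottoms out near 1% in the 1000-2000 copies/ul
# working range, so both ends of the 1..2 replication scale can be read
# from a single dilution at minimal technical error.

suppressMessages(library(repliddpcr))
seed <- 1
dir.create("results", showWarnings = FALSE)

lambdas <- c(0.05, 0.11, 0.25, 0.5, 1, 1.6, 2, 3, 4, 5, 5.73, 7)
analytic <- cv_of_estimator(lambdas, n_droplets = 20000)

mc <- vapply(seq_along(lambdas), function(i) {
  set.seed(seed + i)
  wells <- do.call(rbind, lapply(1:2000, function(w)
    simulate_droplets(lambdas[i] * 1000, replicate_id = paste0("w", w))))
  est <- estimate_concentration(wells)$concentration
  sd(est) / mean(est)
}, numeric(1))

tab <- data.frame(
  occupancy = lambdas,
  concentration_per_ul = lambdas * 1000,
  cv_analytic = signif(analytic, 4),
  cv_monte_carlo = signif(mc, 4)
)
write.table(tab, "results/error_model.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write_provenance("results/error_model.provenance.json",
                 inputs = list(),
                 config = list(seed = seed, n_wells = 2000,
                               n_droplets = 20000))

cat("Estimator CV by occupancy (20,000 droplets/well):\n")
print(tab, row.names = FALSE)
cat(sprintf("\nCV at range boundaries (0.11, 5.73): %.2f%%, %.2f%% (< 2.5%%)\n",
            100 * analytic[lambdas == 0.11], 100 * analytic[lambdas == 5.73]))
cat(sprintf("CV in the working range (1-2 copies/droplet): %.2f-%.2f%%\n",
            100 * min(analytic[lambdas %in% c(1, 2)]),
            100 * max(analytic[lambdas %in% c(1, 2)])))
cat(sprintf("Max |MC - analytic| relative difference: %.1f%%\n",
            100 * max(abs(mc - analytic) / analytic)))
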