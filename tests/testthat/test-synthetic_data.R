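# Origin-firing model, population copy-number profiles, and simulators.

test_that("trep follows nearest-origin kinematics", {
  m <- replication_model(200e3, 100e3, firing_time = 10, fork_speed = 1)
  expect_equal(trep_profile(m, 105e3), 15)  # 5 kb at 1 kb/min
  expect_equal(trep_profile(m, 100e3), 10)  # at the origin: firing time

  # two origins: brute-force minimum over per-origin arrival times
  m2 <- replication_model(300e3, c(40e3, 220e3), c(5, 20), fork_speed = 2)
  grid <- seq(0, 299e3, 1e3)
  got <- trep_profile(m2, grid)
  want <- pmin(5 + abs(grid - 40e3) / 2000, 20 + abs(grid - 220e3) / 2000)
  expect_equal(got, want)

  expect_error(replication_model(1e5, numeric(0), numeric(0)), "origin")
  expect_error(replication_model(1e5, 2e5, 1), "within")
})

test_that("inefficient origins delay the population-median trep", {
  m_eff <- replication_model(200e3, c(50e3, 150e3), c(5, 30))
  m_ineff <- replication_model(200e3, c(50e3, 150e3), c(5, 30),
                               efficiency = c(0.3, 1))
  pos <- c(50e3, 60e3)
  expect_true(all(trep_profile(m_ineff, pos, seed = 4) >=
                    trep_profile(m_eff, pos)))
  # deterministic given the seed
  expect_equal(trep_profile(m_ineff, pos, seed = 4),
               trep_profile(m_ineff, pos, seed = 4))
})

test_that("population copy-number profiles respect their bounds", {
  m <- replication_model(400e3, c(50e3, 350e3), c(5, 25), fork_speed = 1.5)
  pos <- seq(0, 399e3, 2e3)

  # synchronized: before S entry everything ~1, long after ~2
  expect_equal(copy_number_profile(m, population_synchronized(0, 1), pos),
               rep(1, length(pos)), tolerance = 1e-4)
  expect_equal(copy_number_profile(m, population_synchronized(500, 1), pos),
               rep(2, length(pos)), tolerance = 1e-4)
  # degenerate sigma = 0: step function
  step <- copy_number_profile(m, population_synchronized(20, 0), pos)
  expect_true(all(step %in% c(1, 2)))

  for (pop in list(population_synchronized(25, 3),
                   population_sorted_s(0.05, 0.05),
                   population_asynchronous(0.3, 0.1))) {
    cn <- copy_number_profile(m, pop, pos)
    expect_true(all(cn >= 1 - 1e-9 & cn <= 2 + 1e-9))
  }

  # sorted-S: latest-replicating position reads exactly 1
  cn_s <- copy_number_profile(m, population_sorted_s(0.05, 0.05), pos)
  expect_equal(min(cn_s), 1)
})

test_that("asynchronous dynamic range equals 1 + S-phase fraction", {
  m <- replication_model(400e3, c(50e3, 350e3), c(5, 25), fork_speed = 1.5)
  pos <- seq(0, 399e3, 1e3)
  cn <- copy_number_profile(m, population_asynchronous(0.2), pos)
  expect_identical(min(cn), 1)
  expect_identical(max(cn), 1.2)
})

test_that("droplet simulation matches the binomial partitioning model", {
  expect_equal(simulate_droplets(0, seed = 1)$n_positive, 0)
  expect_error(simulate_droplets(-1), ">= 0")

  # determinism given the seed
  expect_identical(simulate_droplets(1000, seed = 12)$n_positive,
                   simulate_droplets(1000, seed = 12)$n_positive)

  # lambda = 1: mean positive fraction over wells ~ 1 - exp(-1)
  frac <- with_test_seed(6, replicate(1000, {
    w <- simulate_droplets(1000, n_droplets = 20000)
    w$n_positive / w$n_total
  }))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - (1 - exp(-1))), 3 * se)

  # round-trip through the estimator is unbiased at both range ends
  for (lam in c(0.11, 5.73)) {
    est <- with_test_seed(7, replicate(500, {
      estimate_concentration(simulate_droplets(lam * 1000))$concentration
    }))
    expect_lt(abs(mean(est) - lam * 1000), 3 * sd(est) / sqrt(length(est)))
  }
})

test_that("simulated ddPCR experiments reproduce the input copy numbers", {
  pr <- integer_copy_probes()
  dr <- simulate_ddpcr_experiment(
    c(unique1 = 1, unique2 = 1, dup = 1, trip = 1), pr, seed = 31)
  expect_equal(nrow(dr), 4 * 3)

  # equal copy number: per-probe replicate means mutually consistent
  est <- estimate_concentration(dr)
  u1 <- replicate_ci(est[est$probe_id == "unique1", ])
  u2 <- replicate_ci(est[est$probe_id == "unique2", ])
  expect_true(u1$ci_low <= u2$ci_high && u2$ci_low <= u1$ci_high)

  # mid-S landscape: early probes at about twice the late concentration
  m <- replication_model(300e3, 50e3, firing_time = 10, fork_speed = 1.5)
  cn <- copy_number_profile(m, population_synchronized(25, 3),
                            c(50e3, 280e3))
  pr2 <- probe_spec(c("early", "late"), start = c(50e3, 280e3),
                    end = c(50.2e3, 280.2e3))
  dr2 <- simulate_ddpcr_experiment(c(early = cn[1], late = cn[2]), pr2,
                                   seed = 32)
  est2 <- estimate_concentration(dr2)
  cm <- tapply(est2$concentration, est2$probe_id, mean)
  expect_equal(unname(cm["early"] / cm["late"]), 2, tolerance = 0.05)

  expect_warning(
    simulate_ddpcr_experiment(c(unique1 = 3, unique2 = 1, dup = 1, trip = 1),
                              pr, base_concentration = 3000, seed = 2),
    "occupancy")
})

test_that("sequencing-count simulation hits the calibrated noise level", {
  # default overdispersion: ~5% CV at 1000 reads/bin
  cnt <- simulate_sortseq_counts(rep(1, 10000), mean_depth = 1000, seed = 41)
  expect_equal(sd(cnt$nonRep) / mean(cnt$nonRep), 0.05, tolerance = 0.1)

  # Poisson limit: CV = 1/sqrt(1000) ~ 3.2%
  cnt_p <- simulate_sortseq_counts(rep(1, 10000), mean_depth = 1000,
                                   size = Inf, seed = 42)
  expect_equal(sd(cnt_p$nonRep) / mean(cnt_p$nonRep), 1 / sqrt(1000),
               tolerance = 0.1)

  # copy number 2 bins hold twice the replicating reads on average
  cnt2 <- simulate_sortseq_counts(rep(c(1, 2), each = 5000), seed = 43)
  expect_equal(mean(cnt2$rep[5001:10000]) / mean(cnt2$rep[1:5000]), 2,
               tolerance = 0.02)
})

test_that("allele-specific simulation separates haplotypes additively", {
  hapA <- replication_model(400e3, c(100e3, 395e3), c(8, 30), fork_speed = 1.5)
  probes <- probe_spec(
    c("A_probe", "B_probe", "pan"),
    start = rep(100e3, 3), end = rep(100.2e3, 3),
    allele_tag = c("A", "B", NA)
  )
  # identical haplotypes: alleles statistically indistinguishable
  dr <- simulate_allele_experiment(hapA, hapA, population_sorted_s(),
                                   probes, seed = 51)
  est <- estimate_concentration(dr)
  cm <- tapply(est$concentration, est$probe_id, mean)
  expect_equal(unname(cm["B_probe"] / cm["A_probe"]), 1, tolerance = 0.02)
  # pan-allelic probe reads the sum of the two allele concentrations
  expect_equal(unname(cm["pan"]), unname(cm["A_probe"] + cm["B_probe"]),
               tolerance = 0.03)

  # inactivated origin on haplotype B: B probe lower in S-sorted material
  hapB <- replication_model(400e3, 395e3, 30, fork_speed = 1.5)
  dr2 <- simulate_allele_experiment(hapA, hapB, population_sorted_s(),
                                    probes, seed = 52)
  est2 <- estimate_concentration(dr2)
  cm2 <- tapply(est2$concentration, est2$probe_id, mean)
  expect_lt(cm2[["B_probe"]], cm2[["A_probe"]])

  bad <- probes; bad$allele_tag[1] <- "Z"
  expect_error(simulate_allele_experiment(hapA, hapB, population_sorted_s(),
                                          bad), "allele_tag")
})

test_that("screen simulation recovers injected delays as RI rank order", {
  fx <- screen_fixture()
  delays <- c(wt = 0, null_mut = 0, m1 = 4, m2 = 8, m3 = 12, m4 = 16, m5 = 20)
  dr <- simulate_screen(fx$model, fx$probes, fx$target_position, delays,
                        seed = 42)
  est <- estimate_concentration(dr)
  ri <- vapply(names(delays), function(st) {
    e <- est[est$sample_id == st, ]
    cm <- tapply(e$concentration, e$probe_id, mean)
    mean(replication_index(cm[c("tgtL", "tgtR")], cm[["early"]],
                           cm[["late"]]))
  }, numeric(1))

  # zero-delay strain is indistinguishable from wild type
  expect_lt(abs(ri[["null_mut"]] - ri[["wt"]]), 0.05)
  # delayed strains move the index up; rank order matches injected delays
  expect_true(all(ri[c("m1", "m2", "m3", "m4", "m5")] > ri[["wt"]]))
  expect_gte(cor(ri[-2], delays[-2], method = "spearman"), 0.95)

  # controls are unaffected by the targeted delay
  ctrl_ratio <- vapply(c("wt", "m5"), function(st) {
    e <- est[est$sample_id == st, ]
    cm <- tapply(e$concentration, e$probe_id, mean)
    cm[["early"]] / cm[["late"]]
  }, numeric(1))
  expect_equal(unname(ctrl_ratio["m5"] / ctrl_ratio["wt"]), 1,
               tolerance = 0.1)
})
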