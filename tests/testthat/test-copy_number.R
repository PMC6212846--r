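# Baseline normalization, dual normalization, replication index.

test_that("copy-adjusted baseline normalization recovers integer ratios", {
  pr <- integer_copy_probes()
  # equal unique concentrations: everything reads 1
  pr_u <- probe_spec(c("a", "b", "c"), start = c(0, 200, 400),
                     end = c(100, 300, 500))
  v <- baseline_normalize(c(a = 7, b = 7, c = 7), pr_u)
  expect_equal(v$value, c(1, 1, 1))

  # copy-adjusted baseline: mean(10,10,10,10) = 10, values 1:1:2:3
  v2 <- baseline_normalize(c(unique1 = 10, unique2 = 10, dup = 20, trip = 30), pr)
  expect_equal(v2$value, c(1, 1, 2, 3))

  # invariant to the units of the input concentrations
  v3 <- baseline_normalize(
    c(unique1 = 10, unique2 = 10, dup = 20, trip = 30) * 1e3, pr)
  expect_equal(v3$value, v2$value)

  expect_error(baseline_normalize(c(unique1 = 10), pr), "no concentration")
  expect_error(baseline_normalize(numeric(0), pr), "no concentrations")
})

test_that("simulated G2 diploid recovers the 1:2:3 probe ratio", {
  pr <- integer_copy_probes()
  dr <- simulate_ddpcr_experiment(
    c(unique1 = 1, unique2 = 1, dup = 1, trip = 1), pr, seed = 101)
  est <- estimate_concentration(dr)
  conc <- tapply(est$concentration, est$probe_id, mean)
  v <- baseline_normalize(conc, pr)
  expect_equal(v$value[v$probe_id == "dup"] / v$value[v$probe_id == "unique1"],
               2, tolerance = 0.02)
  expect_equal(v$value[v$probe_id == "trip"] / v$value[v$probe_id == "unique1"],
               3, tolerance = 0.02)
})

test_that("control ratio behaves across the cell cycle", {
  # G1: both controls unreplicated
  expect_equal(control_ratio(c(e = 1000, l = 1000), "e", "l"), 1)
  # early fully replicated, late not started
  expect_equal(control_ratio(c(e = 2000, l = 1000), "e", "l"), 2)
  expect_error(control_ratio(c(e = 1000), "e", "l"), "missing")
  expect_error(control_ratio(c(e = 1, l = 0), "e", "l"), "zero")

  # imperfect synchrony keeps the peak ratio below 2
  times <- seq(0, 70, 2)
  ratios <- (1 + pnorm((times - 30) / 4)) / (1 + pnorm((times - 42) / 4))
  expect_lt(max(ratios), 2)
  expect_gt(max(ratios), 1.5)
})

test_that("switch point is the argmax of the control ratio", {
  mk <- function(r) lapply(r, function(x) c(e = 1000 * x, l = 1000))
  sw <- find_switch_point(mk(c(1, 1.4, 1.9, 1.6, 1.1)), "e", "l")
  expect_equal(sw$index, 3)  # third sample (0-based index 2)
  expect_false(sw$degenerate)

  sw2 <- find_switch_point(mk(c(1.2, 1.2, 1.2)), "e", "l")
  expect_equal(sw2$index, 1)  # tie broken toward the earlier sample
  expect_true(sw2$degenerate)
  expect_error(find_switch_point(mk(c(1, 2)), "e", "l"), ">= 3")
})

test_that("switch time tracks completion of the early control locus", {
  # synchronized course, sigma = 3 min, sampled every 2 min
  sigma <- 3
  trep <- c(e = 30, l = 42, p = 36)
  times <- seq(0, 70, 2)
  course <- lapply(times, function(t) 1000 * (1 + pnorm((t - trep) / sigma)))
  sw <- find_switch_point(course, "e", "l")
  t95 <- 30 + qnorm(0.95) * sigma  # early locus >= 95% replicated
  expect_lte(abs(times[sw$index] - t95), 2)
})

test_that("dual normalization is continuous and recovers probe kinetics", {
  sigma <- 3
  trep <- c(e = 10, p1 = 25, p2 = 40, l = 55)
  times <- seq(0, 70, 2)
  course <- lapply(times, function(t)
    1000 * (1 + pnorm((t - trep) / sigma)))
  names(course) <- paste0("t", times)

  # G1 point: everything reads 1
  g1 <- dual_normalize(course[1], switch = 1, early = "e", late = "l")
  expect_equal(g1$value, rep(1, 4), tolerance = 1e-3)

  sw <- find_switch_point(course, "e", "l")$index
  dn <- dual_normalize(course, sw, early = "e", late = "l")

  # post-switch sample where the probe equals the early control reads 2
  last <- dn[dn$time_index == length(times) & dn$probe_id == "p1", ]
  expect_equal(last$value, 2, tolerance = 1e-3)

  # noise-free: values within [1, 2] and non-decreasing for every probe
  for (pid in names(trep)) {
    v <- dn$value[dn$probe_id == pid]
    expect_true(all(v >= 1 - 1e-9 & v <= 2 + 1e-9))
    expect_true(all(diff(v) >= -1e-9))
  }

  # Boltzmann midpoint of each normalized probe series recovers trep
  for (pid in c("p1", "p2")) {
    fit <- fit_boltzmann(times, dn$value[dn$probe_id == pid])
    expect_lt(abs(trep_of(fit) - trep[[pid]]), 1.5)
  }
})

test_that("replication index maps controls to 0/1 and is scale invariant", {
  expect_equal(replication_index(2000, 2000, 1000), 0)
  expect_equal(replication_index(1000, 2000, 1000), 1)
  expect_equal(replication_index(1500, 2000, 1000), 0.5)
  expect_error(replication_index(1500, 1000, 2000), "degenerate")

  # invariance under multiplicative rescaling of all three concentrations
  for (s in c(0.1, 3.7, 42)) {
    expect_equal(replication_index(1400 * s, 1900 * s, 1100 * s),
                 replication_index(1400, 1900, 1100))
  }
})

test_that("RI ordering matches true replication-time ordering", {
  fx <- screen_fixture()
  pos <- seq(10e3, 390e3, 20e3)
  trep <- trep_profile(fx$model, pos)
  cn <- copy_number_profile(fx$model, population_sorted_s(0.05, 0.05), pos)
  c_early <- max(cn); c_late <- min(cn)
  ri <- replication_index(cn, c_early + 1e-9, c_late - 1e-9)
  expect_equal(cor(ri, trep, method = "spearman"), 1)
})

test_that("allele-specific delay is detected at an inactivated origin", {
  # haplotype A: active origin at 100 kb; haplotype B: that origin lost,
  # locus passively replicated from a distant late origin
  hapA <- replication_model(400e3, c(100e3, 395e3), c(8, 30), fork_speed = 1.5)
  hapB <- replication_model(400e3, 395e3, 30, fork_speed = 1.5)
  probes <- probe_spec(
    c("ori_wt", "ori_mut", "pan_early", "pan_late"),
    start = c(100e3, 100e3, 5e3, 380e3),
    end = c(100.2e3, 100.2e3, 5.2e3, 380.2e3),
    allele_tag = c("A", "B", NA, NA),
    role = c("target", "target", "target", "target")
  )
  dr <- simulate_allele_experiment(hapA, hapB, population_sorted_s(),
                                   probes, seed = 7)
  est <- estimate_concentration(dr)
  conc <- function(p) est$concentration[est$probe_id == p]
  d <- allele_delay(conc("ori_wt"), conc("ori_mut"))
  expect_lt(d$ratio, 1)
  expect_true(d$significant)

  # identical alleles: ratio ~1
  d0 <- allele_delay(c(1000, 1010, 990), c(1005, 995, 1000))
  expect_equal(d0$ratio, 1, tolerance = 0.01)
  expect_false(d0$significant)
})

test_that("a proximal early origin cushions the delay of an inactivated origin", {
  # isolated inactivated origin: nearest alternative fork is far away
  hapA_iso <- replication_model(400e3, c(100e3, 395e3), c(8, 30), fork_speed = 1.5)
  hapB_iso <- replication_model(400e3, 395e3, 30, fork_speed = 1.5)
  # flanked: an equally early neighbour origin 15 kb away rescues the locus
  hapA_fl <- replication_model(400e3, c(100e3, 115e3, 395e3), c(8, 8, 30),
                               fork_speed = 1.5)
  hapB_fl <- replication_model(400e3, c(115e3, 395e3), c(8, 30),
                               fork_speed = 1.5)
  # replicated fraction of S cells at the locus, on the shared S progression
  cn_at <- function(hapA, hapB) {
    grid <- seq(0, 399e3, 1e3)
    tr <- range(c(trep_profile(hapA, grid), trep_profile(hapB, grid)))
    q <- function(hap) {
      tp <- trep_profile(hap, 100e3)
      (tr[2] - tp) / (tr[2] - tr[1])
    }
    c(A = q(hapA), B = q(hapB))
  }
  iso <- cn_at(hapA_iso, hapB_iso)
  fl <- cn_at(hapA_fl, hapB_fl)
  expect_lt(iso[["B"]], iso[["A"]])
  expect_lt(fl[["A"]] - fl[["B"]], iso[["A"]] - iso[["B"]])
})
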