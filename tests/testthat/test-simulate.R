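test_that("haplotype frequencies follow the D' parameterization", {
  f <- hap_freqs_from_ld(0.2, 0.3, 0)
  expect_equal(unname(f["AB"]), 0.06)
  expect_equal(sum(f), 1)
  # pA = pB = 0.2, D' = 0.8: Dmax = 0.16, fAB = 0.04 + 0.8 * 0.16
  f2 <- hap_freqs_from_ld(0.2, 0.2, 0.8)
  expect_equal(unname(f2["AB"]), 0.168)
  # round-trip D' over a grid, both signs
  for (pA in c(0.05, 0.2, 0.5)) for (pB in c(0.1, 0.4, 0.8))
    for (dp in c(-0.5, 0, 0.3, 0.8, 1)) {
      fr <- hap_freqs_from_ld(pA, pB, dp)
      expect_true(all(fr >= 0))
      expect_equal(dprime_from_freqs(fr), dp, tolerance = 1e-12)
      expect_equal(unname(fr["AB"] + fr["Ab"]), pA, tolerance = 1e-12)
      expect_equal(unname(fr["AB"] + fr["aB"]), pB, tolerance = 1e-12)
    }
})

test_that("cohort sampling is HWE-consistent and seed-deterministic", {
  f <- hap_freqs_from_ld(0.2, 0.3, 0)
  d1 <- sample_cohort(f, 500, seed = 301)
  d2 <- sample_cohort(f, 500, seed = 301)
  expect_identical(d1, d2)
  big <- sample_cohort(f, 1e5, seed = 302)
  pt <- phasetypes(big)
  # E[GA] = 2 pA; 3 binomial SEs
  se <- sqrt(2 * 0.2 * 0.8 / 1e5)
  expect_lt(abs(mean(pt[, "GA"]) - 0.4), 3 * se)
  # degenerate frequencies give a constant cohort
  dd <- sample_cohort(c(AB = 0, aB = 0, Ab = 0, ab = 1), 50, seed = 303)
  expect_true(all(diplotype_labels(dd) == "ab/ab"))
})

test_that("continuous phenotypes follow the scenario's linear model", {
  sc <- sim_scenario("additive_cis_cont", sigma = 1e-12)
  d <- sample_cohort(sc$freqs, 200, seed = 304)
  sim <- simulate_phenotype(sc, d)
  expect_equal(sim$response, -2 + 1.5 * phasetypes(d)[, "CisAB"],
               tolerance = 1e-9, ignore_attr = TRUE)
  # dominant generator: identical linear predictor for GA = 1 and GA = 2
  scd <- sim_scenario("t1e_dominant_A")
  pt <- phasetypes(all_diplotypes())
  eta <- scd$eta(pt, scd)
  expect_equal(unique(eta[pt[, "GA"] >= 1]), unique(eta[pt[, "GA"] == 2]))
})

test_that("binary phenotype generation hits exact group sizes", {
  sc <- sim_scenario("pow_additive_cis", n_cases = 150, n_controls = 250)
  set.seed(305)
  sim <- simulate_phenotype(sc)
  expect_equal(sum(sim$response == 1), 150)
  expect_equal(sum(sim$response == 0), 250)
  expect_equal(nrow(sim$diplotypes), 400)
  # pathologically certain outcome cannot fill the control group
  sc2 <- sim_scenario("t1e_additive_A", beta0 = 40, n_cases = 5,
                      n_controls = 5)
  set.seed(306)
  expect_error(simulate_phenotype(sc2), "rejection sampling")
})

test_that("switch errors flip only double heterozygotes", {
  labs <- c("AB/ab", "Ab/aB", "ab/ab", "AB/AB", "Ab/ab", "AB/aB")
  d <- do.call(rbind, lapply(rep(labs, 20), diplotype_from_label))
  class(d) <- c("diplotype_set", "data.frame")
  expect_identical(inject_switch_errors(d, 0), d)
  flipped <- inject_switch_errors(d, 1, seed = 307)
  lab_f <- diplotype_labels(flipped)
  lab_0 <- diplotype_labels(d)
  dh <- lab_0 %in% c("AB/ab", "Ab/aB")
  expect_true(all(lab_f[lab_0 == "AB/ab"] == "Ab/aB"))
  expect_true(all(lab_f[lab_0 == "Ab/aB"] == "AB/ab"))
  expect_identical(lab_f[!dh], lab_0[!dh])
  # genotypes never change
  expect_equal(phasetypes(flipped)[, c("GA", "GB")],
               phasetypes(d)[, c("GA", "GB")])
  expect_error(inject_switch_errors(d, 1.2), "rate")
  # intermediate rate flips about the right share
  many <- do.call(rbind, lapply(rep("AB/ab", 2000), diplotype_from_label))
  class(many) <- c("diplotype_set", "data.frame")
  part <- inject_switch_errors(many, 0.3, seed = 308)
  share <- mean(diplotype_labels(part) == "Ab/aB")
  expect_lt(abs(share - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("heritability calibration round-trips exactly and empirically", {
  f <- hap_freqs_from_ld(0.2, 0.2, 0)
  expect_equal(h2_to_effect(0, f), 0)
  for (h2 in c(0.003, 0.01, 0.2)) {
    b <- h2_to_effect(h2, f, term = "CisAB", sigma = 1)
    v <- phasereg:::population_term_variance(f, "CisAB")
    expect_equal(b^2 * v / (b^2 * v + 1), h2, tolerance = 1e-12)
  }
  # empirical check on a large simulated cohort
  b <- h2_to_effect(0.01, f, term = "CisAB")
  d <- sample_cohort(f, 1e5, seed = 309)
  g <- b * phasetypes(d)[, "CisAB"]
  set.seed(310)
  y <- g + rnorm(1e5)
  expect_equal(var(g) / var(y), 0.01, tolerance = 0.15)
})

test_that("diplotype probabilities sum to one and match sampling", {
  f <- hap_freqs_from_ld(0.3, 0.25, 0.4)
  dp <- diplotype_probs(f)
  expect_equal(sum(dp$prob), 1)
  d <- sample_cohort(f, 2e4, seed = 311)
  emp <- table(factor(diplotype_labels(d),
                      levels = diplotype_labels(dp$diplotypes)))
  expect_lt(max(abs(emp / 2e4 - dp$prob)), 0.012)
})

test_that("estimate_rates is reproducible and tracks failures", {
  sc <- sim_scenario("t1e_additive_A", n_cases = 120, n_controls = 120,
                     n_iter = 8)
  r1 <- estimate_rates(sc, tests = c("rop_cis", "rop_trans"), seed = 9)
  r2 <- estimate_rates(sc, tests = c("rop_cis", "rop_trans"), seed = 9)
  expect_equal(r1$rate, r2$rate)
  expect_true(all(r1$rate >= 0 & r1$rate <= 1))
  expect_equal(r1$mc_se,
               sqrt(r1$rate * (1 - r1$rate) / (r1$n_iter - r1$n_failed)))
  # a rare haplotype makes the OR test fail in some iterations without
  # derailing the summary
  sc2 <- sim_scenario("t1e_additive_A", pA = 0.02, pB = 0.02, dprime = 0.9,
                      n_cases = 60, n_controls = 60, n_iter = 6)
  r3 <- estimate_rates(sc2, tests = "or_test", seed = 10)
  expect_true(r3$n_failed >= 0)
})

test_that("conditional adjustment helps without LD and the null is clean", {
  # allelic heterogeneity, no LD: adjusting for SNP A sharpens the SNP B
  # test; with a null model everything sits near the nominal level
  sc <- sim_scenario("het", pA = 0.2, pB = 0.3, dprime = 0, n = 400,
                     n_iter = 150)
  r <- conditional_power_experiment(sc, seed = 11)
  rb <- function(nm) r$rate[r$test == nm]
  expect_gte(rb("snpB_conditional") + 0.02, rb("snpB_unconditional"))
  expect_gt(rb("snpB_conditional"), 0.5)
  # phase tests stay near nominal under allelic heterogeneity
  band <- 3 * sqrt(0.05 * 0.95 / 150)
  expect_lt(abs(rb("rop_cis") - 0.05), band + 0.02)
  expect_lt(abs(rb("rop_trans") - 0.05), band + 0.02)
  sc0 <- sim_scenario("het", betaG = 0, n = 300, n_iter = 150)
  r0 <- conditional_power_experiment(sc0, seed = 12)
  expect_true(all(abs(r0$rate - 0.05) < band + 0.03))
})

test_that("LD reshapes phase-test power as expected (analytic route)", {
  # rare-rare cis: LD helps
  rr <- power_ratio_surface(0.05, 0.05, effect = "cis", method = "analytic")
  expect_gt(rr$ratio, 1)
  # equal common frequencies, trans: LD hurts
  tt <- power_ratio_surface(0.3, 0.3, effect = "trans", method = "analytic")
  expect_lt(tt$ratio, 1)
  # saturation: large effect, both powers ~ 1
  st <- power_ratio_surface(0.3, 0.3, effect = "cis", method = "analytic",
                            betaP = 4, sigma = 0.5)
  expect_equal(st$ratio, 1, tolerance = 0.01)
  # analytic and simulated power agree on one cell
  sim <- power_ratio_surface(0.2, 0.3, effect = "cis",
                             method = "simulation", n_iter = 300, seed = 13)
  ana <- power_ratio_surface(0.2, 0.3, effect = "cis", method = "analytic")
  expect_lt(abs(sim$power_d1 - ana$power_d1), 0.1)
  expect_lt(abs(sim$power_d2 - ana$power_d2), 0.1)
})

test_that("scenario configs load from YAML and JSON", {
  cfg <- list(model = "pow_additive_cis", pA = 0.1, pB = 0.25,
              dprime = 0.8, n_cases = 50, n_controls = 70, n_iter = 3)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  s1 <- read_scenario(yml)
  expect_equal(s1$model, "pow_additive_cis")
  expect_equal(s1$pA, 0.1)
  expect_equal(s1$n_controls, 70)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, js, auto_unbox = TRUE)
  s2 <- read_scenario(js)
  expect_equal(s2$freqs, s1$freqs)
  expect_error(read_scenario(tempfile(fileext = ".txt")), "format")
})
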