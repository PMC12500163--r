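test_that("phase test statistics match an independent glm/anova refit", {
  d <- fixed_cohort(200, seed = 11)
  set.seed(12)
  y_g <- rnorm(200)                       # no phase effect
  y_b <- rbinom(200, 1, 0.4)
  X <- rop_design_of(d)
  for (fam in c("gaussian", "binomial")) {
    y <- if (fam == "gaussian") y_g else y_b
    for (tt in c("LRT", "score", "Wald")) {
      # the score oracle reaches the same statistic through anova.glm's
      # one-step route, which agrees less tightly than a shared refit
      tol <- if (tt == "score") 1e-6 else 1e-8
      m <- rop(y, d, family = fam, test = tt)
      oc <- oracle_drop_test(y, X, "Pcis", fam, tt)
      ot <- oracle_drop_test(y, X, "Ptrans", fam, tt)
      expect_lt(abs(m$cis$p_value - oc$p), tol)
      expect_lt(abs(m$trans$p_value - ot$p), tol)
      expect_lt(abs(m$cis$statistic - oc$statistic),
                tol * max(1, oc$statistic))
      expect_equal(m$cis$df, 1L)
      expect_equal(m$trans$df, 1L)
    }
  }
})

test_that("test statistics are invariant to the reference-allele coding", {
  refs <- c("AB", "aB", "Ab", "ab")
  for (s in 1:3) {
    d <- fixed_cohort(300, pA = 0.25, pB = 0.35, dprime = 0.4, seed = 100 + s)
    set.seed(200 + s)
    pt <- phasetypes(d)
    y_g <- 0.3 * pt[, "CisAB"] + rnorm(300)
    y_b <- rbinom(300, 1, plogis(-1 + 0.4 * pt[, "TransAB"]))
    for (fam in c("gaussian", "binomial")) {
      y <- if (fam == "gaussian") y_g else y_b
      base <- rop(y, d, family = fam)
      for (pc in refs) for (ptr in refs) {
        m <- rop(y, d, family = fam, pcis = pc, ptrans = ptr)
        expect_equal(m$cis$statistic, base$cis$statistic, tolerance = 1e-8)
        expect_equal(m$trans$statistic, base$trans$statistic,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("phase coefficient obeys the sign law under reference recoding", {
  d <- fixed_cohort(500, seed = 21)
  set.seed(22)
  y <- 0.6 * phasetypes(d)[, "CisAB"] + rnorm(500)
  b_AB <- coef(rop(y, d, pcis = "AB"))["Pcis"]
  # Cis_ab is an affine shift of Cis_AB: identical coefficient
  expect_equal(unname(coef(rop(y, d, pcis = "ab"))["Pcis"]), unname(b_AB),
               tolerance = 1e-8)
  # Cis_aB = GB - Cis_AB and Cis_Ab = GA - Cis_AB: sign flips exactly
  expect_equal(unname(coef(rop(y, d, pcis = "aB"))["Pcis"]), -unname(b_AB),
               tolerance = 1e-8)
  expect_equal(unname(coef(rop(y, d, pcis = "Ab"))["Pcis"]), -unname(b_AB),
               tolerance = 1e-8)
})

test_that("fitted values do not depend on the reference coding", {
  d <- fixed_cohort(250, seed = 31)
  set.seed(32)
  y <- rbinom(250, 1, plogis(-0.5 + 0.5 * phasetypes(d)[, "CisAB"]))
  f1 <- fitted(rop(y, d, family = "binomial"))
  f2 <- fitted(rop(y, d, family = "binomial", pcis = "Ab", ptrans = "ab"))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("degenerate cohorts are rejected", {
  d <- diplotype_set(a1 = c(rep(0, 9), 1), b1 = rep(0, 10),
                     a2 = rep(0, 10), b2 = rep(0, 10))  # ab/ab + one Ab/ab
  expect_error(rop(rnorm(10), d), "degenerate")
  expect_error(rop(rnorm(5), fixed_cohort(10)), "different lengths")
})

test_that("samples with missing phase or phenotype are dropped with a count", {
  d <- fixed_cohort(120, seed = 41)
  d$a1[1:5] <- NA
  set.seed(42)
  y <- rnorm(120); y[6:8] <- NA
  m <- rop(y, d)
  expect_equal(m$n_dropped, 8L)
  expect_equal(m$n, 112L)
})

test_that("an absent haplotype makes the cis term inestimable, not dropped", {
  # D' = 1 with pA = 0.05 < pB = 0.25 removes the Ab haplotype, so
  # CisAB == GA in every individual
  freqs <- hap_freqs_from_ld(0.05, 0.25, 1)
  expect_equal(unname(freqs["Ab"]), 0)
  d <- sample_cohort(freqs, 400, seed = 51)
  pt <- phasetypes(d)
  expect_true(all(pt[, "CisAB"] == pt[, "GA"]))
  set.seed(52)
  y <- rnorm(400)
  m <- rop(y, d)
  expect_equal(m$cis$status, "inestimable")
  expect_true(is.na(m$cis$p_value))
  expect_equal(m$trans$status, "ok")
  rep <- estimability_report(rop_design_of(d))
  expect_false(rep$estimable[rep$term == "Pcis"])
  expect_match(rep$aliased_with[rep$term == "Pcis"], "GA")
  expect_true(rep$estimable[rep$term == "Ptrans"])
})

test_that("an all-zero phase column is aliased with the intercept", {
  d <- fixed_cohort(200, seed = 61)
  X <- rop_design_of(d)
  X[, "Pcis"] <- 0
  rep <- estimability_report(X)
  expect_false(rep$estimable[rep$term == "Pcis"])
})

test_that("multi-allelic joint tests have (m-1)(n-1) df and match the oracle", {
  set.seed(71)
  n <- 500
  hA1 <- sample(c("A1", "A2", "A3"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  hA2 <- sample(c("A1", "A2", "A3"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  hB1 <- sample(c("B1", "B2", "B3"), n, TRUE, prob = c(0.6, 0.25, 0.15))
  hB2 <- sample(c("B1", "B2", "B3"), n, TRUE, prob = c(0.6, 0.25, 0.15))
  y <- rnorm(n)
  mc <- multiallelic_phasetypes(hA1, hB1, hA2, hB2,
                                allelesA = c("A1", "A2", "A3"),
                                allelesB = c("B1", "B2", "B3"),
                                ref = "first")
  m <- rop_multiallelic(y, mc)
  expect_equal(m$cis$df, 4L)
  expect_equal(m$trans$df, 4L)
  oc <- oracle_drop_test(y, m$fit$X, grep("^cis\\.", colnames(m$fit$X),
                                          value = TRUE), "gaussian", "LRT")
  expect_equal(m$cis$p_value, oc$p, tolerance = 1e-8)
  # m = 3, n = 2
  mc2 <- multiallelic_phasetypes(hA1, ifelse(hB1 == "B3", "B1", hB1),
                                 hA2, ifelse(hB2 == "B3", "B1", hB2),
                                 allelesA = c("A1", "A2", "A3"),
                                 allelesB = c("B1", "B2"), ref = "first")
  m2 <- rop_multiallelic(y, mc2)
  expect_equal(m2$cis$df, 2L)
  # m = n = 2 reduces to the biallelic statistic
  d <- fixed_cohort(300, seed = 72)
  lab <- function(x, one, zero) ifelse(x == 1L, one, zero)
  mc3 <- multiallelic_phasetypes(lab(d$a1, "A", "a"), lab(d$b1, "B", "b"),
                                 lab(d$a2, "A", "a"), lab(d$b2, "B", "b"),
                                 allelesA = c("a", "A"),
                                 allelesB = c("b", "B"), ref = "first")
  set.seed(73)
  y3 <- rnorm(300)
  m3 <- rop_multiallelic(y3, mc3)
  b3 <- rop(y3, d)
  expect_equal(m3$cis$df, 1L)
  expect_equal(m3$cis$statistic, b3$cis$statistic, tolerance = 1e-8)
  expect_equal(m3$trans$statistic, b3$trans$statistic, tolerance = 1e-8)
})

test_that("recessive cis test is a 2-df joint test with Dcis = 1(Pcis == 1)", {
  pt <- phasetypes(all_diplotypes())
  expect_equal(as.integer(pt[, "CisAB"] == 1L),
               c(0, 0, 0, 1, 0, 0, 0, 1, 1, 0))
  d <- fixed_cohort(400, seed = 81)
  set.seed(82)
  y <- rnorm(400)
  for (mv in 1:2) {
    r <- recessive_cis_test(y, d, model_variant = mv)
    expect_equal(r$df, 2L)
    Pcis <- phasetypes(d)[, "CisAB"]
    X <- rop_design_of(d)[, c("(Intercept)", "GA", "DA", "GB", "DB")]
    X <- cbind(X, Pcis = Pcis, Dcis = as.integer(Pcis == 1))
    if (mv == 1) {
      Ptr <- phasetypes(d)[, "TransAB"]
      X <- cbind(X, Ptrans = Ptr, Dtrans = as.integer(Ptr == 1))
    }
    oc <- oracle_drop_test(y, X, c("Pcis", "Dcis"), "gaussian", "LRT")
    expect_equal(r$p_value, oc$p, tolerance = 1e-8)
  }
})

test_that("covariates enter additively and affect the tests", {
  d <- fixed_cohort(300, seed = 91)
  set.seed(92)
  z <- rnorm(300)
  y <- 1.5 * z + rnorm(300)
  m_adj <- rop(y, d, covariates = data.frame(z = z))
  X <- cbind(rop_design_of(d)[, 1:5], z = z,
             rop_design_of(d)[, c("Pcis", "Ptrans")])
  oc <- oracle_drop_test(y, X, "Pcis", "gaussian", "LRT")
  expect_equal(m_adj$cis$p_value, oc$p, tolerance = 1e-8)
  expect_true("z" %in% names(coef(m_adj)))
})

test_that("rop methods: predict, residuals, simulate, summary are coherent", {
  d <- fixed_cohort(150, seed = 101)
  set.seed(102)
  y <- 0.5 * phasetypes(d)[, "CisAB"] + rnorm(150)
  m <- rop(y, d)
  expect_equal(predict(m), fitted(m))
  expect_equal(predict(m, newdata = list(diplotypes = d)), unname(fitted(m)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(residuals(m, type = "response"), y - fitted(m))
  sim <- simulate(m, nsim = 3, seed = 9)
  expect_equal(dim(sim), c(150L, 3L))
  s <- summary(m)
  expect_s3_class(s, "summary.rop")
  expect_true(all(c("Pcis", "Ptrans") %in% rownames(s$coefficients)))
  expect_output(print(m), "RoP cis")
})

test_that("logistic intercept of -2 corresponds to prevalence 0.12", {
  set.seed(111)
  y <- rbinom(50000, 1, plogis(-2))
  fit <- phasereg:::fit_design(y, matrix(1, 50000, 1,
                                         dimnames = list(NULL, "(Intercept)")),
                               "binomial")
  expect_equal(round(fit$fitted[1], 2), 0.12)
})
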