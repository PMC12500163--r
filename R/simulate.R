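#' Two-locus haplotype frequencies from allele frequencies and D'
#'
#' Computes the four haplotype frequencies of two biallelic loci under the
#' standard D' parameterization of linkage disequilibrium:
#' `fAB = pA*pB + D` with `D = dprime * Dmax`, where `Dmax` is the largest
#' magnitude of `D` compatible with the allele frequencies
#' (`min(pA(1-pB), (1-pA)pB)` for positive `dprime`,
#' `min(pA*pB, (1-pA)(1-pB))` for negative).  The remaining three
#' frequencies follow from the marginal constraints.
#'
#' @param pA,pB alternative-allele frequencies in (0, 1).
#' @param dprime D' in `[-1, 1]`.
#' @return Named numeric vector `c(AB, aB, Ab, ab)` summing to 1.
#' @examples
#' hap_freqs_from_ld(0.2, 0.3, 0)      # independence: fAB = 0.06
#' hap_freqs_from_ld(0.2, 0.2, 0.8)
#' @export
hap_freqs_from_ld <- function(pA, pB, dprime) {
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, dprime >= -1, dprime <= 1)
  dmax <- if (dprime >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D <- dprime * dmax
  f <- c(AB = pA * pB + D,
         aB = (1 - pA) * pB - D,
         Ab = pA * (1 - pB) - D,
         ab = (1 - pA) * (1 - pB) + D)
  stopifnot(all(f >= -1e-12))
  pmax(f, 0)
}

#' Recover D' from haplotype frequencies
#'
#' @param freqs named frequencies as from [hap_freqs_from_ld()].
#' @return D' (0 when either locus is monomorphic).
#' @export
dprime_from_freqs <- function(freqs) {
  pA <- freqs[["AB"]] + freqs[["Ab"]]
  pB <- freqs[["AB"]] + freqs[["aB"]]
  D <- freqs[["AB"]] - pA * pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(0)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax == 0) 0 else D / dmax
}

hap_codes <- matrix(c(1, 1,  0, 1,  1, 0,  0, 0), ncol = 2, byrow = TRUE,
                    dimnames = list(c("AB", "aB", "Ab", "ab"), c("a", "b")))

#' Sample a cohort of diplotypes under Hardy-Weinberg equilibrium
#'
#' Each individual is formed from two independent haplotype draws from the
#' given population haplotype frequencies.
#'
#' @param freqs named haplotype frequencies (`AB`, `aB`, `Ab`, `ab`).
#' @param n number of individuals.
#' @param seed optional RNG seed for reproducibility.
#' @return A [diplotype_set] of `n` individuals.
#' @export
sample_cohort <- function(freqs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- freqs[c("AB", "aB", "Ab", "ab")]
  idx <- sample.int(4L, 2L * n, replace = TRUE, prob = freqs)
  h1 <- idx[seq_len(n)]; h2 <- idx[n + seq_len(n)]
  diplotype_set(a1 = hap_codes[h1, "a"], b1 = hap_codes[h1, "b"],
                a2 = hap_codes[h2, "a"], b2 = hap_codes[h2, "b"])
}

# --- generating models -------------------------------------------------
# Linear predictors are functions of the phasetype matrix.  Continuous
# models add N(0, sigma^2) noise; binary models draw Bernoulli outcomes
# from the logit and are resampled to fixed case/control counts.
sim_models <- function() list(
  het = list(family = "gaussian", beta0 = -2, betaG = 0.5, betaP = 0,
             eta = function(pt, s) s$beta0 + s$betaG * (pt[, "GA"] + pt[, "GB"])),
  additive_cis_cont = list(family = "gaussian", beta0 = -2, betaG = 0, betaP = 1.5,
             eta = function(pt, s) s$beta0 + s$betaP * pt[, "CisAB"]),
  additive_trans_cont = list(family = "gaussian", beta0 = -2, betaG = 0, betaP = 1.5,
             eta = function(pt, s) s$beta0 + s$betaP * pt[, "TransAB"]),
  t1e_additive_A = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 + s$betaG * pt[, "GA"]),
  t1e_dominant_A = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 + s$betaG * (pt[, "GA"] >= 1)),
  t1e_recessive_A = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 + s$betaG * (pt[, "GA"] == 2)),
  t1e_additive_both = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 + s$betaG * (pt[, "GA"] + pt[, "GB"])),
  t1e_dominant_both = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 +
               s$betaG * ((pt[, "GA"] >= 1) + (pt[, "GB"] >= 1))),
  t1e_recessive_both = list(family = "binomial", beta0 = -2, betaG = 1, betaP = 0,
             eta = function(pt, s) s$beta0 +
               s$betaG * ((pt[, "GA"] == 2) + (pt[, "GB"] == 2))),
  pow_additive_cis = list(family = "binomial", beta0 = -2, betaG = 0, betaP = 0.5,
             eta = function(pt, s) s$beta0 + s$betaP * pt[, "CisAB"]),
  pow_dominant_cis = list(family = "binomial", beta0 = -2, betaG = 0, betaP = 0.5,
             eta = function(pt, s) s$beta0 + s$betaP * (pt[, "CisAB"] >= 1)),
  pow_recessive_cis = list(family = "binomial", beta0 = -2, betaG = 0, betaP = 1.5,
             eta = function(pt, s) s$beta0 + s$betaP * (pt[, "CisAB"] == 2)),
  pow_additive_trans = list(family = "binomial", beta0 = -2, betaG = 0, betaP = 0.5,
             eta = function(pt, s) s$beta0 + s$betaP * pt[, "TransAB"]),
  pow_dominant_trans = list(family = "binomial", beta0 = -2, betaG = 0, betaP = 0.5,
             eta = function(pt, s) s$beta0 + s$betaP * (pt[, "TransAB"] >= 1)))

#' Define a simulation scenario
#'
#' Bundles a generating model with its population parameters.  The model
#' ids cover the standard study designs: three continuous models
#' (`"het"` for allelic heterogeneity, `"additive_cis_cont"`,
#' `"additive_trans_cont"`), six binary null models with marginal effects
#' only (`"t1e_additive_A"`, `"t1e_dominant_A"`, `"t1e_recessive_A"` and
#' the `_both` variants, all with `beta0 = -2`, `betaG = 1`), and five
#' binary phase-effect models (`"pow_additive_cis"`, `"pow_dominant_cis"`,
#' `"pow_recessive_cis"`, `"pow_additive_trans"`, `"pow_dominant_trans"`,
#' with `betaP = 0.5`, or `1.5` for the recessive cis model).  The
#' logistic intercept `-2` corresponds to a baseline prevalence of 0.12.
#' Coefficients may be overridden for non-default designs (for example the
#' heritability-calibrated switch-error study).
#'
#' @param model one of the model ids above.
#' @param pA,pB,dprime population haplotype parameters, see
#'   [hap_freqs_from_ld()].
#' @param n cohort size for continuous models.
#' @param n_cases,n_controls group sizes for binary models.
#' @param n_iter Monte-Carlo iterations for [estimate_rates()].
#' @param alpha nominal test level.
#' @param beta0,betaG,betaP,sigma coefficient overrides (`NULL` keeps the
#'   model default; `sigma` is the residual SD of continuous models).
#' @param switch_rate proportion of double heterozygotes whose observed
#'   phase is flipped after phenotype generation (phasing-error study).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(model, pA = 0.2, pB = 0.2, dprime = 0,
                         n = 1000, n_cases = 1000, n_controls = 1000,
                         n_iter = 1000, alpha = 0.05,
                         beta0 = NULL, betaG = NULL, betaP = NULL,
                         sigma = 1, switch_rate = 0) {
  models <- sim_models()
  model <- match.arg(model, names(models))
  def <- models[[model]]
  stopifnot(n_iter >= 1, switch_rate >= 0, switch_rate <= 1)
  s <- list(model = model, family = def$family,
            pA = pA, pB = pB, dprime = dprime,
            freqs = hap_freqs_from_ld(pA, pB, dprime),
            n = n, n_cases = n_cases, n_controls = n_controls,
            n_iter = n_iter, alpha = alpha,
            beta0 = if (is.null(beta0)) def$beta0 else beta0,
            betaG = if (is.null(betaG)) def$betaG else betaG,
            betaP = if (is.null(betaP)) def$betaP else betaP,
            sigma = sigma, switch_rate = switch_rate, eta = def$eta)
  class(s) <- "sim_scenario"
  s
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$model, "(", x$family, ")\n")
  cat(sprintf("  pA = %g, pB = %g, D' = %g\n", x$pA, x$pB, x$dprime))
  if (x$family == "gaussian")
    cat(sprintf("  n = %d, sigma = %g\n", x$n, x$sigma))
  else
    cat(sprintf("  %d cases / %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  beta0 = %g, betaG = %g, betaP = %g; n_iter = %d, alpha = %g\n",
              x$beta0, x$betaG, x$betaP, x$n_iter, x$alpha))
  if (x$switch_rate > 0)
    cat(sprintf("  switch-error rate = %g\n", x$switch_rate))
  invisible(x)
}

#' Simulate a phenotype (and, for binary models, the cohort)
#'
#' Continuous models add Gaussian noise with SD `sigma` to the linear
#' predictor evaluated on the supplied cohort.  Binary models ignore the
#' supplied cohort and draw fresh individuals, assigning case/control
#' status by a Bernoulli draw from the logistic model, until exactly
#' `n_cases` and `n_controls` individuals have been collected (rejection
#' sampling; capped at 1e7 draws).
#'
#' @param scenario a [sim_scenario].
#' @param cohort a [diplotype_set]; required for continuous models.
#' @return List with `response` and `diplotypes`.
#' @export
simulate_phenotype <- function(scenario, cohort = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$family == "gaussian") {
    if (is.null(cohort)) stop("continuous models need a cohort")
    pt <- phasetypes(cohort)
    y <- scenario$eta(pt, scenario) +
      stats::rnorm(nrow(pt), 0, scenario$sigma)
    return(list(response = y, diplotypes = cohort))
  }
  # binary: rejection-sample fresh individuals to exact group sizes
  want1 <- scenario$n_cases; want0 <- scenario$n_controls
  got <- list(); drawn <- 0L; max_draws <- 1e7
  n1 <- 0L; n0 <- 0L
  block <- max(2048L, 2L * (want1 + want0))
  while (n1 < want1 || n0 < want0) {
    if (drawn >= max_draws)
      stop("rejection sampling exceeded ", max_draws,
           " draws; model prevalence too extreme for the requested groups")
    d <- sample_cohort(scenario$freqs, block)
    pt <- phasetypes(d)
    p <- stats::plogis(scenario$eta(pt, scenario))
    yy <- stats::rbinom(block, 1L, p)
    drawn <- drawn + block
    take1 <- which(yy == 1L)[seq_len(min(want1 - n1, sum(yy == 1L)))]
    take0 <- which(yy == 0L)[seq_len(min(want0 - n0, sum(yy == 0L)))]
    take <- c(take1, take0)
    if (length(take))
      got[[length(got) + 1L]] <-
        cbind(d$a1[take], d$b1[take], d$a2[take], d$b2[take], yy[take])
    n1 <- n1 + length(take1); n0 <- n0 + length(take0)
  }
  m <- do.call(rbind, got)
  list(response = m[, 5L],
       diplotypes = diplotype_set(m[, 1L], m[, 2L], m[, 3L], m[, 4L]))
}

#' Inject phasing switch errors
#'
#' A switch error swaps which haplotype each allele is assigned to.  For a
#' two-locus diplotype this is only detectable — and only has any effect —
#' in double heterozygotes, where it converts `AB/ab` into `Ab/aB` and
#' vice versa.  Each double heterozygote is flipped independently with the
#' given probability; genotypes are untouched.
#'
#' @param diplotypes a [diplotype_set].
#' @param rate switch-error probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A [diplotype_set] with corrupted phase.
#' @export
inject_switch_errors <- function(diplotypes, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(diplotypes)
  d <- diplotypes
  dh <- which(!is.na(d$a1) & (d$a1 + d$a2 == 1L) & (d$b1 + d$b2 == 1L))
  flip <- dh[stats::runif(length(dh)) < rate]
  if (length(flip)) {
    tmp <- d$b1[flip]
    d$b1[flip] <- d$b2[flip]
    d$b2[flip] <- tmp
  }
  diplotype_set(d$a1, d$b1, d$a2, d$b2)
}

#' Exact diplotype distribution implied by haplotype frequencies
#'
#' @param freqs haplotype frequencies.
#' @return List with `diplotypes` ([all_diplotypes()]) and their `prob`
#'   under Hardy-Weinberg equilibrium.
#' @export
diplotype_probs <- function(freqs) {
  d <- all_diplotypes()
  hap_f <- function(a, b)
    freqs[[paste0(ifelse(a == 1, "A", "a"), ifelse(b == 1, "B", "b"))]]
  f1 <- mapply(hap_f, d$a1, d$b1)
  f2 <- mapply(hap_f, d$a2, d$b2)
  prob <- ifelse(f1 == f2 & d$a1 == d$a2 & d$b1 == d$b2,
                 f1 * f2, 2 * f1 * f2)
  list(diplotypes = d, prob = unname(prob))
}

#' Effect size achieving a target heritability
#'
#' Solves `h2 = beta^2 * Var(term) / (beta^2 * Var(term) + sigma^2)` for
#' `beta`, with `Var(term)` computed exactly from the population diplotype
#' distribution under Hardy-Weinberg equilibrium.  The residual SD is held
#' fixed (default 1) and the effect size is scaled to the target.
#'
#' @param h2 target heritability in `[0, 1)`.
#' @param freqs haplotype frequencies.
#' @param term which phasetype (or genotype) column carries the effect,
#'   e.g. `"CisAB"`.
#' @param sigma fixed residual SD.
#' @return The coefficient `beta` (0 when `h2 = 0`).
#' @export
h2_to_effect <- function(h2, freqs, term = "CisAB", sigma = 1) {
  stopifnot(h2 >= 0, h2 < 1)
  if (h2 == 0) return(0)
  v <- population_term_variance(freqs, term)
  if (v <= 0) stop("term '", term, "' has zero population variance")
  sigma * sqrt(h2 / ((1 - h2) * v))
}

population_term_variance <- function(freqs, term) {
  dp <- diplotype_probs(freqs)
  x <- phasetypes(dp$diplotypes)[, term]
  m <- sum(dp$prob * x)
  sum(dp$prob * x^2) - m^2
}

# deterministic per-iteration seed stream
iter_seed <- function(seed, i) as.integer((as.numeric(seed) * 1000003 + i) %% 2147483629)

# --- test registry -----------------------------------------------------
# Each entry maps a test name to a function(y, d, family) -> p-value.
# rop cis/trans share one fit per iteration.
run_registered_tests <- function(y, d, family, tests) {
  p <- stats::setNames(rep(NA_real_, length(tests)), tests)
  grab <- function(res) if (res$status == "ok") res$p_value else NA_real_
  if (any(c("rop_cis", "rop_trans") %in% tests)) {
    fit <- tryCatch(rop(y, d, family = family), error = function(e) NULL)
    if (!is.null(fit)) {
      if ("rop_cis" %in% tests) p["rop_cis"] <- grab(fit$cis)
      if ("rop_trans" %in% tests) p["rop_trans"] <- grab(fit$trans)
    }
  }
  single <- function(expr) tryCatch(grab(expr), error = function(e) NA_real_)
  for (t in setdiff(tests, c("rop_cis", "rop_trans"))) {
    p[t] <- switch(t,
      interaction_1df = single(interaction_test(y, d, family = family, df = 1)),
      interaction_4df = single(interaction_test(y, d, family = family, df = 4)),
      saturated = single(saturated_test(y, d, family = family)),
      or_test = single(haplotype_or_cohort(y, d)),
      or_test_em = single(haplotype_or_cohort(y, d, freq_method = "em")),
      hap_regression = single(haplotype_regression(y, d, family = family)),
      recessive_cis_m1 = single(recessive_cis_test(y, d, family = family,
                                                   model_variant = 1)),
      recessive_cis_m2 = single(recessive_cis_test(y, d, family = family,
                                                   model_variant = 2)),
      stop("unknown test: ", t))
  }
  p
}

#' Monte-Carlo rejection rates for a scenario
#'
#' Repeatedly generates a cohort and phenotype from the scenario, applies
#' the requested tests, and reports per-test rejection rates at the
#' scenario's `alpha` with Monte-Carlo standard errors
#' `sqrt(r(1-r)/n_iter)`.  An iteration in which a test fails or is
#' inestimable is excluded from that test's denominator and counted in
#' `n_failed`.  Per-iteration seeds are derived deterministically from the
#' master seed, so results are reproducible and independent of the order
#' in which scenarios are run.
#'
#' @param scenario a [sim_scenario].
#' @param tests character vector of registered test names: `"rop_cis"`,
#'   `"rop_trans"`, `"interaction_1df"`, `"interaction_4df"`,
#'   `"saturated"`, `"or_test"`, `"or_test_em"` (binary only),
#'   `"hap_regression"`,
#'   `"recessive_cis_m1"`, `"recessive_cis_m2"`.
#' @param seed master seed.
#' @return A `power_summary` data frame: one row per test with `rate`,
#'   `mc_se`, `n_iter`, `n_failed`.
#' @export
estimate_rates <- function(scenario, tests = c("rop_cis", "rop_trans"),
                           seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  pm <- matrix(NA_real_, scenario$n_iter, length(tests),
               dimnames = list(NULL, tests))
  for (i in seq_len(scenario$n_iter)) {
    set.seed(iter_seed(seed, i))
    sim <- if (scenario$family == "gaussian")
      simulate_phenotype(scenario, sample_cohort(scenario$freqs, scenario$n))
    else simulate_phenotype(scenario)
    d <- sim$diplotypes
    if (scenario$switch_rate > 0)
      d <- inject_switch_errors(d, scenario$switch_rate)
    pm[i, ] <- run_registered_tests(sim$response, d, scenario$family, tests)
  }
  n_ok <- colSums(!is.na(pm))
  rate <- colSums(pm <= scenario$alpha, na.rm = TRUE) / pmax(n_ok, 1L)
  out <- data.frame(test = tests, rate = unname(rate),
                    mc_se = unname(sqrt(rate * (1 - rate) / pmax(n_ok, 1L))),
                    n_iter = scenario$n_iter,
                    n_failed = scenario$n_iter - unname(n_ok),
                    alpha = scenario$alpha,
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario
  class(out) <- c("power_summary", "data.frame")
  out
}

#' @export
print.power_summary <- function(x, ...) {
  s <- attr(x, "scenario")
  if (!is.null(s))
    cat(sprintf("Rejection rates: model %s, pA=%g pB=%g D'=%g, %d iterations\n",
                s$model, s$pA, s$pB, s$dprime, s$n_iter))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conditional-analysis power experiment
#'
#' Contrasts the two standard single-variant strategies for a secondary
#' signal — testing SNP B without (`Y ~ GB`) and with (`Y ~ GA + GB`)
#' adjustment for the primary SNP A genotype — against the phase tests, on
#' data generated from a continuous scenario (allelic heterogeneity, cis,
#' or trans truth).  Conditional analysis responds to LD rather than to
#' the generating mechanism, which is why it cannot separate allelic
#' heterogeneity from phase effects; the phase tests can.
#'
#' @param scenario a continuous [sim_scenario].
#' @param seed master seed.
#' @return A `power_summary` with rows `snpB_unconditional`,
#'   `snpB_conditional`, `rop_cis`, `rop_trans`.
#' @export
conditional_power_experiment <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"),
            scenario$family == "gaussian")
  tests <- c("snpB_unconditional", "snpB_conditional", "rop_cis", "rop_trans")
  pm <- matrix(NA_real_, scenario$n_iter, 4L, dimnames = list(NULL, tests))
  for (i in seq_len(scenario$n_iter)) {
    set.seed(iter_seed(seed, i))
    d <- sample_cohort(scenario$freqs, scenario$n)
    sim <- simulate_phenotype(scenario, d)
    y <- sim$response
    pt <- phasetypes(d)
    X1 <- cbind(`(Intercept)` = 1, GB = pt[, "GB"])
    X2 <- cbind(`(Intercept)` = 1, GA = pt[, "GA"], GB = pt[, "GB"])
    f1 <- fit_design(y, X1, "gaussian")
    f2 <- fit_design(y, X2, "gaussian")
    pm[i, "snpB_unconditional"] <- test_terms(f1, "GB")$p_value
    pm[i, "snpB_conditional"] <- test_terms(f2, "GB")$p_value
    fit <- tryCatch(rop(y, d), error = function(e) NULL)
    if (!is.null(fit)) {
      pm[i, "rop_cis"] <- if (fit$cis$status == "ok") fit$cis$p_value else NA
      pm[i, "rop_trans"] <- if (fit$trans$status == "ok") fit$trans$p_value else NA
    }
  }
  n_ok <- colSums(!is.na(pm))
  rate <- colSums(pm <= scenario$alpha, na.rm = TRUE) / pmax(n_ok, 1L)
  out <- data.frame(test = tests, rate = unname(rate),
                    mc_se = unname(sqrt(rate * (1 - rate) / pmax(n_ok, 1L))),
                    n_iter = scenario$n_iter,
                    n_failed = scenario$n_iter - unname(n_ok),
                    alpha = scenario$alpha, stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario
  class(out) <- c("power_summary", "data.frame")
  out
}

#' LD sensitivity of the phase tests: power-ratio surface
#'
#' For a grid of allele-frequency pairs, computes the power of the cis (or
#' trans) test at two LD levels and their ratio (power at `dprime_pair[2]`
#' over power at `dprime_pair[1]`).  The default design is a quantitative
#' outcome with `n = 1000`, residual SD 2 and phase coefficient 1.
#' `method = "analytic"` evaluates the noncentral chi-squared
#' approximation with the noncentrality computed from exact population
#' design moments (the residual variance of the phase column after
#' projection on the adjustment columns); `method = "simulation"`
#' estimates power empirically.
#'
#' @param pA_grid,pB_grid allele-frequency grids.
#' @param effect `"cis"` or `"trans"`.
#' @param dprime_pair the two D' values compared.
#' @param n,sigma,betaP design constants.
#' @param method `"simulation"` or `"analytic"`.
#' @param n_iter simulation iterations per cell.
#' @param alpha test level.
#' @param seed master seed (simulation method).
#' @return Data frame with one row per grid cell: `pA`, `pB`, `power_d1`,
#'   `power_d2`, `ratio`.
#' @export
power_ratio_surface <- function(pA_grid, pB_grid, effect = c("cis", "trans"),
                                dprime_pair = c(0, 0.8), n = 1000,
                                sigma = 2, betaP = 1,
                                method = c("simulation", "analytic"),
                                n_iter = 500, alpha = 0.05, seed = 1) {
  effect <- match.arg(effect)
  method <- match.arg(method)
  model <- if (effect == "cis") "additive_cis_cont" else "additive_trans_cont"
  phase_col <- if (effect == "cis") "CisAB" else "TransAB"
  grid <- expand.grid(pA = pA_grid, pB = pB_grid)
  pw <- function(pA, pB, dprime, cell) {
    if (method == "analytic") {
      analytic_power(hap_freqs_from_ld(pA, pB, dprime), phase_col,
                     n = n, sigma = sigma, betaP = betaP, alpha = alpha)
    } else {
      sc <- sim_scenario(model, pA = pA, pB = pB, dprime = dprime, n = n,
                         betaP = betaP, sigma = sigma, n_iter = n_iter,
                         alpha = alpha)
      tn <- if (effect == "cis") "rop_cis" else "rop_trans"
      estimate_rates(sc, tests = tn, seed = iter_seed(seed, cell))$rate
    }
  }
  res <- lapply(seq_len(nrow(grid)), function(k) {
    p1 <- pw(grid$pA[k], grid$pB[k], dprime_pair[1], 2L * k)
    p2 <- pw(grid$pA[k], grid$pB[k], dprime_pair[2], 2L * k + 1L)
    data.frame(pA = grid$pA[k], pB = grid$pB[k],
               power_d1 = p1, power_d2 = p2,
               ratio = if (p1 > 0) p2 / p1 else NA_real_)
  })
  do.call(rbind, res)
}

# power of the 1-df phase test from exact population design moments:
# noncentrality = n * betaP^2 * (residual variance of the phase column
# given intercept, genotypes, dominance terms and the other phase term) / sigma^2
analytic_power <- function(freqs, phase_col, n, sigma, betaP, alpha = 0.05) {
  dp <- diplotype_probs(freqs)
  pt <- phasetypes(dp$diplotypes)
  other <- if (phase_col == "CisAB") "TransAB" else "CisAB"
  Z <- cbind(1, pt[, c("GA", "DA", "GB", "DB", other)])
  x <- pt[, phase_col]
  w <- dp$prob
  Mzz <- crossprod(Z * w, Z)
  Mzx <- crossprod(Z * w, x)
  gamma <- tryCatch(solve(Mzz, Mzx), error = function(e) {
    # drop population-aliased columns from the projection
    q <- qr(Z * sqrt(w))
    keep <- q$pivot[seq_len(q$rank)]
    g <- rep(0, ncol(Z))
    g[keep] <- solve(Mzz[keep, keep, drop = FALSE], Mzx[keep, , drop = FALSE])
    g
  })
  v_res <- sum(w * (x - drop(Z %*% gamma))^2)
  ncp <- n * betaP^2 * v_res / sigma^2
  stats::pchisq(stats::qchisq(1 - alpha, 1), 1, ncp = ncp, lower.tail = FALSE)
}

#' Switch-error robustness experiment
#'
#' Estimates, for each minor-allele-frequency scenario, the power of the
#' cis test and the type-I error of the trans test when phenotype is
#' generated from the true phase but the analyzed phase carries switch
#' errors in double heterozygotes.  The phenotype is continuous with an
#' additive cis effect calibrated to a target heritability via
#' [h2_to_effect()] (residual SD fixed at 1).
#'
#' @param maf_scenarios list of `c(pA, pB)` pairs (independent loci).
#' @param rates switch-error rates, always including 0 as benchmark.
#' @param h2 target heritability of the cis term.
#' @param n cohort size.
#' @param n_iter Monte-Carlo iterations.
#' @param seed master seed.
#' @param alpha test level.
#' @return Data frame: one row per scenario and rate with `cis_power`,
#'   `trans_t1e`, and `cis_power_ratio` relative to the zero-error row of
#'   the same scenario.
#' @export
switch_error_experiment <- function(maf_scenarios = list(c(0.05, 0.05),
                                                         c(0.05, 0.2),
                                                         c(0.2, 0.2)),
                                    rates = c(0, 0.05, 0.1, 0.2),
                                    h2 = 0.003, n = 5000, n_iter = 2000,
                                    seed = 1, alpha = 0.05) {
  if (!0 %in% rates) rates <- c(0, rates)
  out <- list()
  for (k in seq_along(maf_scenarios)) {
    p <- maf_scenarios[[k]]
    freqs <- hap_freqs_from_ld(p[1], p[2], 0)
    beta <- h2_to_effect(h2, freqs, term = "CisAB", sigma = 1)
    base <- NA_real_
    for (r in sort(rates)) {
      sc <- sim_scenario("additive_cis_cont", pA = p[1], pB = p[2],
                         dprime = 0, n = n, beta0 = 0, betaP = beta,
                         sigma = 1, n_iter = n_iter, alpha = alpha,
                         switch_rate = r)
      res <- estimate_rates(sc, tests = c("rop_cis", "rop_trans"),
                            seed = iter_seed(seed, k))
      cis_p <- res$rate[res$test == "rop_cis"]
      if (r == 0) base <- cis_p
      out[[length(out) + 1L]] <- data.frame(
        pA = p[1], pB = p[2], switch_rate = r,
        cis_power = cis_p,
        trans_t1e = res$rate[res$test == "rop_trans"],
        cis_power_ratio = cis_p / base, n_iter = n_iter)
    }
  }
  do.call(rbind, out)
}

#' Read a simulation scenario from a YAML or JSON config file
#'
#' The file holds keys matching the arguments of [sim_scenario()]
#' (`model`, `pA`, `pB`, `dprime`, ...).  The format is chosen by file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path config file path.
#' @return A [sim_scenario].
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported scenario format: .", ext))
  do.call(sim_scenario, cfg)
}
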