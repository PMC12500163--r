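#' Genotype interaction (epistasis) tests
#'
#' Classic two-locus epistasis tests that use genotypes only.  With
#' `df = 1` the model is `g(E(Y)) = b0 + bGA*GA + bGB*GB + bI*GA*GB` and
#' the interaction coefficient is tested on 1 df.  With `df = 4` the model
#' adds dominance terms and all four products `GA*GB`, `GA*DB`, `DA*GB`,
#' `DA*DB`, tested jointly on 4 df.  Neither test uses phase, so a
#' significant result cannot distinguish cis from trans mechanisms; the
#' 1-df version is also prone to type-I-error inflation when the loci are
#' in LD and one carries a dominant or recessive marginal effect.
#'
#' @inheritParams rop
#' @param df 1 or 4.
#' @return A [phase_test].
#' @export
interaction_test <- function(response, diplotypes, covariates = NULL,
                             family = stats::gaussian(), df = 1,
                             test = c("LRT", "Wald", "score")) {
  test <- match.arg(test)
  family <- resolve_family(family)
  stopifnot(df %in% c(1, 4))
  cov_m <- prepare_covariates(covariates, length(response))
  cc <- drop_incomplete(response, diplotypes, cov_m)
  response <- cc$response; cov_m <- cc$cov_m
  pt <- phasetypes(cc$diplotypes)
  GA <- pt[, "GA"]; GB <- pt[, "GB"]; DA <- pt[, "DA"]; DB <- pt[, "DB"]
  if (df == 1) {
    X <- cbind(`(Intercept)` = 1, GA = GA, GB = GB)
    if (!is.null(cov_m)) X <- cbind(X, cov_m)
    X <- cbind(X, `GA:GB` = GA * GB)
    terms <- "GA:GB"
    nm <- "genotype interaction (1 df)"
  } else {
    X <- cbind(`(Intercept)` = 1, GA = GA, DA = DA, GB = GB, DB = DB)
    if (!is.null(cov_m)) X <- cbind(X, cov_m)
    X <- cbind(X, `GA:GB` = GA * GB, `GA:DB` = GA * DB,
               `DA:GB` = DA * GB, `DA:DB` = DA * DB)
    terms <- c("GA:GB", "GA:DB", "DA:GB", "DA:DB")
    nm <- "genotype interaction (4 df)"
  }
  full <- fit_design(response, X, family)
  test_terms(full, terms, test = test, name = nm)
}

#' Saturated two-locus test with a phase indicator
#'
#' Adds to the 4-df interaction design the phase term
#' `V = 1(GA = GB = 1 and the alternative alleles are in cis)` and jointly
#' tests the four interaction products plus `V` on 5 df.  The design
#' saturates the ten diplotype means, so any additive cis or trans mean
#' structure is captured, but the test cannot say whether a signal is cis
#' or trans, and the extra degrees of freedom cost power relative to the
#' targeted 1-df phase tests.
#'
#' @inheritParams rop
#' @return A [phase_test].  When the cohort contains no cis double
#'   heterozygote the `V` column is aliased and the effective df drop to 4
#'   (reported in the result).
#' @export
saturated_test <- function(response, diplotypes, covariates = NULL,
                           family = stats::gaussian(),
                           test = c("LRT", "Wald", "score")) {
  test <- match.arg(test)
  family <- resolve_family(family)
  cov_m <- prepare_covariates(covariates, length(response))
  cc <- drop_incomplete(response, diplotypes, cov_m)
  response <- cc$response; cov_m <- cc$cov_m
  pt <- phasetypes(cc$diplotypes)
  GA <- pt[, "GA"]; GB <- pt[, "GB"]; DA <- pt[, "DA"]; DB <- pt[, "DB"]
  V <- as.integer(GA == 1L & GB == 1L & pt[, "CisAB"] == 1L)
  X <- cbind(`(Intercept)` = 1, GA = GA, DA = DA, GB = GB, DB = DB)
  if (!is.null(cov_m)) X <- cbind(X, cov_m)
  X <- cbind(X, `GA:GB` = GA * GB, `GA:DB` = GA * DB,
             `DA:GB` = DA * GB, `DA:DB` = DA * DB, V = V)
  full <- fit_design(response, X, family)
  test_terms(full, c("GA:GB", "GA:DB", "DA:GB", "DA:DB", "V"),
             test = test, name = "saturated (5 df)")
}

#' Haplotype odds-ratio test
#'
#' Case-control test built from the phased haplotype frequencies in cases
#' (`f1`) and controls (`f0`):
#' \deqn{\log(OR) = \log\frac{f^1_{AB} f^1_{ab}}{f^1_{Ab} f^1_{aB}}
#'              - \log\frac{f^0_{AB} f^0_{ab}}{f^0_{Ab} f^0_{aB}}}
#' with statistic `log(OR)^2 / (v1 + v0)` referred to chi-squared on 1 df,
#' where `v_g = (1/(2 n_g)) * sum of reciprocal haplotype frequencies` in
#' group `g` (the symmetric log-odds-ratio variance over all four
#' haplotypes).  Under a rare outcome the log OR approximates an additive
#' cis effect and is zero under a pure trans effect, so the test has power
#' against cis but not trans mechanisms; it is inflated when both loci
#' carry marginal effects.
#'
#' @param f1,f0 named haplotype frequency vectors for cases and controls
#'   with elements `AB`, `aB`, `Ab`, `ab` (each summing to 1).
#' @param n1,n0 numbers of case and control individuals (each contributes
#'   two haplotypes).
#' @param continuity continuity correction added to each haplotype *count*
#'   before forming frequencies (default 0: a zero frequency is an error,
#'   since silent corrections change the statistic; use `0.5` for the
#'   conventional correction).
#' @return A [phase_test] with the `log_or` estimate.
#' @export
haplotype_or_test <- function(f1, f0, n1, n0, continuity = 0) {
  haps <- c("AB", "aB", "Ab", "ab")
  f1 <- f1[haps]; f0 <- f0[haps]
  if (anyNA(f1) || anyNA(f0))
    stop("f1 and f0 must be named vectors with elements AB, aB, Ab, ab")
  if (abs(sum(f1) - 1) > 1e-6 || abs(sum(f0) - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1 within each group")
  if (continuity > 0) {
    c1 <- f1 * 2 * n1 + continuity; f1 <- c1 / sum(c1)
    c0 <- f0 * 2 * n0 + continuity; f0 <- c0 / sum(c0)
  }
  if (any(f1 <= 0) || any(f0 <= 0))
    stop("zero haplotype frequency; rerun with a continuity correction ",
         "(e.g. continuity = 0.5) if appropriate")
  log_or <- log(f1["AB"] * f1["ab"] / (f1["Ab"] * f1["aB"])) -
            log(f0["AB"] * f0["ab"] / (f0["Ab"] * f0["aB"]))
  v1 <- sum(1 / f1) / (2 * n1)
  v0 <- sum(1 / f0) / (2 * n0)
  stat <- unname(log_or^2 / (v1 + v0))
  phase_test("haplotype OR", stat, 1L,
             stats::pchisq(stat, 1L, lower.tail = FALSE),
             estimates = c(log_or = unname(log_or)),
             se = c(log_or = sqrt(v1 + v0)))
}

#' Haplotype odds-ratio test from a cohort
#'
#' Tabulates per-group haplotype frequencies from a [diplotype_set] and
#' calls [haplotype_or_test()].  With `freq_method = "observed"` the
#' phased haplotype counts are used directly.  With `freq_method = "em"`
#' the frequencies are instead estimated per group by the classical
#' two-locus EM algorithm from genotypes alone (phase ignored), which is
#' how this benchmark has historically been run on unphased data.  The
#' distinction matters: the EM step assumes random haplotype pairing
#' within each group, which case-control conditioning violates whenever
#' both loci carry marginal effects, and the resulting test inflates in
#' exactly that situation, whereas the observed-phase version stays
#' calibrated there.
#'
#' @param response 0/1 case indicator.
#' @param diplotypes a [diplotype_set].
#' @param continuity see [haplotype_or_test()].
#' @param freq_method `"observed"` (default) or `"em"`.
#' @return A [phase_test].
#' @export
haplotype_or_cohort <- function(response, diplotypes, continuity = 0,
                                freq_method = c("observed", "em")) {
  freq_method <- match.arg(freq_method)
  cc <- drop_incomplete(response, diplotypes, NULL)
  response <- cc$response
  stopifnot(all(response %in% c(0, 1)))
  pt <- phasetypes(cc$diplotypes)
  freqs <- function(g) {
    m <- pt[response == g, , drop = FALSE]
    if (freq_method == "observed") {
      cnt <- stats::setNames(colSums(m[, c("CisAB", "CisaB",
                                           "CisAb", "Cisab")]),
                             c("AB", "aB", "Ab", "ab"))
      cnt / sum(cnt)
    } else {
      em_hap_freqs(m[, "GA"], m[, "GB"])
    }
  }
  haplotype_or_test(freqs(1), freqs(0),
                    n1 = sum(response == 1), n0 = sum(response == 0),
                    continuity = continuity)
}

# classical two-locus haplotype-frequency EM from genotype counts.
# Haplotypes are determined except in double heterozygotes, which are
# split between AB/ab and Ab/aB according to the current frequencies
# under within-group random pairing.
em_hap_freqs <- function(GA, GB, tol = 1e-10, max_iter = 500L) {
  dh <- GA == 1L & GB == 1L
  # outside double heterozygotes every haplotype is determined:
  # e.g. the number of AB haplotypes is min(GA, GB)
  ga <- GA[!dh]; gb <- GB[!dh]
  det <- c(AB = sum(pmin(ga, gb)),
           aB = sum(pmin(2L - ga, gb)),
           Ab = sum(pmin(ga, 2L - gb)),
           ab = sum(pmin(2L - ga, 2L - gb)))
  ndh <- sum(dh)
  f <- rep(0.25, 4); names(f) <- names(det)
  for (i in seq_len(max_iter)) {
    pcis <- unname(f["AB"] * f["ab"] / (f["AB"] * f["ab"] + f["Ab"] * f["aB"]))
    if (!is.finite(pcis)) pcis <- 0.5
    cnt <- det + ndh * c(AB = pcis, aB = 1 - pcis,
                         Ab = 1 - pcis, ab = pcis)[names(det)]
    fn <- cnt / sum(cnt)
    done <- max(abs(fn - f)) < tol
    f <- fn
    if (done) break
  }
  f
}

#' Haplotype regression test
#'
#' Treats each two-locus haplotype as an allele of one multi-allelic
#' marker and models the cis counts additively, with `ab` as the reference
#' haplotype: `g(E(Y)) = b0 + bAB*CisAB + bAb*CisAb + baB*CisaB`, jointly
#' tested on 3 df.  The model omits the per-locus main-effect adjustment,
#' so it responds to marginal effects as well as phase effects, and it
#' cannot detect trans configurations.
#'
#' @inheritParams rop
#' @return A [phase_test].
#' @export
haplotype_regression <- function(response, diplotypes, covariates = NULL,
                                 family = stats::gaussian(),
                                 test = c("LRT", "Wald", "score")) {
  test <- match.arg(test)
  family <- resolve_family(family)
  cov_m <- prepare_covariates(covariates, length(response))
  cc <- drop_incomplete(response, diplotypes, cov_m)
  response <- cc$response; cov_m <- cc$cov_m
  pt <- phasetypes(cc$diplotypes)
  X <- matrix(1, nrow = nrow(pt), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  if (!is.null(cov_m)) X <- cbind(X, cov_m)
  X <- cbind(X, CisAB = pt[, "CisAB"], CisAb = pt[, "CisAb"],
             CisaB = pt[, "CisaB"])
  full <- fit_design(response, X, family)
  test_terms(full, c("CisAB", "CisAb", "CisaB"), test = test,
             name = "haplotype regression (3 df)")
}
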