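#' Regression on phase: test cis and trans effects of a variant pair
#'
#' Fits the phase-aware generalized linear model
#' \deqn{g(E(Y)) = \beta_0 + \beta_{GA} GA + \beta_{DA} DA + \beta_{GB} GB
#'   + \beta_{DB} DB + \beta_{Pcis} P_{cis} + \beta_{Ptrans} P_{trans}}
#' where `GA`, `GB` are additive genotypes, `DA`, `DB` dominance
#' (heterozygosity) indicators, and the phasetypes `Pcis`, `Ptrans` count
#' how many of the individual's haplotype pairings place the two counted
#' alleles on the same, respectively opposite, chromosomes.  The cis and
#' trans phase effects are then tested separately with two 1-df tests of
#' `H0: beta_Pcis = 0` and `H0: beta_Ptrans = 0`, each adjusted for both
#' marginal effects and the other phase term.
#'
#' Because the phasetypes for different reference-allele orientations are
#' affine combinations of the genotype columns and one another, the two
#' test statistics do not depend on which allele is counted (`pcis`,
#' `ptrans`): only the sign of the fitted phase coefficient can change.
#' Fitted values are likewise invariant.
#'
#' A phase term that is linearly dependent on the genotype/covariate
#' columns (for example when one haplotype is absent from the cohort) is
#' reported with status `"inestimable"` instead of being dropped silently,
#' since dropping it would change the hypothesis being tested.
#'
#' @param response numeric phenotype vector (0/1 for `family = binomial`).
#' @param diplotypes a [diplotype_set] aligned with `response`.
#' @param covariates optional numeric matrix or data frame of additional
#'   adjustment covariates (entered additively).
#' @param family `gaussian()` (identity link) or `binomial()` (logit);
#'   a character name is accepted.
#' @param test `"LRT"` (default), `"Wald"` or `"score"`.  The three are
#'   asymptotically equivalent and all reference-allele invariant.
#' @param pcis,ptrans which cis/trans phasetype carries the phase term:
#'   an allele pair among `"AB"`, `"aB"`, `"Ab"`, `"ab"`.  Default `"AB"`,
#'   i.e. the coding oriented on the alternative alleles.
#' @return An object of class `rop` with components `cis` and `trans`
#'   (class [phase_test]), the joint fit, and bookkeeping fields.
#'   Supported methods: `print`, `summary`, `coef`, `vcov`, `fitted`,
#'   `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' set.seed(1)
#' freqs <- hap_freqs_from_ld(pA = 0.3, pB = 0.3, dprime = 0)
#' d <- sample_cohort(freqs, n = 400)
#' pt <- phasetypes(d)
#' y <- 0.8 * pt[, "CisAB"] + rnorm(400)
#' rop(y, d)
#' @export
rop <- function(response, diplotypes, covariates = NULL,
                family = stats::gaussian(), test = c("LRT", "Wald", "score"),
                pcis = "AB", ptrans = "AB") {
  test <- match.arg(test)
  family <- resolve_family(family)
  pcis <- match.arg(pcis, c("AB", "aB", "Ab", "ab"))
  ptrans <- match.arg(ptrans, c("AB", "aB", "Ab", "ab"))
  stopifnot(inherits(diplotypes, "diplotype_set"))
  if (length(response) != nrow(diplotypes))
    stop("response and diplotypes have different lengths")
  cov_m <- prepare_covariates(covariates, length(response))

  cc <- drop_incomplete(response, diplotypes, cov_m)
  y <- cc$response; d <- cc$diplotypes; cov_m <- cc$cov_m
  n_dropped <- cc$n_dropped

  if (length(unique(diplotype_labels(d))) < 3L)
    stop("degenerate cohort: fewer than 3 distinct diplotypes observed")

  pt <- phasetypes(d)
  X <- rop_design(pt, cov_m, pcis = pcis, ptrans = ptrans)
  full <- fit_design(y, X, family)
  out <- structure(list(
    cis = test_terms(full, "Pcis", test = test, name = "RoP cis"),
    trans = test_terms(full, "Ptrans", test = test, name = "RoP trans"),
    fit = full, family = family, test = test,
    pcis = pcis, ptrans = ptrans,
    diplotypes = d, phasetypes = pt, covariates = cov_m,
    n = length(y), n_dropped = n_dropped, call = match.call()),
    class = "rop")
  out
}

# complete-case restriction shared by all cohort-level tests
drop_incomplete <- function(response, diplotypes, cov_m) {
  keep <- !is.na(response) & stats::complete.cases(diplotypes) &
    (if (is.null(cov_m)) TRUE else stats::complete.cases(cov_m))
  d <- diplotypes[keep, , drop = FALSE]
  class(d) <- c("diplotype_set", "data.frame")
  list(response = response[keep], diplotypes = d,
       cov_m = if (is.null(cov_m)) NULL else cov_m[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cov_m <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(cov_m)) stop("covariates must be numeric")
  if (nrow(cov_m) != n) stop("covariates have wrong number of rows")
  if (is.null(colnames(cov_m)))
    colnames(cov_m) <- paste0("cov", seq_len(ncol(cov_m)))
  cov_m
}

rop_design <- function(pt, cov_m, pcis = "AB", ptrans = "AB") {
  X <- cbind(`(Intercept)` = 1,
             pt[, c("GA", "DA", "GB", "DB"), drop = FALSE])
  if (!is.null(cov_m)) X <- cbind(X, cov_m)
  cbind(X,
        Pcis = pt[, paste0("Cis", pcis)],
        Ptrans = pt[, paste0("Trans", ptrans)])
}

#' @export
print.rop <- function(x, digits = 4L, ...) {
  cat("Regression on phase (", x$fit$family$family, " family, ",
      x$test, " tests)\n", sep = "")
  cat("n =", x$n,
      if (x$n_dropped > 0)
        paste0("(", x$n_dropped, " dropped: missing phase/phenotype)"),
      "\n")
  for (r in list(x$cis, x$trans)) {
    if (r$status != "ok")
      cat(sprintf("  %-10s status: %s\n", r$name, r$status))
    else
      cat(sprintf("  %-10s chisq = %.*g on %d df, p = %.*g\n",
                  r$name, digits, r$statistic, r$df, digits, r$p_value))
  }
  invisible(x)
}

#' @export
summary.rop <- function(object, ...) {
  cf <- object$fit$coefficients
  se <- rep(NA_real_, length(cf)); names(se) <- names(cf)
  if (!is.null(object$fit$vcov))
    se[object$fit$kept] <- sqrt(diag(object$fit$vcov))
  z <- cf / se
  tab <- cbind(Estimate = cf, `Std. Error` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(call = object$call, family = object$fit$family$family,
                 test = object$test, coefficients = tab,
                 cis = object$cis, trans = object$trans, n = object$n,
                 n_dropped = object$n_dropped,
                 aliased = object$fit$aliased,
                 dispersion = object$fit$phi),
            class = "summary.rop")
}

#' @export
print.summary.rop <- function(x, digits = 4L, ...) {
  cat("Regression on phase\n")
  cat("Family:", x$family, "  Test:", x$test, "  n =", x$n, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "aliased")
  if (length(x$aliased))
    cat("Aliased:", paste(x$aliased, collapse = ", "), "\n")
  cat("\nPhase tests:\n")
  for (r in list(x$cis, x$trans)) print(r, digits = digits)
  invisible(x)
}

#' @export
coef.rop <- function(object, ...) object$fit$coefficients

#' @export
vcov.rop <- function(object, ...) object$fit$vcov

#' @export
fitted.rop <- function(object, ...) object$fit$fitted

#' @rdname rop
#' @param object,x a fitted `rop` object.
#' @param newdata optional list with elements `diplotypes` (a
#'   [diplotype_set]) and, if the model used them, `covariates`.
#' @param type `"response"` (default) or `"link"`.
#' @param ... unused.
#' @export
predict.rop <- function(object, newdata = NULL,
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$fit$family$linkfun(object$fit$fitted)
  } else {
    pt <- phasetypes(newdata$diplotypes)
    cov_m <- prepare_covariates(newdata$covariates, nrow(pt))
    X <- rop_design(pt, cov_m, pcis = object$pcis, ptrans = object$ptrans)
    cf <- object$fit$coefficients
    cf[is.na(cf)] <- 0   # aliased columns carry no additional information
    eta <- drop(X[, names(cf), drop = FALSE] %*% cf)
  }
  if (type == "response") object$fit$family$linkinv(eta) else eta
}

#' @export
residuals.rop <- function(object,
                          type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$fit$y; mu <- object$fit$fitted
  fam <- object$fit$family
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(fam$variance(mu)),
         deviance = {
           d <- fam$dev.resids(y, mu, rep(1, length(y)))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' @rdname rop
#' @param nsim number of response vectors to simulate from the fitted model.
#' @param seed optional RNG seed.
#' @export
simulate.rop <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fit$fitted
  n <- length(mu)
  sims <- switch(object$fit$family$family,
    gaussian = replicate(nsim, stats::rnorm(n, mu, sqrt(object$fit$phi)),
                         simplify = FALSE),
    binomial = replicate(nsim, stats::rbinom(n, 1L, mu), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rop <- function(x, ...) {
  lab <- diplotype_labels(x$diplotypes)
  y <- x$fit$y
  if (x$fit$family$family == "gaussian") {
    graphics::boxplot(y ~ factor(lab), xlab = "diplotype",
                      ylab = "phenotype", ...)
  } else {
    m <- tapply(y, factor(lab), mean)
    graphics::barplot(m, xlab = "diplotype", ylab = "proportion of cases",
                      ...)
  }
  invisible(x)
}

#' Joint cis/trans tests for multi-allelic variant pairs
#'
#' Fits the multi-allelic phase model: additive and dominance genotype
#' terms for every non-reference allele at each locus, plus cis and trans
#' phasetype counts for every non-reference allele pair, and jointly tests
#' all cis (respectively trans) coefficients.  With `m` and `n` alleles
#' the nominal degrees of freedom are `(m-1)(n-1)` per test; aliased terms
#' are excluded from the statistic and reported.
#'
#' @param response phenotype vector.
#' @param codes a [multiallelic_phasetypes] object.
#' @param covariates optional numeric covariates.
#' @param family,test as in [rop()].
#' @return List of class `rop_multiallelic` with `cis` and `trans`
#'   [phase_test] results and the joint `fit`.
#' @export
rop_multiallelic <- function(response, codes, covariates = NULL,
                             family = stats::gaussian(),
                             test = c("LRT", "Wald", "score")) {
  test <- match.arg(test)
  family <- resolve_family(family)
  stopifnot(inherits(codes, "multiallelic_phasetypes"))
  nonrefA <- codes$allelesA[-1L]
  nonrefB <- codes$allelesB[-1L]
  pair_cols <- as.vector(outer(nonrefA, nonrefB,
                               function(i, j) paste0(i, ":", j)))
  cov_m <- prepare_covariates(covariates, length(response))
  X <- cbind(`(Intercept)` = rep(1, length(response)),
             name_prefix(codes$G_A[, nonrefA, drop = FALSE], "GA."),
             name_prefix(codes$D_A[, nonrefA, drop = FALSE], "DA."),
             name_prefix(codes$G_B[, nonrefB, drop = FALSE], "GB."),
             name_prefix(codes$D_B[, nonrefB, drop = FALSE], "DB."))
  if (!is.null(cov_m)) X <- cbind(X, cov_m)
  X <- cbind(X,
             name_prefix(codes$cis[, pair_cols, drop = FALSE], "cis."),
             name_prefix(codes$trans[, pair_cols, drop = FALSE], "trans."))
  full <- fit_design(response, X, family)
  structure(list(
    cis = test_terms(full, paste0("cis.", pair_cols), test = test,
                     name = "RoP cis (joint)"),
    trans = test_terms(full, paste0("trans.", pair_cols), test = test,
                       name = "RoP trans (joint)"),
    fit = full, m = length(codes$allelesA), n_alleles_b = length(codes$allelesB),
    test = test), class = "rop_multiallelic")
}

name_prefix <- function(m, prefix) {
  colnames(m) <- paste0(prefix, colnames(m))
  m
}

#' @export
print.rop_multiallelic <- function(x, ...) {
  cat("Multi-allelic regression on phase (",
      x$fit$family$family, " family)\n", sep = "")
  print(x$cis); print(x$trans)
  invisible(x)
}

#' Joint test for recessive cis effects
#'
#' The additive phasetype has limited power against recessive cis effects
#' (both haplotypes carrying the cis configuration).  This test augments
#' the phase terms with dominance phasetypes `Dcis = 1(Pcis == 1)` (and,
#' in model variant 1, `Dtrans = 1(Ptrans == 1)`) and jointly tests
#' `H0: beta_Pcis = beta_Dcis = 0` on 2 df.  Variant 1 keeps the trans
#' phase terms in the model; variant 2 omits them, which improves power
#' against recessive cis effects at the cost of type-I-error inflation if
#' the true effect is in trans.
#'
#' @inheritParams rop
#' @param model_variant 1 (trans terms retained) or 2 (omitted).
#' @return A [phase_test] with 2 df (minus any aliased terms).
#' @export
recessive_cis_test <- function(response, diplotypes, covariates = NULL,
                               family = stats::gaussian(),
                               model_variant = 1,
                               test = c("LRT", "Wald", "score"),
                               pcis = "AB", ptrans = "AB") {
  test <- match.arg(test)
  family <- resolve_family(family)
  stopifnot(model_variant %in% c(1, 2))
  cov_m <- prepare_covariates(covariates, length(response))
  cc <- drop_incomplete(response, diplotypes, cov_m)
  response <- cc$response; cov_m <- cc$cov_m
  pt <- phasetypes(cc$diplotypes)
  Pcis <- pt[, paste0("Cis", match.arg(pcis, c("AB", "aB", "Ab", "ab")))]
  Ptrans <- pt[, paste0("Trans", match.arg(ptrans, c("AB", "aB", "Ab", "ab")))]
  X <- cbind(`(Intercept)` = 1,
             pt[, c("GA", "DA", "GB", "DB"), drop = FALSE])
  if (!is.null(cov_m)) X <- cbind(X, cov_m)
  X <- cbind(X, Pcis = Pcis, Dcis = as.integer(Pcis == 1L))
  if (model_variant == 1)
    X <- cbind(X, Ptrans = Ptrans, Dtrans = as.integer(Ptrans == 1L))
  full <- fit_design(response, X, family)
  test_terms(full, c("Pcis", "Dcis"), test = test,
             name = sprintf("recessive cis (model %d)", model_variant))
}

#' Estimability of phase terms in a design
#'
#' Reports, for each phase column of a design matrix, whether it is
#' estimable or lies in the linear span of the adjustment columns
#' (intercept, genotypes, dominance terms, covariates), and if aliased,
#' which adjustment columns reproduce it.  A cis term collapses onto the
#' genotype columns, for example, when one of the four haplotypes is
#' absent from the cohort — the situation in which a phase hypothesis is
#' no longer testable.
#'
#' @param design numeric design matrix with named columns.
#' @param phase_terms columns to assess; defaults to every column whose
#'   name starts with `Pcis`, `Ptrans`, `Dcis`, `Dtrans`, `Cis`, `Trans`,
#'   `cis.` or `trans.`.
#' @param tol tolerance for declaring a residual zero.
#' @return Data frame with columns `term`, `estimable`, `aliased_with`.
#' @export
estimability_report <- function(design, phase_terms = NULL, tol = 1e-8) {
  design <- as.matrix(design)
  stopifnot(!is.null(colnames(design)))
  if (is.null(phase_terms))
    phase_terms <- grep("^(Pcis|Ptrans|Dcis|Dtrans|Cis|Trans|cis\\.|trans\\.)",
                        colnames(design), value = TRUE)
  adj <- design[, setdiff(colnames(design), phase_terms), drop = FALSE]
  res <- lapply(phase_terms, function(term) {
    v <- design[, term]
    fit <- stats::lm.fit(adj, v)
    inspan <- max(abs(fit$residuals)) <= tol * max(1, max(abs(v)))
    aliased_with <- if (inspan) {
      cf <- fit$coefficients
      paste(names(cf)[!is.na(cf) & abs(cf) > tol], collapse = ",")
    } else ""
    data.frame(term = term, estimable = !inspan,
               aliased_with = aliased_with, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
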