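# Shared fixtures and independent oracles for the test suite.
# The oracle refits models through stats::glm()/anova.glm() on data frames,
# a code path fully independent of the package's design-matrix engine.

# one deterministic uniform draw from its own seed (leaves the caller's
# RNG stream untouched apart from reseeding)
runif2 <- function(seed, lo, hi) {
  set.seed(seed)
  stats::runif(1, lo, hi)
}

fixed_cohort <- function(n = 200, pA = 0.3, pB = 0.25, dprime = 0.3,
                         seed = 42) {
  sample_cohort(hap_freqs_from_ld(pA, pB, dprime), n, seed = seed)
}

# full-vs-reduced test through stats::glm + anova.glm (LRT or Rao), or a
# Wald quadratic form built from stats::vcov
oracle_drop_test <- function(y, X, terms, family = "gaussian",
                             test = c("LRT", "score", "Wald")) {
  test <- match.arg(test)
  # standard aliasing treatment: columns outside the identified full model
  # are excluded from both fits
  qx <- qr(X)
  X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  terms_s <- make.names(terms)
  df$..y <- y
  fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
  form_full <- stats::as.formula(
    paste("..y ~ 0 +", paste(setdiff(names(df), "..y"), collapse = "+")))
  form_red <- stats::as.formula(
    paste("..y ~ 0 +",
          paste(setdiff(names(df), c("..y", terms_s)), collapse = "+")))
  g1 <- stats::glm(form_full, data = df, family = fam,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (test == "Wald") {
    b <- stats::coef(g1)[terms_s]
    V <- stats::vcov(g1)[terms_s, terms_s, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    return(list(statistic = stat, df = length(terms_s),
                p = stats::pchisq(stat, length(terms_s), lower.tail = FALSE)))
  }
  g0 <- stats::glm(form_red, data = df, family = fam,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  an <- stats::anova(g0, g1, test = if (test == "score") "Rao" else "LRT")
  disp <- summary(g1)$dispersion
  stat <- (if (test == "score") an$Rao[2] else an$Deviance[2]) / disp
  list(statistic = stat, df = an$Df[2], p = an[["Pr(>Chi)"]][2])
}

rop_design_of <- function(d, pcis = "AB", ptrans = "AB") {
  pt <- phasetypes(d)
  cbind(`(Intercept)` = 1, pt[, c("GA", "DA", "GB", "DB")],
        Pcis = pt[, paste0("Cis", pcis)],
        Ptrans = pt[, paste0("Trans", ptrans)])
}

# Table of the full additive-phasetype coding for the ten diplotypes,
# transcribed cell by cell from the published tabulation.
reference_phasetype_table <- function() {
  m <- rbind(
    "ab/ab" = c(0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 2),
    "Ab/ab" = c(1, 0, 1, 0, 0, 0, 1, 1, 0, 0, 1, 1),
    "aB/ab" = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    "AB/ab" = c(1, 1, 1, 1, 1, 0, 0, 1, 0, 1, 1, 0),
    "Ab/aB" = c(1, 1, 1, 1, 0, 1, 1, 0, 1, 0, 0, 1),
    "Ab/Ab" = c(2, 0, 0, 0, 0, 0, 2, 0, 0, 0, 2, 0),
    "aB/aB" = c(0, 2, 0, 0, 0, 2, 0, 0, 0, 2, 0, 0),
    "AB/aB" = c(1, 2, 1, 0, 1, 1, 0, 0, 1, 1, 0, 0),
    "AB/Ab" = c(2, 1, 0, 1, 1, 0, 1, 0, 1, 0, 1, 0),
    "AB/AB" = c(2, 2, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0))
  colnames(m) <- c("GA", "GB", "DA", "DB",
                   "CisAB", "CisaB", "CisAb", "Cisab",
                   "TransAB", "TransaB", "TransAb", "Transab")
  storage.mode(m) <- "integer"
  m
}

# parse one diplotype label like "AB/ab" into a one-row diplotype_set
diplotype_from_label <- function(lab) {
  h <- strsplit(lab, "/")[[1]]
  al <- function(s, i, up) as.integer(substr(s, i, i) == up)
  diplotype_set(al(h[1], 1, "A"), al(h[1], 2, "B"),
                al(h[2], 1, "A"), al(h[2], 2, "B"))
}
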