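# Internal GLM machinery shared by the phase tests and benchmarks.
# Designs are built as explicit numeric matrices (no formula/model.frame
# overhead), fitted with stats::glm.fit, and hypotheses are tested by
# comparing a full and a reduced design (LRT), by a quadratic form in the
# full-fit coefficients (Wald), or by the Rao score evaluated at the
# reduced-model fit.

resolve_family <- function(family) {
  if (is.character(family)) family <- get(family, mode = "function")()
  if (is.function(family)) family <- family()
  if (!inherits(family, "family")) stop("invalid 'family'")
  if (!family$family %in% c("gaussian", "binomial"))
    stop("only gaussian and binomial families are supported")
  family
}

# Fit y ~ X by maximum likelihood.  Aliased (rank-deficient) columns are
# detected beforehand by a pivoted QR of the weighted-ish design and
# excluded, so the fit itself is full rank; their identity is recorded.
fit_design <- function(y, X, family) {
  family <- resolve_family(family)
  n <- length(y)
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  rank <- qrX$rank
  keep <- sort(qrX$pivot[seq_len(rank)])
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  Xk <- X[, keep, drop = FALSE]
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xk, y, family = family,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  status <- "ok"
  if (!fit$converged) status <- "not_converged"
  if (family$family == "binomial" && sep_warn &&
      any(abs(fit$coefficients) > 12)) status <- "separation"
  p <- fit$rank
  # dispersion: fixed at 1 for binomial; Pearson estimate for gaussian
  phi <- if (family$family == "binomial") 1 else
    sum(fit$weights * fit$residuals^2) / (n - p)
  coef_full <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  coef_full[keep] <- fit$coefficients
  # (X'WX)^{-1} on the kept columns, scaled by dispersion
  XtWX <- crossprod(Xk * sqrt(fit$weights))
  vc <- tryCatch(phi * chol2inv(chol(XtWX)), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(colnames(Xk), colnames(Xk))
  list(coefficients = coef_full, kept = colnames(Xk), aliased = aliased,
       vcov = vc, deviance = fit$deviance, phi = phi, rank = p,
       fitted = fit$fitted.values, weights = fit$weights,
       family = family, y = y, X = X, status = status, n = n)
}

# Joint test of the coefficients on `terms` (columns of the full design).
# df counts the tested columns that are estimable in the full fit.
test_terms <- function(full, terms, test = c("LRT", "Wald", "score"),
                       name = paste(terms, collapse = "+")) {
  test <- match.arg(test)
  missing_cols <- setdiff(terms, colnames(full$X))
  if (length(missing_cols))
    stop("tested term(s) not in design: ", paste(missing_cols, collapse = ", "))
  testable <- intersect(terms, full$kept)
  est <- full$coefficients[terms]
  se <- rep(NA_real_, length(terms)); names(se) <- terms
  if (!is.null(full$vcov))
    se[testable] <- sqrt(diag(full$vcov)[testable])
  if (full$status != "ok")
    return(phase_test(name, NA_real_, NA_integer_, NA_real_, est, se,
                      status = full$status, aliased = setdiff(terms, testable)))
  if (length(testable) == 0L)
    return(phase_test(name, NA_real_, NA_integer_, NA_real_, est, se,
                      status = "inestimable", aliased = terms))
  df <- length(testable)
  # aliased non-tested columns are excluded from the reduced design too:
  # they are not part of the operative (identified) model
  keep0 <- setdiff(full$kept, terms)
  stat <- switch(test,
    LRT = {
      red <- fit_design(full$y, full$X[, keep0, drop = FALSE], full$family)
      (red$deviance - full$deviance) / full$phi
    },
    Wald = {
      if (is.null(full$vcov)) return(
        phase_test(name, NA_real_, NA_integer_, NA_real_, est, se,
                   status = "inestimable", aliased = setdiff(terms, testable)))
      b <- full$coefficients[testable]
      V <- full$vcov[testable, testable, drop = FALSE]
      drop(crossprod(b, solve(V, b)))
    },
    score = {
      red <- fit_design(full$y, full$X[, keep0, drop = FALSE], full$family)
      Xk <- full$X[, full$kept, drop = FALSE]
      mu0 <- red$fitted
      w0 <- switch(full$family$family,
                   binomial = mu0 * (1 - mu0),
                   gaussian = rep(1, full$n))
      s <- crossprod(Xk, full$y - mu0)
      I <- crossprod(Xk * sqrt(w0))
      drop(crossprod(s, solve(I, s))) / full$phi
    })
  stat <- max(stat, 0)
  phase_test(name, stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
             est, se, status = "ok", aliased = setdiff(terms, testable),
             test = test)
}

#' Phase/epistasis test result
#'
#' Container returned by every hypothesis test in the package: the test
#' statistic and its chi-squared reference degrees of freedom, the p-value,
#' and per-term estimates with standard errors.  `status` is `"ok"` for a
#' clean fit; `"inestimable"` flags a tested term that is linearly
#' dependent on the adjustment columns (the statistic is then withheld
#' rather than silently testing a different hypothesis), and
#' `"not_converged"` / `"separation"` flag fitting failures.
#'
#' @param name test label.
#' @param statistic chi-squared statistic.
#' @param df degrees of freedom.
#' @param p_value p-value.
#' @param estimates,se named coefficient estimates and standard errors for
#'   the tested terms (`NA` for aliased terms).
#' @param status one of `"ok"`, `"inestimable"`, `"not_converged"`,
#'   `"separation"`.
#' @param aliased names of tested terms excluded for rank deficiency.
#' @param test which statistic was used (`"LRT"`, `"Wald"`, `"score"`).
#' @return An object of class `phase_test`.
#' @keywords internal
#' @export
phase_test <- function(name, statistic, df, p_value, estimates = NULL,
                       se = NULL, status = "ok", aliased = character(),
                       test = NA_character_) {
  if (status != "ok") { statistic <- NA_real_; p_value <- NA_real_ }
  structure(list(name = name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimates = estimates, se = se, status = status,
                 aliased = aliased, test = test),
            class = "phase_test")
}

#' @export
print.phase_test <- function(x, digits = 4L, ...) {
  cat("Test:", x$name,
      if (!is.na(x$test)) paste0("(", x$test, ")"), "\n")
  if (x$status != "ok") {
    cat("  status:", x$status)
    if (length(x$aliased))
      cat("  [aliased:", paste(x$aliased, collapse = ", "), "]")
    cat("\n")
  } else {
    cat(sprintf("  chisq = %.*g on %d df, p = %.*g\n",
                digits, x$statistic, x$df, digits, x$p_value))
    if (length(x$aliased))
      cat("  note: aliased term(s) excluded:",
          paste(x$aliased, collapse = ", "), "\n")
  }
  if (!is.null(x$estimates)) {
    tab <- cbind(estimate = x$estimates, se = x$se)
    print(round(tab, digits))
  }
  invisible(x)
}

#' @export
as.data.frame.phase_test <- function(x, ...) {
  data.frame(test = x$name, statistic = x$statistic, df = x$df,
             p_value = x$p_value, status = x$status,
             stringsAsFactors = FALSE)
}
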