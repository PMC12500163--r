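#' Construct a set of two-locus diplotypes
#'
#' A diplotype is the unordered pair of two-locus haplotypes carried by one
#' individual.  Each haplotype is described by two 0/1 allele indicators,
#' one per locus, where 1 marks the alternative allele (written `A` at the
#' first locus and `B` at the second) and 0 the reference allele (`a`, `b`).
#' Over two biallelic loci there are exactly ten distinct diplotypes, four
#' with the alternative alleles in cis and four in trans (plus the
#' configurations where phase is immaterial).
#'
#' Haplotype order within an individual carries no information, so the pair
#' is stored in a canonical order: `(h1, h2)` and `(h2, h1)` produce
#' identical objects.
#'
#' @param a1,b1 0/1 allele indicators at locus A and locus B on the first
#'   haplotype.
#' @param a2,b2 allele indicators on the second haplotype.
#' @return An object of class `diplotype_set`: a data frame with integer
#'   columns `a1`, `b1`, `a2`, `b2`, one row per individual.  Rows with any
#'   `NA` represent individuals whose phase is unobserved; they are kept so
#'   that sample alignment with phenotype tables is preserved, and dropped
#'   (with a count) by the fitting functions.
#' @examples
#' # one individual AB/ab (alternative alleles in cis) and one Ab/aB (trans)
#' d <- diplotype_set(a1 = c(1, 1), b1 = c(1, 0), a2 = c(0, 0), b2 = c(0, 1))
#' format(d)
#' @export
diplotype_set <- function(a1, b1, a2, b2) {
  n <- length(a1)
  if (length(b1) != n || length(a2) != n || length(b2) != n)
    stop("allele indicator vectors must have equal length")
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (any(!is.na(x) & !(x %in% c(0L, 1L))))
      stop("allele indicators must be 0, 1 or NA (column ", nm, ")")
    x
  }
  a1 <- chk(a1, "a1"); b1 <- chk(b1, "b1")
  a2 <- chk(a2, "a2"); b2 <- chk(b2, "b2")
  # canonical haplotype order: larger (a, b) pair first, so AB/ab == ab/AB
  swap <- !is.na(a1) & !is.na(a2) &
    (a1 * 2L + b1 < a2 * 2L + b2)
  swap[is.na(swap)] <- FALSE
  ta <- a1[swap]; tb <- b1[swap]
  a1[swap] <- a2[swap]; b1[swap] <- b2[swap]
  a2[swap] <- ta; b2[swap] <- tb
  out <- data.frame(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
  class(out) <- c("diplotype_set", "data.frame")
  out
}

#' All ten distinct two-locus diplotypes
#'
#' Returns the ten distinct diplotypes of two biallelic loci in the
#' conventional tabulation order (by increasing number of alternative
#' alleles, cis double heterozygote before trans).
#'
#' @return A `diplotype_set` with ten rows, row names giving the usual
#'   `"AB/ab"`-style labels.
#' @export
all_diplotypes <- function() {
  d <- diplotype_set(
    a1 = c(0, 1, 0, 1, 1, 1, 0, 1, 1, 1),
    b1 = c(0, 0, 1, 1, 0, 0, 1, 1, 1, 1),
    a2 = c(0, 0, 0, 0, 0, 1, 0, 0, 1, 1),
    b2 = c(0, 0, 0, 0, 1, 0, 1, 1, 0, 1))
  rownames(d) <- diplotype_labels(d)
  d
}

#' Human-readable diplotype labels
#'
#' @param d a `diplotype_set`.
#' @return Character vector like `"AB/ab"`; `NA` for rows with missing phase.
#' @export
diplotype_labels <- function(d) {
  hap <- function(a, b)
    paste0(ifelse(a == 1L, "A", "a"), ifelse(b == 1L, "B", "b"))
  out <- paste0(hap(d$a1, d$b1), "/", hap(d$a2, d$b2))
  out[!stats::complete.cases(d[, c("a1", "b1", "a2", "b2")])] <- NA_character_
  out
}

#' @export
format.diplotype_set <- function(x, ...) diplotype_labels(x)

#' @export
print.diplotype_set <- function(x, max = 10L, ...) {
  n <- nrow(x)
  cat("diplotype_set:", n, "individuals\n")
  lab <- diplotype_labels(x)
  shown <- utils::head(lab, max)
  cat(" ", paste(shown, collapse = " "), if (n > max) "..." else "", "\n")
  invisible(x)
}
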