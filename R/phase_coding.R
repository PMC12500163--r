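#' Additive phasetype coding of two-locus diplotypes
#'
#' Encodes each diplotype into the full set of per-individual regression
#' terms: additive genotypes `GA`, `GB` (count of alternative alleles at
#' each locus), dominance indicators `DA`, `DB` (1 for a heterozygous
#' genotype, 0 otherwise), and the eight additive phasetypes.  The
#' phasetype `Cis_ij` counts how many of the individual's two haplotypes
#' carry allele `i` at the first locus together with allele `j` at the
#' second; `Trans_ij` counts how often `i` and `j` occur on *opposite*
#' haplotypes.  Both take values in 0, 1, 2 and each group of four sums to
#' 2 for every diplotype.
#'
#' The columns satisfy the linear identities
#' `CisAB + CisAb = TransAB + TransAb = GA` and
#' `CisAB + CisaB = TransAB + TransaB = GB`, which is what makes the
#' downstream phase tests invariant to the choice of reference alleles.
#'
#' @param d a [diplotype_set].
#' @return An integer matrix with one row per individual and columns
#'   `GA, GB, DA, DB, CisAB, CisaB, CisAb, Cisab, TransAB, TransaB,
#'   TransAb, Transab`.  Rows for individuals with unobserved phase are
#'   `NA`.
#' @examples
#' phasetypes(all_diplotypes())
#' @export
phasetypes <- function(d) {
  stopifnot(inherits(d, "diplotype_set"))
  a1 <- d$a1; b1 <- d$b1; a2 <- d$a2; b2 <- d$b2
  GA <- a1 + a2
  GB <- b1 + b2
  out <- cbind(
    GA = GA,
    GB = GB,
    DA = as.integer(GA == 1L),
    DB = as.integer(GB == 1L),
    CisAB   = (a1 & b1) + (a2 & b2),
    CisaB   = (!a1 & b1) + (!a2 & b2),
    CisAb   = (a1 & !b1) + (a2 & !b2),
    Cisab   = (!a1 & !b1) + (!a2 & !b2),
    TransAB = (a1 & b2) + (a2 & b1),
    TransaB = (!a1 & b2) + (!a2 & b1),
    TransAb = (a1 & !b2) + (a2 & !b1),
    Transab = (!a1 & !b2) + (!a2 & !b1))
  storage.mode(out) <- "integer"
  rownames(out) <- rownames(d)
  out
}

#' Re-express a phasetype coding under different reference alleles
#'
#' The phasetype columns are by default oriented on the alternative alleles
#' (`A`, `B`).  Choosing the other allele as the "counted" allele at either
#' locus relabels the coding: genotype counts flip (`GA` becomes `2 - GA`),
#' dominance terms are unchanged, and the cis/trans columns permute.  No
#' information is gained or lost, and the phase tests are invariant to this
#' choice.
#'
#' @param code a phasetype matrix as returned by [phasetypes()].
#' @param refA,refB which allele is counted at each locus: `"A"`/`"B"`
#'   (the default orientation) or `"a"`/`"b"`.
#' @return A phasetype matrix in the same column layout, expressed in the
#'   requested orientation.  Applying the same swap twice returns the
#'   original coding.
#' @export
recode_reference <- function(code, refA = c("A", "a"), refB = c("B", "b")) {
  refA <- match.arg(refA)
  refB <- match.arg(refB)
  code <- as.matrix(code)
  stopifnot(all(phasetype_cols %in% colnames(code)))
  out <- code
  if (refA == "a") {
    out[, "GA"] <- 2L - out[, "GA"]
    out <- swap_cols(out, c(CisAB = "CisaB", CisAb = "Cisab",
                            TransAB = "TransaB", TransAb = "Transab"))
  }
  if (refB == "b") {
    out[, "GB"] <- 2L - out[, "GB"]
    out <- swap_cols(out, c(CisAB = "CisAb", CisaB = "Cisab",
                            TransAB = "TransAb", TransaB = "Transab"))
  }
  out
}

phasetype_cols <- c("GA", "GB", "DA", "DB",
                    "CisAB", "CisaB", "CisAb", "Cisab",
                    "TransAB", "TransaB", "TransAb", "Transab")

swap_cols <- function(m, pairs) {
  for (i in seq_along(pairs)) {
    a <- names(pairs)[i]; b <- pairs[i]
    tmp <- m[, a]
    m[, a] <- m[, b]
    m[, b] <- tmp
  }
  m
}

#' Check the linear identities of a phasetype coding
#'
#' Every valid phasetype coding satisfies a fixed set of linear identities:
#' the four cis counts and the four trans counts each sum to 2; the cis and
#' trans counts involving a given allele sum to that allele's genotype; the
#' dominance indicators flag heterozygotes; and the affine relation
#' `Cisab = 2 - GA - GB + CisAB` (and its trans analogue) that underlies
#' reference-allele invariance.
#'
#' @param code a phasetype matrix (one or more rows) in the layout of
#'   [phasetypes()].
#' @return Character vector naming every identity violated in at least one
#'   row; `character(0)` if the coding is internally consistent.
#' @export
verify_identities <- function(code) {
  code <- rbind(as.matrix(code))
  if (is.null(colnames(code)) && ncol(code) == 12L)
    colnames(code) <- phasetype_cols
  stopifnot(all(phasetype_cols %in% colnames(code)))
  g <- function(nm) code[, nm]
  checks <- list(
    cis_sum    = g("CisAB") + g("CisaB") + g("CisAb") + g("Cisab") == 2L,
    trans_sum  = g("TransAB") + g("TransaB") + g("TransAb") + g("Transab") == 2L,
    cis_GA     = g("CisAB") + g("CisAb") == g("GA"),
    trans_GA   = g("TransAB") + g("TransAb") == g("GA"),
    cis_GB     = g("CisAB") + g("CisaB") == g("GB"),
    trans_GB   = g("TransAB") + g("TransaB") == g("GB"),
    dominance_A = g("DA") == as.integer(g("GA") == 1L),
    dominance_B = g("DB") == as.integer(g("GB") == 1L),
    cis_ab_affine = g("Cisab") == 2L - g("GA") - g("GB") + g("CisAB"),
    trans_ab_affine = g("Transab") == 2L - g("GA") - g("GB") + g("TransAB"))
  bad <- vapply(checks, function(ok) any(!ok, na.rm = TRUE), logical(1))
  names(checks)[bad]
}

#' Multi-allelic phasetype coding
#'
#' Extends the phasetype coding to loci with more than two alleles (for
#' example a haplotype block treated as one multi-allelic marker, see
#' [block_to_marker()]).  For allele sets of sizes `m` and `n`, each
#' individual gets additive and dominance genotype counts per non-reference
#' allele and cis/trans counts for every allele pair: `cis[i, j]` counts
#' haplotypes carrying `Ai` with `Bj`, `trans[i, j]` counts co-occurrence
#' of `Ai` and `Bj` on opposite haplotypes.  With `m = n = 2` this reduces
#' exactly to [phasetypes()].
#'
#' @param hapA1,hapB1 allele labels on the first haplotype at locus A and
#'   locus B (character vectors, one element per individual).
#' @param hapA2,hapB2 labels on the second haplotype.
#' @param allelesA,allelesB the allele sets.  If `NULL`, the observed
#'   labels are used.  The first element is the reference allele when
#'   `ref = "first"`.
#' @param ref how the reference allele is chosen: `"frequency"` (default)
#'   takes the most frequent allele in the cohort (ties broken by
#'   lexicographic order), `"first"` takes the first element of each
#'   allele set.
#' @return An object of class `multiallelic_phasetypes`: a list with the
#'   count matrices `G_A` (n-by-m), `D_A`, `G_B`, `D_B`, `cis` and `trans`
#'   (n-by-mn, columns named `"Ai:Bj"`), the allele sets (reference allele
#'   first) and the chosen references `refA`, `refB`.
#' @export
multiallelic_phasetypes <- function(hapA1, hapB1, hapA2, hapB2,
                                    allelesA = NULL, allelesB = NULL,
                                    ref = c("frequency", "first")) {
  ref <- match.arg(ref)
  hapA1 <- as.character(hapA1); hapA2 <- as.character(hapA2)
  hapB1 <- as.character(hapB1); hapB2 <- as.character(hapB2)
  n_ind <- length(hapA1)
  stopifnot(length(hapB1) == n_ind, length(hapA2) == n_ind,
            length(hapB2) == n_ind)

  order_alleles <- function(obs, declared, locus) {
    if (is.null(declared)) declared <- sort(unique(obs))
    unknown <- setdiff(unique(obs), declared)
    if (length(unknown))
      stop("unknown allele label(s) at locus ", locus, ": ",
           paste(unknown, collapse = ", "))
    if (ref == "frequency") {
      cnt <- table(factor(obs, levels = declared))
      # most frequent first; ties by lexicographic label order
      declared <- declared[order(-as.integer(cnt[declared]), declared)]
    }
    declared
  }
  allelesA <- order_alleles(c(hapA1, hapA2), allelesA, "A")
  allelesB <- order_alleles(c(hapB1, hapB2), allelesB, "B")
  m <- length(allelesA); n_b <- length(allelesB)

  ind <- function(x, lev) outer(x, lev, `==`) * 1L   # n x k indicator
  IA1 <- ind(hapA1, allelesA); IA2 <- ind(hapA2, allelesA)
  IB1 <- ind(hapB1, allelesB); IB2 <- ind(hapB2, allelesB)

  G_A <- IA1 + IA2; G_B <- IB1 + IB2
  D_A <- (G_A == 1L) * 1L; D_B <- (G_B == 1L) * 1L
  colnames(G_A) <- colnames(D_A) <- allelesA
  colnames(G_B) <- colnames(D_B) <- allelesB

  pair_names <- as.vector(outer(allelesA, allelesB,
                                function(i, j) paste0(i, ":", j)))
  cis <- matrix(0L, n_ind, m * n_b, dimnames = list(NULL, pair_names))
  trans <- cis
  for (i in seq_len(m)) for (j in seq_len(n_b)) {
    nm <- paste0(allelesA[i], ":", allelesB[j])
    cis[, nm]   <- IA1[, i] * IB1[, j] + IA2[, i] * IB2[, j]
    trans[, nm] <- IA1[, i] * IB2[, j] + IA2[, i] * IB1[, j]
  }
  structure(list(G_A = G_A, D_A = D_A, G_B = G_B, D_B = D_B,
                 cis = cis, trans = trans,
                 allelesA = allelesA, allelesB = allelesB,
                 refA = allelesA[1L], refB = allelesB[1L]),
            class = "multiallelic_phasetypes")
}

#' @export
print.multiallelic_phasetypes <- function(x, ...) {
  cat("multiallelic_phasetypes:", nrow(x$G_A), "individuals;",
      length(x$allelesA), "alleles at locus A (ref", x$refA, "),",
      length(x$allelesB), "at locus B (ref", x$refB, ")\n")
  invisible(x)
}

#' Collapse a phased variant window into one multi-allelic marker
#'
#' Treats each distinct haplotype over a window of phased variants as one
#' allele of a multi-allelic marker, so that an LD block can enter the
#' phase tests through the multi-allelic coding.  Haplotype labels are the
#' concatenated 0/1 alleles of the window's variants in genomic order; the
#' most frequent haplotype becomes the reference allele (frequency ties
#' broken lexicographically).
#'
#' @param hap1,hap2 numeric or integer matrices (individuals by variants)
#'   with the 0/1 allele carried by each haplotype at each variant of the
#'   window, columns in genomic order.  `NA` marks a variant whose phase
#'   (or genotype) is unobserved for that individual.
#' @return A list with `labels1`, `labels2` (haplotype-string allele labels
#'   per individual, `NA` for excluded individuals), `alleles` (labels in
#'   reference-first order), `freq` (named relative frequencies among
#'   retained haplotypes), `ref`, and `n_excluded`.
#' @export
block_to_marker <- function(hap1, hap2) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  stopifnot(identical(dim(hap1), dim(hap2)))
  bad <- !stats::complete.cases(hap1) | !stats::complete.cases(hap2)
  if (any(bad))
    warning(sum(bad), " individual(s) excluded: phase unobserved for ",
            "at least one variant in the window")
  collapse <- function(h) apply(h, 1L, paste0, collapse = "")
  labels1 <- collapse(hap1); labels2 <- collapse(hap2)
  labels1[bad] <- NA_character_; labels2[bad] <- NA_character_
  obs <- c(labels1[!bad], labels2[!bad])
  if (length(unique(obs)) < 2L)
    stop("monomorphic block: only one distinct haplotype in the window")
  cnt <- table(obs)
  alleles <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  freq <- as.numeric(cnt[alleles]) / sum(cnt)
  names(freq) <- alleles
  list(labels1 = labels1, labels2 = labels2, alleles = alleles,
       freq = freq, ref = alleles[1L], n_excluded = sum(bad))
}
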