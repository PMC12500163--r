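#' Read phased genotypes from a VCF file
#'
#' Parses the GT (and, when present, PS phase-set) fields of a VCF 4.x
#' file.  A `|` separator marks a phased call; a `/` heterozygote is
#' unphased and cannot contribute to phase analysis.  Haplotype order is
#' meaningful only within a sample's phase set, so two variants are
#' phase-comparable for a sample only when their PS tags agree (or when no
#' PS tag is present, in which case the whole record set is treated as one
#' phase set).
#'
#' @param path VCF file path (plain or bgzipped).
#' @param variants optional character vector of variant IDs or
#'   `"chrom:pos"` keys to retain; an absent variant is an error.
#' @param haploid accept haploid GT calls (e.g. male X).  Default `FALSE`:
#'   a haploid call is an error, since the trans phasetype is undefined
#'   for a single haplotype.
#' @return An object of class `phased_genotypes`: a list with `samples`,
#'   `variants` (data frame: `chrom`, `pos`, `id`, `ref`, `alt`),
#'   and per-variant-by-sample matrices `allele1`, `allele2` (allele
#'   indices, `NA` for missing), `phased` (logical) and `ps` (phase set,
#'   `NA` when untagged).
#' @export
read_phased_vcf <- function(path, variants = NULL, haploid = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  vinfo <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  key <- paste0(vinfo$chrom, ":", vinfo$pos)
  if (!is.null(variants)) {
    idx <- match(variants, vinfo$id)
    idx[is.na(idx)] <- match(variants[is.na(idx)], key)
    if (anyNA(idx))
      stop("variant(s) not found in VCF: ",
           paste(variants[is.na(idx)], collapse = ", "))
  } else idx <- seq_len(nrow(vinfo))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ps <- tryCatch(vcfR::extract.gt(vcf, element = "PS"),
                 error = function(e) NULL)
  gt <- gt[idx, , drop = FALSE]
  ps <- if (is.null(ps)) matrix(NA_character_, nrow(gt), ncol(gt))
        else ps[idx, , drop = FALSE]
  vinfo <- vinfo[idx, , drop = FALSE]

  parse_one <- function(g, where) {
    if (is.na(g) || g %in% c(".", "./.", ".|."))
      return(c(NA_integer_, NA_integer_, NA))
    phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) == 1L) {
      if (!haploid)
        stop("haploid GT '", g, "' at ", where,
             "; haploid calls are only accepted with haploid = TRUE")
      a <- if (parts == ".") NA_integer_ else as.integer(parts)
      return(c(a, NA_integer_, TRUE))
    }
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(
        parts[parts != "."]))))
      stop("malformed GT field '", g, "' at ", where)
    a <- suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
    c(a[1L], a[2L], phased)
  }
  nv <- nrow(gt); ns <- ncol(gt)
  a1 <- a2 <- matrix(NA_integer_, nv, ns, dimnames = dimnames(gt))
  phased <- matrix(NA, nv, ns, dimnames = dimnames(gt))
  for (i in seq_len(nv)) for (j in seq_len(ns)) {
    where <- paste0(vinfo$chrom[i], ":", vinfo$pos[i],
                    " sample ", colnames(gt)[j])
    v <- parse_one(gt[i, j], where)
    a1[i, j] <- v[1L]; a2[i, j] <- v[2L]; phased[i, j] <- as.logical(v[3L])
  }
  structure(list(samples = colnames(gt), variants = vinfo,
                 allele1 = a1, allele2 = a2, phased = phased, ps = ps),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", nrow(x$variants), "variant(s),",
      length(x$samples), "sample(s)\n")
  print(x$variants, row.names = FALSE)
  invisible(x)
}

#' Build two-locus diplotypes from phased VCF genotypes
#'
#' Selects two biallelic variants and assembles each sample's two-locus
#' diplotype from the phased GT calls.  A sample contributes phase
#' information only if (i) every heterozygous call among the two variants
#' is phased, and (ii) the two variants lie in the same phase set when PS
#' tags are present.  Other samples get an `NA` diplotype (they are
#' counted and dropped by the fitting functions); their genotypes are
#' still reported.
#'
#' @param pg a [read_phased_vcf()] result.
#' @param varA,varB variant IDs or `"chrom:pos"` keys.
#' @return List with `diplotypes` (a [diplotype_set], `NA` rows for
#'   samples without usable phase), `GA`, `GB` (genotype counts from all
#'   samples with called genotypes), `samples`, and `n_unphased`.
#' @export
diplotypes_from_vcf <- function(pg, varA, varB) {
  stopifnot(inherits(pg, "phased_genotypes"))
  key <- paste0(pg$variants$chrom, ":", pg$variants$pos)
  pick <- function(v) {
    i <- match(v, pg$variants$id)
    if (is.na(i)) i <- match(v, key)
    if (is.na(i)) stop("variant not found: ", v)
    i
  }
  ia <- pick(varA); ib <- pick(varB)
  for (i in c(ia, ib)) {
    if (grepl(",", pg$variants$alt[i], fixed = TRUE))
      stop("variant ", pg$variants$id[i], " is multi-allelic; ",
           "use the multi-allelic coding (multiallelic_phasetypes)")
  }
  bad_allele <- function(a) !is.na(a) & a > 1L
  if (any(bad_allele(pg$allele1[c(ia, ib), ])) ||
      any(bad_allele(pg$allele2[c(ia, ib), ])))
    stop("allele index > 1 at a biallelic record; malformed VCF")

  a1 <- pg$allele1[ia, ]; a2 <- pg$allele2[ia, ]
  b1 <- pg$allele1[ib, ]; b2 <- pg$allele2[ib, ]
  GA <- a1 + a2; GB <- b1 + b2
  hetA <- !is.na(GA) & GA == 1L
  hetB <- !is.na(GB) & GB == 1L
  ok_phaseA <- !hetA | (pg$phased[ia, ] %in% TRUE)
  ok_phaseB <- !hetB | (pg$phased[ib, ] %in% TRUE)
  same_ps <- is.na(pg$ps[ia, ]) | is.na(pg$ps[ib, ]) |
    pg$ps[ia, ] == pg$ps[ib, ]
  # a sample needs a consistent phase set only if both sites are het
  usable <- !is.na(GA) & !is.na(GB) & ok_phaseA & ok_phaseB &
    (!(hetA & hetB) | same_ps)
  n_unphased <- sum(!usable)
  if (n_unphased > 0)
    warning(n_unphased, " sample(s) excluded from phase analysis: ",
            "missing genotype, unphased heterozygote, or phase-set mismatch")
  d <- diplotype_set(ifelse(usable, a1, NA), ifelse(usable, b1, NA),
                     ifelse(usable, a2, NA), ifelse(usable, b2, NA))
  list(diplotypes = d, GA = GA, GB = GB, samples = pg$samples,
       n_unphased = n_unphased)
}

#' Write a cohort of diplotypes to a minimal phased VCF
#'
#' Serializes a [diplotype_set] as two phased biallelic records; mainly
#' useful for round-trip checks and for preparing small example inputs.
#'
#' @param d a [diplotype_set].
#' @param path output path.
#' @param sample_ids optional sample names (default `S1...Sn`).
#' @param chrom,posA,posB coordinates to write.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(d, path, sample_ids = NULL,
                             chrom = "1", posA = 100L, posB = 200L) {
  stopifnot(inherits(d, "diplotype_set"))
  n <- nrow(d)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  gt <- function(x1, x2)
    ifelse(is.na(x1) | is.na(x2), "./.", paste0(x1, "|", x2))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  rowA <- paste(c(chrom, posA, "varA", "A", "T", ".", ".", ".", "GT",
                  gt(d$a1, d$a2)), collapse = "\t")
  rowB <- paste(c(chrom, posB, "varB", "C", "G", ".", ".", ".", "GT",
                  gt(d$b1, d$b2)), collapse = "\t")
  writeLines(c(header, rowA, rowB), path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Reads a delimited table with a header row and a mandatory `sample_id`
#' column.  Duplicate sample ids are an error.
#'
#' @param path TSV/CSV path (delimiter inferred from the extension;
#'   default tab).
#' @return Data frame with `sample_id` as character.
#' @export
read_phenotypes <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(ph))
    stop("phenotype table must contain a 'sample_id' column")
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample ids in phenotype table")
  ph
}

# inner join of phenotypes onto genotype sample order; errors on an empty
# intersection and reports the join count
align_phenotypes <- function(ph, samples, response, covariates = NULL) {
  idx <- match(samples, ph$sample_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("0 samples after join of genotypes and phenotypes")
  message(sum(keep), " of ", length(samples),
          " genotyped samples matched to phenotypes")
  ph2 <- ph[idx[keep], , drop = FALSE]
  if (!response %in% names(ph2))
    stop("response column not found: ", response)
  y <- ph2[[response]]
  if (!is.numeric(y)) stop("response column must be numeric: ", response)
  covs <- NULL
  if (!is.null(covariates) && length(covariates)) {
    miss <- setdiff(covariates, names(ph2))
    if (length(miss)) stop("covariate column(s) not found: ",
                           paste(miss, collapse = ", "))
    covs <- ph2[, covariates, drop = FALSE]
  }
  list(keep = keep, response = y, covariates = covs, table = ph2)
}
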