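#' Construct a genotype matrix object
#'
#' The central container of the package: an n_samples x n_variants matrix of
#' allele-dosage codes (0/1/2 counting the minor allele `allele_a1`, `NA` for
#' missing) together with per-variant metadata and a binary case/control
#' phenotype.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_a1`, `allele_a2`, `maf` (one row per genotype column).
#' @param samples character vector of sample ids (one per genotype row).
#' @param phenotype integer vector: 1 = case, 0 = control, NA = missing.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, variants, samples, phenotype) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(
    nrow(genotypes) == length(samples),
    nrow(genotypes) == length(phenotype),
    ncol(genotypes) == nrow(variants)
  )
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  req <- c("snp_id", "chrom", "pos_bp", "allele_a1", "allele_a2", "maf")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$snp_id)) stop("duplicate snp ids in variants")
  rownames(genotypes) <- samples
  colnames(genotypes) <- variants$snp_id
  structure(
    list(
      genotypes = genotypes,
      variants = as.data.frame(variants, stringsAsFactors = FALSE),
      samples = as.character(samples),
      phenotype = as.integer(phenotype)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%d cases / %d controls)\n",
    length(x$samples), nrow(x$variants),
    sum(x$phenotype == 1L, na.rm = TRUE), sum(x$phenotype == 0L, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by variant
#'
#' @param gm a `genotype_matrix`.
#' @param snps character snp ids or integer/logical column index.
#' @return a `genotype_matrix` restricted to the selected variants, in the
#'   requested order.
#' @export
subset_variants <- function(gm, snps) {
  if (is.character(snps)) {
    idx <- match(snps, gm$variants$snp_id)
    if (anyNA(idx)) stop("unknown snp id(s): ", paste(snps[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_len(ncol(gm$genotypes))[snps]
  }
  genotype_matrix(
    gm$genotypes[, idx, drop = FALSE],
    gm$variants[idx, , drop = FALSE],
    gm$samples,
    gm$phenotype
  )
}

#' Extract one variant's genotype codes
#'
#' @param gm a `genotype_matrix`.
#' @param snp_id a single snp id.
#' @return integer vector of codes for that variant.
#' @export
genotype_column <- function(gm, snp_id) {
  idx <- match(snp_id, gm$variants$snp_id)
  if (is.na(idx)) stop("unknown snp id: ", snp_id)
  gm$genotypes[, idx]
}

# Orient codes so allele_a1 is the empirical minor allele; ties keep the
# incoming designation. Returns list(genotypes, a1, a2, maf) with columns
# flipped (code -> 2 - code) where the incoming a1 frequency exceeded 0.5.
orient_minor_allele <- function(genotypes, a1, a2) {
  m <- ncol(genotypes)
  maf <- numeric(m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    nm <- g[!is.na(g)]
    if (!length(nm)) {
      maf[j] <- NA_real_
      next
    }
    f <- sum(nm) / (2 * length(nm))
    if (f > 0.5) {
      genotypes[, j] <- 2L - genotypes[, j]
      tmp <- a1[j]; a1[j] <- a2[j]; a2[j] <- tmp
      f <- 1 - f
    }
    maf[j] <- f
  }
  list(genotypes = genotypes, a1 = a1, a2 = a2, maf = maf)
}
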