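#' Minor allele frequency of one genotype column
#'
#' @param genotype_column integer codes in \{0, 1, 2, NA\}.
#' @return `min(f, 1 - f)` where `f` is the counted-allele frequency over
#'   non-missing genotypes; always in [0, 0.5].
#' @export
compute_maf <- function(genotype_column) {
  g <- genotype_column[!is.na(genotype_column)]
  if (!length(g)) stop("MAF is undefined: all genotypes missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the conditional distribution of heterozygote counts
#' given the allele counts: the P-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one. This is the
#' standard exact HWE test; the asymptotic chi-square is unreliable in the
#' far tail where QC thresholds such as 0.001 operate.
#'
#' @param genotype_column integer codes in \{0, 1, 2, NA\}.
#' @return exact P-value in (0, 1].
#' @export
hwe_exact_p <- function(genotype_column) {
  g <- genotype_column[!is.na(genotype_column)]
  if (!length(g)) stop("HWE is undefined: all genotypes missing")
  hwe_exact_p_counts(sum(g == 2L), sum(g == 1L), sum(g == 0L))
}

#' Exact HWE test from genotype counts
#'
#' @param hom_minor,het,hom_major genotype counts.
#' @return exact P-value.
#' @export
hwe_exact_p_counts <- function(hom_minor, het, hom_major) {
  n <- hom_minor + het + hom_major
  if (n < 1L) stop("HWE is undefined with no genotypes")
  rare <- 2L * hom_minor + het
  if (rare > n) rare <- 2L * n - rare         # work with the minor allele
  if (rare == 0L) return(1.0)                 # monomorphic: one outcome
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  n_aa <- (rare - hets) %/% 2L
  n_bb <- n - n_aa - hets
  logp <- lfactorial(n) - lfactorial(n_aa) - lfactorial(hets) -
    lfactorial(n_bb) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(het, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Quality-control thresholds
#'
#' @param maf_min minimum minor allele frequency (default 0.05, the
#'   interaction-scan threshold; the pathway-analysis convention is 0.01).
#' @param hwe_p_min minimum exact Hardy-Weinberg P (default 0.001).
#' @param max_missing_per_snp maximum per-SNP missing fraction (default 0.05).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 0.001,
                          max_missing_per_snp = 0.05) {
  stopifnot(
    maf_min >= 0, maf_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
    max_missing_per_snp >= 0, max_missing_per_snp <= 1
  )
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 max_missing_per_snp = max_missing_per_snp),
            class = "qc_thresholds")
}

#' Apply per-SNP QC filters
#'
#' Drops SNPs with MAF below `maf_min`, exact HWE P below `hwe_p_min`, or
#' missing fraction above `max_missing_per_snp`; survivor order is preserved.
#' Per-filter drop counts are reported via `message()` and attached as the
#' `"qc_drops"` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] object.
#' @param hwe_stratum `"all"` (default) computes HWE on all samples,
#'   `"controls"` on controls only.
#' @return the filtered `genotype_matrix`.
#' @export
qc_filter <- function(gm, thresholds = qc_thresholds(), hwe_stratum = c("all", "controls")) {
  hwe_stratum <- match.arg(hwe_stratum)
  G <- gm$genotypes
  hweG <- if (hwe_stratum == "controls") {
    G[!is.na(gm$phenotype) & gm$phenotype == 0L, , drop = FALSE]
  } else G
  maf <- apply(G, 2L, compute_maf)
  hwe <- apply(hweG, 2L, hwe_exact_p)
  missf <- colMeans(is.na(G))
  fail_maf <- maf < thresholds$maf_min
  fail_hwe <- hwe < thresholds$hwe_p_min
  fail_mis <- missf > thresholds$max_missing_per_snp
  keep <- !(fail_maf | fail_hwe | fail_mis)
  message(sprintf(
    "qc_filter (HWE on %s): %d/%d SNPs retained (dropped: maf %d, hwe %d, missing %d)",
    hwe_stratum, sum(keep), length(keep), sum(fail_maf), sum(fail_hwe), sum(fail_mis)
  ))
  if (!any(keep)) warning("qc_filter removed every SNP")
  out <- subset_variants(gm, keep)
  attr(out, "qc_drops") <- c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                             missing = sum(fail_mis))
  out
}
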