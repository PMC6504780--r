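# Shared fixture builders; everything is generated in code, seeded.

# Toy genotype matrix straight from a code matrix (no file I/O).
toy_gm <- function(G, phenotype, chrom = rep("1", ncol(G)),
                   pos = seq_len(ncol(G)) * 1000L) {
  m <- ncol(G)
  maf <- apply(G, 2L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  })
  variants <- data.frame(
    snp_id = sprintf("rsT%03d", seq_len(m)), chrom = chrom, pos_bp = pos,
    allele_a1 = rep("A", m), allele_a2 = rep("G", m), maf = maf,
    stringsAsFactors = FALSE
  )
  genotype_matrix(G, variants, sprintf("id%03d", seq_len(nrow(G))), phenotype)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "gwepi", mustWork = TRUE)
}

# Independent brute-force allele-pair table: explicit per-sample loop over
# the four cells (the oracle for the vectorised construction).
brute_pair_table <- function(g1, g2) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    c1 <- c(2 - g1[i], g1[i])   # index 1 = a2, 2 = a1
    c2 <- c(2 - g2[i], g2[i])
    for (j in 1:2) for (k in 1:2) {
      tab[3 - j, 3 - k] <- tab[3 - j, 3 - k] + 0.5 * c1[j] * c2[k]
    }
  }
  tab
}

# Exhaustive-permutation HWE oracle for tiny samples: enumerates every
# distinct ordering of the allele multiset into n ordered diploid slots.
enumerate_hwe_distribution <- function(n, rare) {
  alleles <- c(rep(1L, rare), rep(0L, 2L * n - rare))
  perms <- unique_perms(alleles)
  hets <- vapply(perms, function(p) {
    sum(p[seq(1, 2 * n, 2)] != p[seq(2, 2 * n, 2)])
  }, integer(1))
  tab <- table(hets)
  stats::setNames(as.numeric(tab) / length(perms), names(tab))
}

unique_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1L]] <- c(v, p)
  }
  unique(out)
}
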