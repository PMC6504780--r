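#' Cohort specification for the synthetic generators
#'
#' Defaults mirror the study design the analysis targets: an all-female
#' case/control cohort of 493 extremely obese cases and 537 never-overweight
#' controls genotyped on a common-variant panel (MAF >= 0.05).
#'
#' @param n_cases,n_controls stratum sizes (defaults 493 and 537).
#' @param m_snps number of SNPs.
#' @param maf_range MAF sampling interval, a subset of (0, 0.5].
#' @param missing_rate per-genotype missingness probability (default 0).
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 493L, n_controls = 537L, m_snps = 100L,
                        maf_range = c(0.05, 0.5), missing_rate = 0, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, m_snps >= 1L,
            maf_range[1L] >= 0.01, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L],
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 m_snps = as.integer(m_snps), maf_range = maf_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Assemble a genotype_matrix from raw simulated codes on a synthetic map.
build_sim_matrix <- function(G, phenotype, chrom = "1", pos_step = 5000L) {
  n <- nrow(G); m <- ncol(G)
  orc <- orient_minor_allele(G, rep("A", m), rep("B", m))
  variants <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)), chrom = chrom,
    pos_bp = seq_len(m) * pos_step, allele_a1 = orc$a1, allele_a2 = orc$a2,
    maf = orc$maf, stringsAsFactors = FALSE
  )
  genotype_matrix(orc$genotypes, variants,
                  sprintf("s%04d", seq_len(n)), phenotype)
}

apply_missingness <- function(G, rate) {
  if (rate > 0) G[stats::runif(length(G)) < rate] <- NA_integer_
  G
}

#' Simulate a null case/control cohort
#'
#' Per-SNP MAFs are drawn uniformly from `maf_range`; genotypes are
#' `Binomial(2, maf)` independent of phenotype; the first `n_cases` samples
#' are labelled cases. Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return a [genotype_matrix()]; the drawn MAFs are in attribute
#'   `"true_maf"`.
#' @export
simulate_null_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  mafs <- stats::runif(spec$m_snps, spec$maf_range[1L], spec$maf_range[2L])
  G <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  G <- apply_missingness(G, spec$missing_rate)
  gm <- build_sim_matrix(G, c(rep(1L, spec$n_cases), rep(0L, spec$n_controls)))
  attr(gm, "true_maf") <- mafs
  gm
}

#' Epistatic effect specification
#'
#' @param snp1_index,snp2_index panel indices of the interacting SNP pair.
#' @param b0,b1,b2,b3 logit-scale intercept, marginal and interaction
#'   coefficients of the penetrance model
#'   `logit P(case) = b0 + b1 g1 + b2 g2 + b3 g1 g2`.
#' @return an `epistasis_spec` list.
#' @export
epistasis_spec <- function(snp1_index, snp2_index, b0 = 0, b1 = 0, b2 = 0, b3 = 0) {
  stopifnot(snp1_index != snp2_index, snp1_index >= 1L, snp2_index >= 1L)
  structure(list(snp1_index = as.integer(snp1_index),
                 snp2_index = as.integer(snp2_index),
                 b0 = b0, b1 = b1, b2 = b2, b3 = b3),
            class = "epistasis_spec")
}

#' Simulate a cohort with a planted SNP-SNP interaction
#'
#' Individuals are drawn with null genotypes and assigned case status with
#' probability `plogis(b0 + b1 g1 + b2 g2 + b3 g1 g2)`; draws are rejected
#' until the case and control quotas are both met (ascertainment sampling),
#' with a hard cap of 1e7 draws. Background SNPs are independent of the
#' phenotype.
#'
#' @param spec a [cohort_spec()].
#' @param effect an [epistasis_spec()] (indices within `spec$m_snps`).
#' @return a [genotype_matrix()].
#' @export
simulate_epistatic_cohort <- function(spec, effect) {
  stopifnot(effect$snp1_index <= spec$m_snps, effect$snp2_index <= spec$m_snps)
  set.seed(spec$seed)
  mafs <- stats::runif(spec$m_snps, spec$maf_range[1L], spec$maf_range[2L])
  need_ca <- spec$n_cases; need_co <- spec$n_controls
  got_ca <- 0L; got_co <- 0L
  keep <- vector("list", 0L)
  drawn <- 0L
  batch <- max(1000L, need_ca + need_co)
  while (got_ca < need_ca || got_co < need_co) {
    if (drawn >= 1e7) stop("case/control quotas unattainable within 1e7 draws")
    G <- vapply(mafs, function(p) stats::rbinom(batch, 2L, p), integer(batch))
    drawn <- drawn + batch
    g1 <- G[, effect$snp1_index]; g2 <- G[, effect$snp2_index]
    pr <- stats::plogis(effect$b0 + effect$b1 * g1 + effect$b2 * g2 +
                          effect$b3 * g1 * g2)
    y <- stats::rbinom(batch, 1L, pr)
    ca_rows <- which(y == 1L); co_rows <- which(y == 0L)
    ca_rows <- ca_rows[seq_len(min(length(ca_rows), need_ca - got_ca))]
    co_rows <- co_rows[seq_len(min(length(co_rows), need_co - got_co))]
    if (length(ca_rows)) {
      keep[[length(keep) + 1L]] <- cbind(G[ca_rows, , drop = FALSE], 1L)
      got_ca <- got_ca + length(ca_rows)
    }
    if (length(co_rows)) {
      keep[[length(keep) + 1L]] <- cbind(G[co_rows, , drop = FALSE], 0L)
      got_co <- got_co + length(co_rows)
    }
  }
  all_rows <- do.call(rbind, keep)
  y <- all_rows[, ncol(all_rows)]
  G <- all_rows[, -ncol(all_rows), drop = FALSE]
  ord <- order(-y)                              # cases first, stable
  G <- G[ord, , drop = FALSE]; y <- y[ord]
  G <- apply_missingness(G, spec$missing_rate)
  build_sim_matrix(G, y)
}

#' LD-block specification
#'
#' @param haplotype_freqs named numeric: haplotype allele strings (equal
#'   length, 2-4 sites) to frequencies summing to 1.
#' @param case_shift signed shift added to `shift_haplotype`'s frequency in
#'   the case stratum (other haplotypes renormalized proportionally).
#' @param shift_haplotype the haplotype receiving the shift (default: the
#'   first).
#' @return an `ld_block_spec` list.
#' @export
ld_block_spec <- function(haplotype_freqs, case_shift = 0,
                          shift_haplotype = names(haplotype_freqs)[1L]) {
  stopifnot(!is.null(names(haplotype_freqs)),
            abs(sum(haplotype_freqs) - 1) < 1e-8,
            all(haplotype_freqs >= 0),
            shift_haplotype %in% names(haplotype_freqs))
  k <- unique(nchar(names(haplotype_freqs)))
  if (length(k) != 1L || k < 2L || k > 4L) {
    stop("haplotypes must be equal-length strings over 2-4 sites")
  }
  shifted <- shift_freqs(haplotype_freqs, shift_haplotype, case_shift)
  structure(list(haplotype_freqs = haplotype_freqs, case_shift = case_shift,
                 shift_haplotype = shift_haplotype, case_freqs = shifted,
                 n_snps = k),
            class = "ld_block_spec")
}

shift_freqs <- function(freqs, hap, shift) {
  f <- freqs
  target <- f[[hap]] + shift
  if (target < 0 || target > 1) stop("case_shift produces an invalid frequency")
  others <- setdiff(names(f), hap)
  rest <- sum(f[others])
  if (rest > 0) f[others] <- f[others] * (1 - target) / rest
  f[hap] <- target
  if (any(f < -1e-12)) stop("case_shift produces a negative frequency")
  f / sum(f)
}

#' Simulate genotypes from an LD block
#'
#' Each individual is the unphased sum of two haplotypes drawn independently
#' from the stratum-specific haplotype distribution (the case stratum uses
#' the shifted frequencies).
#'
#' @param spec an [ld_block_spec()].
#' @param n_cases,n_controls stratum sizes.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] over the block's SNPs.
#' @export
simulate_ld_block <- function(spec, n_cases, n_controls, seed = 1L) {
  set.seed(seed)
  haps <- names(spec$haplotype_freqs)
  k <- spec$n_snps
  hmat <- do.call(rbind, strsplit(haps, ""))
  draw <- function(n, freqs) {
    i1 <- sample.int(length(haps), n, replace = TRUE, prob = freqs)
    i2 <- sample.int(length(haps), n, replace = TRUE, prob = freqs)
    list(h1 = hmat[i1, , drop = FALSE], h2 = hmat[i2, , drop = FALSE])
  }
  ca <- draw(n_cases, spec$case_freqs)
  co <- draw(n_controls, spec$haplotype_freqs)
  h1 <- rbind(ca$h1, co$h1); h2 <- rbind(ca$h2, co$h2)
  n <- n_cases + n_controls
  G <- matrix(NA_integer_, n, k)
  a1 <- character(k); a2 <- character(k)
  for (j in seq_len(k)) {
    alle <- sort(unique(c(h1[, j], h2[, j])))
    if (length(alle) == 1L) alle <- c(alle, "?")
    cnt <- sum(h1[, j] == alle[1L]) + sum(h2[, j] == alle[1L])
    minor <- if (cnt > n) 2L else 1L            # n individuals = 2n alleles
    a1[j] <- alle[minor]; a2[j] <- alle[3L - minor]
    G[, j] <- (h1[, j] == a1[j]) + (h2[, j] == a1[j])
  }
  orc <- orient_minor_allele(G, a1, a2)
  variants <- data.frame(
    snp_id = sprintf("blk%02d", seq_len(k)), chrom = "1",
    pos_bp = seq_len(k) * 1000L, allele_a1 = orc$a1, allele_a2 = orc$a2,
    maf = orc$maf, stringsAsFactors = FALSE
  )
  genotype_matrix(orc$genotypes, variants, sprintf("s%04d", seq_len(n)),
                  c(rep(1L, n_cases), rep(0L, n_controls)))
}

#' Pathway-signal specification
#'
#' @param n_genes number of genes tiled on the synthetic chromosome.
#' @param snps_per_gene integer range `c(lo, hi)` of SNPs per gene body.
#' @param enriched_set_id id of the planted gene set.
#' @param enriched_size member count of the planted set (5-200; default 19,
#'   the size regime of a small curated immune pathway).
#' @param effect_logit marginal logit effect applied to member-gene SNPs.
#' @param n_sets total number of gene sets (planted + size-matched random).
#' @return a `pathway_signal_spec` list.
#' @export
pathway_signal_spec <- function(n_genes = 200L, snps_per_gene = c(2L, 4L),
                                enriched_set_id = "planted_set",
                                enriched_size = 19L, effect_logit = 0,
                                n_sets = 20L) {
  stopifnot(enriched_size >= 5L, enriched_size <= 200L,
            enriched_size <= n_genes, n_sets >= 1L,
            snps_per_gene[1L] >= 1L, snps_per_gene[1L] <= snps_per_gene[2L])
  structure(list(n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 enriched_set_id = enriched_set_id,
                 enriched_size = as.integer(enriched_size),
                 effect_logit = effect_logit, n_sets = as.integer(n_sets)),
            class = "pathway_signal_spec")
}

#' Simulate a cohort with a planted pathway signal
#'
#' Genes are tiled with non-overlapping 20 kb bodies spaced 50 kb apart on a
#' synthetic chromosome; each gene receives `snps_per_gene` SNPs inside its
#' body, so at flank 0 every SNP maps to exactly one gene. SNPs of the
#' planted set's member genes enter the phenotype model with marginal logit
#' effect `effect_logit` (dosages centred at their expectation so the case
#' rate stays near the cohort's); case/control quotas are filled by
#' rejection sampling. Gene sets are the planted set plus size-matched
#' random sets.
#'
#' @param spec a [pathway_signal_spec()].
#' @param cohort a [cohort_spec()].
#' @return list with `matrix` (a [genotype_matrix()]), `annotation`
#'   (BED-style data.frame) and `gene_sets` (GMT-style list).
#' @export
simulate_pathway_cohort <- function(spec, cohort) {
  set.seed(cohort$seed)
  body_len <- 20000L; spacing <- 50000L
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  start <- (seq_len(spec$n_genes) - 1L) * spacing + 10001L
  annotation <- data.frame(
    gene_id = gene_ids, chrom = "1", start_bp = start,
    end_bp = start + body_len - 1L, flank_bp = 0L, stringsAsFactors = FALSE
  )
  nsnp <- sample(spec$snps_per_gene[1L]:spec$snps_per_gene[2L],
                 spec$n_genes, replace = TRUE)
  gene_of <- rep(seq_len(spec$n_genes), nsnp)
  m <- length(gene_of)
  pos <- unlist(lapply(seq_len(spec$n_genes), function(i) {
    sort(sample.int(body_len, nsnp[i])) + start[i] - 1L
  }))
  mafs <- stats::runif(m, cohort$maf_range[1L], cohort$maf_range[2L])

  members <- sort(sample(gene_ids, spec$enriched_size))
  eff_snps <- which(gene_ids[gene_of] %in% members)

  need_ca <- cohort$n_cases; need_co <- cohort$n_controls
  got_ca <- 0L; got_co <- 0L; keep <- list(); drawn <- 0L
  batch <- max(1000L, need_ca + need_co)
  while (got_ca < need_ca || got_co < need_co) {
    if (drawn >= 1e7) stop("case/control quotas unattainable within 1e7 draws")
    G <- vapply(mafs, function(p) stats::rbinom(batch, 2L, p), integer(batch))
    drawn <- drawn + batch
    eta <- if (length(eff_snps) && spec$effect_logit != 0) {
      spec$effect_logit *
        drop((G[, eff_snps, drop = FALSE] -
                matrix(2 * mafs[eff_snps], batch, length(eff_snps), byrow = TRUE)) %*%
               rep(1, length(eff_snps)))
    } else rep(0, batch)
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    ca_rows <- which(y == 1L); co_rows <- which(y == 0L)
    ca_rows <- ca_rows[seq_len(min(length(ca_rows), need_ca - got_ca))]
    co_rows <- co_rows[seq_len(min(length(co_rows), need_co - got_co))]
    if (length(ca_rows)) {
      keep[[length(keep) + 1L]] <- cbind(G[ca_rows, , drop = FALSE], 1L)
      got_ca <- got_ca + length(ca_rows)
    }
    if (length(co_rows)) {
      keep[[length(keep) + 1L]] <- cbind(G[co_rows, , drop = FALSE], 0L)
      got_co <- got_co + length(co_rows)
    }
  }
  all_rows <- do.call(rbind, keep)
  y <- all_rows[, ncol(all_rows)]
  G <- all_rows[, -ncol(all_rows), drop = FALSE]
  ord <- order(-y)
  G <- G[ord, , drop = FALSE]; y <- y[ord]
  G <- apply_missingness(G, cohort$missing_rate)

  orc <- orient_minor_allele(G, rep("A", m), rep("B", m))
  variants <- data.frame(
    snp_id = sprintf("ps%05d", seq_len(m)), chrom = "1", pos_bp = pos,
    allele_a1 = orc$a1, allele_a2 = orc$a2, maf = orc$maf,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(orc$genotypes, variants,
                        sprintf("s%04d", seq_along(y)), y)

  sets <- list(list(set_id = spec$enriched_set_id,
                    description = "planted signal set", member_genes = members))
  pool <- setdiff(gene_ids, members)
  for (s in seq_len(spec$n_sets - 1L)) {
    sets[[s + 1L]] <- list(
      set_id = sprintf("random_set_%02d", s),
      description = "size-matched random set",
      member_genes = sort(sample(pool, spec$enriched_size))
    )
  }
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  list(matrix = gm, annotation = annotation, gene_sets = sets)
}
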