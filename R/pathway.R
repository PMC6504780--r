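#' Single-SNP allelic association chi-square
#'
#' 1-df allelic test: the 2x2 table of allele counts (a1 vs a2) by phenotype
#' group, Pearson chi-square, with the continuity correction added to every
#' cell when a cell is zero. The Cochran-Armitage trend test on genotype
#' codes is available as an alternative. Monomorphic SNPs score 0.
#'
#' @param genotypes codes for one SNP.
#' @param phenotype binary vector (1 = case, 0 = control).
#' @param statistic `"allelic"` (default) or `"trend"`.
#' @param cc continuity correction for zero cells of the allelic table.
#' @return nonnegative chi-square statistic.
#' @export
snp_assoc_chi2 <- function(genotypes, phenotype, statistic = c("allelic", "trend"),
                           cc = 0.5) {
  statistic <- match.arg(statistic)
  ok <- !is.na(genotypes) & !is.na(phenotype)
  g <- genotypes[ok]; y <- phenotype[ok]
  if (!any(y == 1L) || !any(y == 0L)) stop("both phenotype groups must be non-empty")
  if (statistic == "trend") return(trend_chi2(g, y))
  a <- sum(g[y == 1L]); b <- 2 * sum(y == 1L) - a
  c_ <- sum(g[y == 0L]); d <- 2 * sum(y == 0L) - c_
  if ((a + c_) == 0 || (b + d) == 0) return(0)   # monomorphic
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + cc; b <- b + cc; c_ <- c_ + cc; d <- d + cc
  }
  pearson_2x2(a, b, c_, d)
}

trend_chi2 <- function(g, y) {
  n <- length(y)
  vg <- stats::var(g) * (n - 1) / n
  if (vg == 0) return(0)
  r <- sum((g - mean(g)) * (y - mean(y))) / n
  vy <- stats::var(y) * (n - 1) / n
  n * r^2 / (vg * vy)
}

#' Gene-level association statistics
#'
#' Maps each SNP to every gene whose flanked interval contains it and scores
#' each gene by the maximum of its SNPs' single-SNP chi-squares. Genes
#' covering no SNP are omitted.
#'
#' @param gm a [genotype_matrix()].
#' @param annotation data.frame from [read_bed_annotation()]; its `flank_bp`
#'   is overridden by `flank`.
#' @param phenotype binary vector; defaults to the matrix phenotype.
#' @param flank flank in bp for SNP-to-gene mapping (default 20000).
#' @param statistic passed to [snp_assoc_chi2()].
#' @return data.frame `gene_id`, `stat`, `n_snps`, ranked descending by
#'   `stat` with ties broken by `gene_id`.
#' @export
gene_level_stats <- function(gm, annotation, phenotype = gm$phenotype,
                             flank = 20000L, statistic = "allelic") {
  idx <- gene_snp_index(gm$variants, annotation, flank)
  chi2 <- snp_chi2_vector(gm$genotypes, phenotype, statistic = statistic)
  gene_stats_from_chi2(idx, chi2)
}

# Named list: for each gene with >= 1 SNP, the integer indices of its SNPs.
gene_snp_index <- function(variants, annotation, flank) {
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    which(variants$chrom == annotation$chrom[i] &
            variants$pos_bp >= annotation$start_bp[i] - flank &
            variants$pos_bp <= annotation$end_bp[i] + flank)
  })
  names(out) <- annotation$gene_id
  out[lengths(out) > 0L]
}

gene_stats_from_chi2 <- function(gene_idx, chi2) {
  stat <- vapply(gene_idx, function(ix) max(chi2[ix]), numeric(1))
  res <- data.frame(gene_id = names(gene_idx), stat = unname(stat),
                    n_snps = unname(lengths(gene_idx)), stringsAsFactors = FALSE)
  res[order(-res$stat, res$gene_id), , drop = FALSE]
}

# Vectorised per-SNP allelic (or trend) chi-square for a phenotype vector.
snp_chi2_vector <- function(G, phenotype, statistic = "allelic", cc = 0.5) {
  ok_ph <- !is.na(phenotype)
  G <- G[ok_ph, , drop = FALSE]
  y <- phenotype[ok_ph]
  M <- !is.na(G)
  Gz <- ifelse(M, G, 0)
  case <- as.numeric(y == 1L)
  ctrl <- 1 - case
  if (statistic == "trend") {
    return(vapply(seq_len(ncol(G)), function(j) {
      snp_assoc_chi2(G[, j], y, statistic = "trend")
    }, numeric(1)))
  }
  a <- drop(crossprod(Gz, case))
  b <- 2 * drop(crossprod(M * 1, case)) - a
  c_ <- drop(crossprod(Gz, ctrl))
  d <- 2 * drop(crossprod(M * 1, ctrl)) - c_
  mono <- (a + c_) == 0 | (b + d) == 0
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a <- a + cc * zero; b <- b + cc * zero; c_ <- c_ + cc * zero; d <- d + cc * zero
  n <- a + b + c_ + d
  chi2 <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  chi2[mono] <- 0
  chi2
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the gene ranking (descending by statistic): member genes ("hits")
#' increment the running sum by `stat^weight_p` normalized by the members'
#' total, non-members decrement it by `1 / (N - N_members)`. The enrichment
#' score is the running sum's signed maximum deviation from zero.
#'
#' @param ranked_stats gene statistics in descending rank order.
#' @param member_flags logical vector, `TRUE` where the ranked gene belongs
#'   to the set.
#' @param weight_p statistic weighting exponent (default 1).
#' @return the enrichment score ES.
#' @export
enrichment_score <- function(ranked_stats, member_flags, weight_p = 1) {
  stopifnot(length(ranked_stats) == length(member_flags))
  nh <- sum(member_flags)
  if (nh == 0L) stop("no member of the set appears in the ranking")
  n <- length(ranked_stats)
  w <- abs(ranked_stats)^weight_p
  nr <- sum(w[member_flags])
  inc <- numeric(n)
  inc[member_flags] <- if (nr > 0) w[member_flags] / nr else 1 / nh
  if (n > nh) inc[!member_flags] <- -1 / (n - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Filter gene sets by post-intersection size
#'
#' Memberships are intersected with the covered-gene universe (genes with at
#' least one QC-passing SNP in their flanked window); sets whose intersected
#' size falls outside `[min_size, max_size]` are dropped.
#'
#' @param gene_sets list of gene sets from [read_gmt()].
#' @param covered_genes character vector of scoreable gene ids.
#' @param min_size,max_size inclusive size bounds (defaults 5 and 200).
#' @return filtered list of gene sets with intersected memberships.
#' @export
filter_gene_sets <- function(gene_sets, covered_genes, min_size = 5L,
                             max_size = 200L) {
  out <- lapply(gene_sets, function(gs) {
    gs$member_genes <- intersect(gs$member_genes, covered_genes)
    gs
  })
  out[vapply(out, function(gs) {
    length(gs$member_genes) >= min_size && length(gs$member_genes) <= max_size
  }, logical(1))]
}

#' Permutation-based GSEA pathway association
#'
#' GenGen-style genotype GSEA: gene statistics (max single-SNP chi-square in
#' the flanked gene window) are ranked and each set's enrichment score
#' computed; `n_perm` phenotype-label permutations (genotypes untouched, so
#' LD is preserved) regenerate the whole ranking each round. Per set,
#' `NES = ES / mean(positive permuted ES)`; `empirical_p =
#' (1 + #\{perm ES >= observed ES\}) / (n_perm + 1)`; FDR compares the
#' fraction of all permuted NES at or above a set's NES with the fraction of
#' observed NES at or above it (capped at 1); FWER is the fraction of
#' permutation rounds whose maximum NES reaches the set's NES.
#'
#' @param gm a [genotype_matrix()].
#' @param annotation data.frame from [read_bed_annotation()].
#' @param gene_sets list of gene sets, already size-filtered
#'   ([filter_gene_sets()]).
#' @param n_perm number of phenotype permutations (>= 100; default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param flank SNP-to-gene flank in bp (default 20000).
#' @param weight_p ES weighting exponent (default 1).
#' @param statistic per-SNP statistic, `"allelic"` or `"trend"`.
#' @return data.frame of class `pathway_result`: `set_id`, `es`, `nes`,
#'   `empirical_p`, `fdr`, `fwer`, sorted by `empirical_p` then `-nes`.
#' @export
gsea_permutation_test <- function(gm, annotation, gene_sets, n_perm = 1000L,
                                  seed, flank = 20000L, weight_p = 1,
                                  statistic = "allelic") {
  if (missing(seed)) stop("a seed is required for the permutation test")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!length(gene_sets)) stop("no gene sets to test")
  gene_idx <- gene_snp_index(gm$variants, annotation, flank)
  genes <- sort(names(gene_idx))
  gene_idx <- gene_idx[genes]
  sets_members <- lapply(gene_sets, function(gs) intersect(gs$member_genes, genes))
  bad <- !vapply(sets_members, length, integer(1))
  if (any(bad)) stop("gene set(s) with no covered gene: ",
                     paste(vapply(gene_sets[bad], `[[`, "", "set_id"), collapse = ", "))
  set_ids <- vapply(gene_sets, `[[`, "", "set_id")

  es_for <- function(phenotype) {
    chi2 <- snp_chi2_vector(gm$genotypes, phenotype, statistic = statistic)
    gs <- gene_stats_from_chi2(gene_idx, chi2)
    vapply(sets_members, function(mem) {
      enrichment_score(gs$stat, gs$gene_id %in% mem, weight_p = weight_p)
    }, numeric(1))
  }

  obs_es <- es_for(gm$phenotype)

  ph <- gm$phenotype
  ok <- which(!is.na(ph))
  set.seed(seed)
  perm_es <- matrix(NA_real_, n_perm, length(gene_sets))
  for (r in seq_len(n_perm)) {
    pph <- ph
    pph[ok] <- ph[sample(ok)]
    perm_es[r, ] <- es_for(pph)
  }

  denom <- vapply(seq_along(gene_sets), function(s) {
    pos <- perm_es[, s][perm_es[, s] > 0]
    if (length(pos)) mean(pos) else NA_real_
  }, numeric(1))
  nes <- obs_es / denom
  perm_nes <- sweep(perm_es, 2L, denom, "/")

  empirical_p <- vapply(seq_along(gene_sets), function(s) {
    (1 + sum(perm_es[, s] >= obs_es[s])) / (n_perm + 1)
  }, numeric(1))

  all_perm_nes <- perm_nes[!is.na(perm_nes)]
  fdr <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    num <- mean(all_perm_nes >= x)
    den <- mean(nes >= x, na.rm = TRUE)
    if (den == 0) return(1)
    min(num / den, 1)
  }, numeric(1))
  perm_max <- apply(perm_nes, 1L, max, na.rm = TRUE)
  fwer <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    mean(perm_max >= x)
  }, numeric(1))

  res <- data.frame(set_id = set_ids, es = obs_es, nes = nes,
                    empirical_p = empirical_p, fdr = fdr, fwer = fwer,
                    stringsAsFactors = FALSE)
  res <- res[order(res$empirical_p, -res$nes, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pathway_result", "data.frame")
  res
}

#' Pathway association from precomputed gene P-values
#'
#' GSA-SNP-style replication method: each gene carries one P-value; gene
#' scores are `-log10(P)`; per set,
#' `z = (mean member score - mean all scores) / (sd all scores / sqrt(set size))`
#' with a two-sided normal P; Benjamini-Hochberg FDR across sets.
#'
#' @param gene_pvalues named numeric vector of per-gene P-values in (0, 1].
#' @param gene_sets list of gene sets.
#' @return data.frame: `set_id`, `n_genes`, `z`, `p`, `bh_fdr`, sorted by `p`.
#'   Sets with no scored gene are omitted with a warning.
#' @export
gsa_snp_pathway <- function(gene_pvalues, gene_sets) {
  stopifnot(!is.null(names(gene_pvalues)),
            all(gene_pvalues > 0), all(gene_pvalues <= 1))
  score <- -log10(gene_pvalues)
  mu <- mean(score); sdv <- stats::sd(score)
  rows <- lapply(gene_sets, function(gs) {
    mem <- intersect(gs$member_genes, names(score))
    if (!length(mem)) {
      warning("gene set with no scored gene omitted: ", gs$set_id)
      return(NULL)
    }
    z <- if (sdv == 0) 0 else (mean(score[mem]) - mu) / (sdv / sqrt(length(mem)))
    data.frame(set_id = gs$set_id, n_genes = length(mem), z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable gene set")
  res <- do.call(rbind, rows)
  res$bh_fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read gene sets from a GMT file
#'
#' @param path tab-separated GMT file: set id, description, member genes.
#' @return list of gene sets, each a list with `set_id`, `description`,
#'   `member_genes` (deduplicated).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d: need set id, description and >= 1 gene", i))
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d has an empty gene list", i))
    list(set_id = f[1L], description = f[2L], member_genes = genes)
  })
  names(out) <- vapply(out, `[[`, "", "set_id")
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(gene_sets, path) {
  writeLines(vapply(gene_sets, function(gs) {
    paste(c(gs$set_id, gs$description, gs$member_genes), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
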