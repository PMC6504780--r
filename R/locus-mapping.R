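#' Map one SNP position to annotated loci
#'
#' A SNP maps to every locus whose interval, widened by its flank, contains
#' the position: `pos_bp` in `[start_bp - flank_bp, end_bp + flank_bp]`.
#' Loci may be genes or cytoband-style regions; overlaps are allowed, so a
#' SNP can map to several loci.
#'
#' @param chrom,pos_bp SNP coordinates (1-based).
#' @param annotation data.frame from [read_bed_annotation()].
#' @return character vector of locus ids (possibly empty).
#' @export
map_snp_to_loci <- function(chrom, pos_bp, annotation) {
  hit <- annotation$chrom == chrom &
    pos_bp >= annotation$start_bp - annotation$flank_bp &
    pos_bp <= annotation$end_bp + annotation$flank_bp
  annotation$gene_id[hit]
}

#' Map many SNPs to loci
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp`.
#' @param annotation data.frame from [read_bed_annotation()].
#' @return named list: for each snp id, the character vector of locus ids.
#' @export
map_snps_to_loci <- function(snps, annotation) {
  out <- lapply(seq_len(nrow(snps)), function(i) {
    map_snp_to_loci(snps$chrom[i], snps$pos_bp[i], annotation)
  })
  names(out) <- snps$snp_id
  out
}

#' Collapse screened interactions into supported locus pairs
#'
#' Implements the interaction-cluster exclusion criteria: an interaction is
#' dropped when either SNP maps to no annotated locus; survivors are grouped
#' by unordered locus pair; a pair is kept only when it is supported by at
#' least `min_support` interactions AND each side is represented by at least
#' two distinct SNPs (a locus touched "independently" by a single SNP is not
#' treated as supported).
#'
#' @param interactions data.frame with columns `snp1`, `snp2`, `p_z` (and
#'   optionally further statistic columns, carried along).
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp` covering
#'   every SNP named in `interactions`.
#' @param annotation data.frame from [read_bed_annotation()].
#' @param min_support minimum number of supporting interactions (default 2).
#' @return data.frame with one row per retained locus pair: `locus1`,
#'   `locus2` (lexicographically ordered), `n_interactions`,
#'   `distinct_snps1`, `distinct_snps2`, `best_p`, sorted by `best_p`
#'   ascending; the supporting interaction rows are in the list-column
#'   `support`.
#' @export
apply_exclusion_criteria <- function(interactions, snps, annotation,
                                     min_support = 2L) {
  need <- unique(c(interactions$snp1, interactions$snp2))
  missing_pos <- setdiff(need, snps$snp_id)
  if (length(missing_pos)) {
    stop("no position for SNP(s): ", paste(missing_pos, collapse = ", "))
  }
  loci <- map_snps_to_loci(snps[snps$snp_id %in% need, , drop = FALSE], annotation)

  rows <- list()
  for (i in seq_len(nrow(interactions))) {
    l1 <- loci[[interactions$snp1[i]]]
    l2 <- loci[[interactions$snp2[i]]]
    if (!length(l1) || !length(l2)) next        # criterion 1: intergenic side
    for (a in l1) for (b in l2) {
      swap <- a > b
      key <- if (swap) paste(b, a, sep = "\r") else paste(a, b, sep = "\r")
      rows[[length(rows) + 1L]] <- data.frame(
        key = key,
        locus1 = if (swap) b else a, locus2 = if (swap) a else b,
        snp_l1 = if (swap) interactions$snp2[i] else interactions$snp1[i],
        snp_l2 = if (swap) interactions$snp1[i] else interactions$snp2[i],
        row = i, p_z = interactions$p_z[i], stringsAsFactors = FALSE
      )
    }
  }
  empty <- data.frame(
    locus1 = character(), locus2 = character(), n_interactions = integer(),
    distinct_snps1 = integer(), distinct_snps2 = integer(), best_p = numeric(),
    stringsAsFactors = FALSE
  )
  if (!length(rows)) return(empty)
  long <- do.call(rbind, rows)

  out <- lapply(split(long, long$key), function(g) {
    d1 <- length(unique(g$snp_l1)); d2 <- length(unique(g$snp_l2))
    if (nrow(g) < min_support || d1 < 2L || d2 < 2L) return(NULL)  # criterion 2
    df <- data.frame(
      locus1 = g$locus1[1L], locus2 = g$locus2[1L], n_interactions = nrow(g),
      distinct_snps1 = d1, distinct_snps2 = d2, best_p = min(g$p_z),
      stringsAsFactors = FALSE
    )
    df$support <- list(interactions[g$row, , drop = FALSE])
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$best_p, res$locus1, res$locus2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
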