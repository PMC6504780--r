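#' Read PLINK text genotypes (ped/map)
#'
#' Alleles are recoded to minor-allele dosages at read time: for each SNP the
#' minor allele is determined empirically (ties keep the first allele
#' encountered in sample order) and the genotype code counts copies of it.
#' "0" alleles denote missing; a pair containing one is coded `NA`. The
#' phenotype is taken from ped column 6 (2 = case, 1 = control, anything else
#' missing).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cM", "pos_bp"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (!n) stop("empty ped file: ", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1L]
    stop(sprintf("ped line %d has %d fields, expected %d (map lists %d SNPs)",
                 bad, lens[bad], want, m))
  }
  ped <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- ped[, 2L]
  ph_raw <- ped[, 6L]
  phenotype <- ifelse(ph_raw == "2", 1L, ifelse(ph_raw == "1", 0L, NA_integer_))

  genotypes <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    al1 <- ped[, 5L + 2L * j]
    al2 <- ped[, 6L + 2L * j]
    ok <- al1 != "0" & al2 != "0"
    obs <- c(rbind(al1[ok], al2[ok]))          # sample order, both chromosomes
    alleles <- unique(obs)
    if (length(alleles) > 2L) {
      stop(sprintf("SNP %s has %d alleles; only biallelic sites are supported",
                   map$snp_id[j], length(alleles)))
    }
    if (length(alleles) == 0L) alleles <- c("?", "?")
    if (length(alleles) == 1L) alleles <- c(alleles, "?")
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    minor <- if (cnt[2L] < cnt[1L]) 2L else 1L  # tie -> first encountered
    a1[j] <- alleles[minor]; a2[j] <- alleles[3L - minor]
    genotypes[ok, j] <- (al1[ok] == a1[j]) + (al2[ok] == a1[j])
  }
  orc <- orient_minor_allele(genotypes, a1, a2)
  variants <- data.frame(
    snp_id = map$snp_id, chrom = as.character(map$chrom), pos_bp = map$pos_bp,
    allele_a1 = orc$a1, allele_a2 = orc$a2, maf = orc$maf,
    stringsAsFactors = FALSE
  )
  genotype_matrix(orc$genotypes, variants, samples, phenotype)
}

#' Write PLINK text genotypes (ped/map)
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the ped path.
#' @export
write_plink_text <- function(gm, ped_path, map_path) {
  v <- gm$variants
  utils::write.table(
    data.frame(v$chrom, v$snp_id, 0, v$pos_bp),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  n <- length(gm$samples)
  ph <- ifelse(is.na(gm$phenotype), "0", ifelse(gm$phenotype == 1L, "2", "1"))
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- gm$genotypes[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$allele_a1, v$allele_a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$allele_a1, v$allele_a2))
    writeLines(paste(c(gm$samples[i], gm$samples[i], "0", "0", "2", ph[i],
                       c(rbind(al1, al2))), collapse = " "), con)
  }
  invisible(ped_path)
}

# 256 x 4 lookup: byte -> 4 genotype codes on the a1-count scale,
# samples packed LSB-first (00 = hom a1 -> 2, 01 = missing, 10 = het,
# 11 = hom a2 -> 0).
.bed_lookup <- local({
  code <- c(2L, NA_integer_, 1L, 0L)
  tab <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    tab[b + 1L, ] <- code[1L + c(
      bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)
    )]
  }
  tab
})

#' Read PLINK binary genotypes (bed/bim/fam)
#'
#' Decodes the 2-bit SNP-major PLINK 1.x .bed encoding (magic bytes 0x6C 0x1B,
#' mode 0x01). As with [read_plink_text()], codes are oriented so that
#' `allele_a1` is the empirical minor allele (ties keep the bim A1).
#'
#' @param bed_path,bim_path,fam_path paths to the three PLINK binary files.
#' @return a [genotype_matrix()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cM", "pos_bp", "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed_path)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("unsupported bed mode byte (only SNP-major 0x01 is supported): ", bed_path)
  }
  bps <- ceiling(n / 4)                       # bytes per SNP
  if (length(raw) - 3L != bps * m) {
    stop(sprintf("bed payload is %d bytes, expected %d for %d samples x %d SNPs",
                 length(raw) - 3L, bps * m, n, m))
  }
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
  genotypes <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    codes <- as.vector(t(.bed_lookup[body[, j] + 1L, , drop = FALSE]))
    genotypes[, j] <- codes[seq_len(n)]
  }
  orc <- orient_minor_allele(genotypes, bim$a1, bim$a2)
  variants <- data.frame(
    snp_id = bim$snp_id, chrom = as.character(bim$chrom), pos_bp = bim$pos_bp,
    allele_a1 = orc$a1, allele_a2 = orc$a2, maf = orc$maf,
    stringsAsFactors = FALSE
  )
  ph_raw <- as.character(fam[[6L]])
  phenotype <- ifelse(ph_raw == "2", 1L, ifelse(ph_raw == "1", 0L, NA_integer_))
  genotype_matrix(orc$genotypes, variants, fam[[2L]], phenotype)
}

#' Write PLINK binary genotypes (bed/bim/fam)
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return invisibly, the prefix.
#' @export
write_plink_binary <- function(gm, prefix) {
  v <- gm$variants
  utils::write.table(
    data.frame(v$chrom, v$snp_id, 0, v$pos_bp, v$allele_a1, v$allele_a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  ph <- ifelse(is.na(gm$phenotype), "0", ifelse(gm$phenotype == 1L, "2", "1"))
  utils::write.table(
    data.frame(gm$samples, gm$samples, 0, 0, 2, ph),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  n <- length(gm$samples); m <- ncol(gm$genotypes)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * ceiling(n / 4) - n
  for (j in seq_len(m)) {
    g <- gm$genotypes[, j]
    # code 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
    two <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
    two <- c(two, rep(0L, pad))
    q <- matrix(two, nrow = 4L)
    bytes <- q[1L, ] + q[2L, ] * 4L + q[3L, ] * 16L + q[4L, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read BED4 gene/region annotation
#'
#' BED intervals are 0-based half-open on disk and converted to 1-based
#' inclusive coordinates on read.
#'
#' @param path BED file with columns chrom, start, end, gene_id.
#' @param flank_bp flank added on both sides when mapping SNPs (0 for strict
#'   containment, 20000 for pathway-style mapping).
#' @return data.frame with columns `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `flank_bp`, sorted by (chrom, start_bp).
#' @export
read_bed_annotation <- function(path, flank_bp = 0) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED4 annotation needs 4 columns: ", path)
  ann <- data.frame(
    gene_id = as.character(bed[[4L]]), chrom = as.character(bed[[1L]]),
    start_bp = as.integer(bed[[2L]]) + 1L, end_bp = as.integer(bed[[3L]]),
    flank_bp = as.integer(flank_bp), stringsAsFactors = FALSE
  )
  if (any(ann$start_bp > ann$end_bp)) stop("annotation has start > end: ", path)
  ann <- ann[order(ann$chrom, ann$start_bp), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write BED4 annotation
#'
#' @param ann annotation data.frame as returned by [read_bed_annotation()].
#' @param path output path (written 0-based half-open).
#' @return invisibly, the path.
#' @export
write_bed_annotation <- function(ann, path) {
  utils::write.table(
    data.frame(ann$chrom, ann$start_bp - 1L, ann$end_bp, ann$gene_id),
    path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a variant report TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_variant_report <- function(gm, path) {
  v <- gm$variants
  v$missing_frac <- colMeans(is.na(gm$genotypes))
  utils::write.table(format_tsv_numbers(v), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
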