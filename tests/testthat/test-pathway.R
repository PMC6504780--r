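test_that("single-SNP allelic chi-square matches the textbook 2x2 value", {
  # equal allele frequencies in both groups -> 0
  g <- c(rep(2L, 10), rep(0L, 10), rep(2L, 10), rep(0L, 10))
  y <- rep(c(1L, 0L), each = 20)
  expect_equal(snp_assoc_chi2(g, y), 0, tolerance = 1e-12)
  expect_equal(snp_assoc_chi2(rep(0L, 40), y), 0)       # monomorphic

  # allele counts cases (60, 40), controls (40, 60): hand Pearson value
  g <- c(rep(2L, 30), rep(0L, 20), rep(2L, 20), rep(0L, 30))
  y <- rep(c(1L, 0L), each = 50)
  a <- 60; b <- 40; cc <- 40; d <- 60; n <- 200
  oracle <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(snp_assoc_chi2(g, y), oracle, tolerance = 1e-12)

  # null calibration: the statistic follows chi-square(1) closely
  set.seed(111)
  stats <- replicate(500, snp_assoc_chi2(rbinom(400, 2, 0.3), rbinom(400, 1, 0.5)))
  expect_lt(abs(mean(stats > qchisq(0.95, 1)) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  expect_lt(abs(median(stats) - qchisq(0.5, 1)), 0.15)
})

test_that("gene-level stats take the max chi-square over mapped SNPs", {
  set.seed(112)
  spec <- cohort_spec(n_cases = 80, n_controls = 80, m_snps = 30, seed = 113)
  gm <- simulate_null_cohort(spec)
  # genes of 3 SNPs each, positions snp j at j*5000; overlapping pair at end
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:10), chrom = "1",
    start_bp = (0:9) * 15000L + 1L, end_bp = (1:10) * 15000L,
    flank_bp = 0L, stringsAsFactors = FALSE
  )
  gs <- gene_level_stats(gm, ann, flank = 0)
  chi2 <- vapply(seq_len(30), function(j)
    snp_assoc_chi2(gm$genotypes[, j], gm$phenotype), numeric(1))
  for (i in seq_len(nrow(gs))) {
    snps <- which(gm$variants$pos_bp >= ann$start_bp[match(gs$gene_id[i], ann$gene_id)] &
                    gm$variants$pos_bp <= ann$end_bp[match(gs$gene_id[i], ann$gene_id)])
    expect_equal(gs$stat[i], max(chi2[snps]), tolerance = 1e-12)
    expect_equal(gs$n_snps[i], length(snps))
  }
  expect_false(is.unsorted(-gs$stat))
  # a SNP in two overlapping windows contributes to both genes
  ann2 <- ann[1:2, ]; ann2$start_bp <- c(1L, 1L); ann2$end_bp <- c(15000L, 15000L)
  gs2 <- gene_level_stats(gm, ann2, flank = 0)
  expect_equal(gs2$stat[gs2$gene_id == "g01"], gs2$stat[gs2$gene_id == "g02"])
})

test_that("enrichment score equals the brute-force running-sum walk", {
  walk_es <- function(stat, member, p = 1) {
    n <- length(stat); nh <- sum(member)
    nr <- sum(abs(stat[member])^p)
    run <- 0; best <- 0
    for (i in seq_len(n)) {
      run <- run + if (member[i]) abs(stat[i])^p / nr else -1 / (n - nh)
      if (abs(run) > abs(best)) best <- run
    }
    best
  }
  set.seed(121)
  for (rep in 1:100) {
    stat <- sort(rchisq(50, 1), decreasing = TRUE)
    member <- seq_len(50) %in% sample.int(50, 8)
    expect_equal(enrichment_score(stat, member), walk_es(stat, member),
                 tolerance = 1e-12)
  }
  # members at the exact top: ES is the sum of their normalized increments
  stat <- sort(rchisq(30, 1), decreasing = TRUE)
  member <- c(rep(TRUE, 5), rep(FALSE, 25))
  expect_equal(enrichment_score(stat, member), 1, tolerance = 1e-12)
  # degenerate all-member set: the walk climbs to exactly 1
  expect_equal(enrichment_score(stat, rep(TRUE, 30)), 1, tolerance = 1e-12)
  expect_error(enrichment_score(stat, rep(FALSE, 30)), "no member")
})

test_that("gene-set size filter applies after intersecting with coverage", {
  mk <- function(id, k) list(set_id = id, description = "",
                             member_genes = sprintf("%s_g%03d", id, seq_len(k)))
  sets <- list(mk("tiny", 4), mk("ok", 10), mk("big", 201))
  universe <- unlist(lapply(sets, `[[`, "member_genes"))
  kept <- filter_gene_sets(sets, universe)
  expect_equal(vapply(kept, `[[`, "", "set_id"), "ok")
  # intersection can push a set below the floor
  kept2 <- filter_gene_sets(sets, sets[[2]]$member_genes[1:4])
  expect_length(kept2, 0)
  # or bring an oversized one inside the bounds
  kept3 <- filter_gene_sets(sets[3], sets[[3]]$member_genes[1:150])
  expect_equal(length(kept3[[1]]$member_genes), 150)
})

test_that("GMT round trip, deduplication and malformed-line errors", {
  td <- withr::local_tempdir()
  writeLines(c("setA\tdesc A\tTOB1\tTOB2\tTOB1",
               "setB\tdesc B\tIL2"), file.path(td, "s.gmt"))
  sets <- read_gmt(file.path(td, "s.gmt"))
  expect_equal(sets$setA$member_genes, c("TOB1", "TOB2"))  # dedup
  expect_equal(sets$setB$member_genes, "IL2")
  write_gmt(sets, file.path(td, "rt.gmt"))
  expect_identical(read_gmt(file.path(td, "rt.gmt")), sets)
  writeLines("broken\tonly-description", file.path(td, "bad.gmt"))
  expect_error(read_gmt(file.path(td, "bad.gmt")), "line 1")
})

test_that("permutation GSEA: determinism, P floor, null behaviour", {
  spec <- pathway_signal_spec(n_genes = 60, snps_per_gene = c(1, 2),
                              enriched_size = 8, effect_logit = 0, n_sets = 10)
  sim <- simulate_pathway_cohort(spec, cohort_spec(n_cases = 80, n_controls = 80,
                                                   seed = 131))
  res1 <- gsea_permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                                n_perm = 100, seed = 7, flank = 0)
  res2 <- gsea_permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                                n_perm = 100, seed = 7, flank = 0)
  expect_identical(res1, res2)                       # bit-reproducible
  expect_true(all(res1$empirical_p >= 1 / 101))      # pseudo-count floor
  expect_true(all(res1$fdr >= 0 & res1$fdr <= 1))
  expect_true(all(res1$fwer >= 0 & res1$fwer <= 1))
  # global null: no set should be extreme, and P-values spread out
  expect_gt(mean(res1$empirical_p), 0.25)
  expect_lte(mean(res1$empirical_p < 0.05), 0.2)
})

test_that("permutation GSEA ranks a planted set first", {
  spec <- pathway_signal_spec(n_genes = 60, snps_per_gene = c(1, 2),
                              enriched_size = 8, effect_logit = 0.6, n_sets = 10)
  sim <- simulate_pathway_cohort(spec, cohort_spec(n_cases = 150, n_controls = 150,
                                                   seed = 141))
  res <- gsea_permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                               n_perm = 200, seed = 9, flank = 0)
  expect_equal(res$set_id[1], "planted_set")
  expect_equal(which.max(res$nes), 1L)
  expect_lt(res$empirical_p[1], 0.05)
})

test_that("precomputed-P pathway method: z construction and BH correction", {
  genes <- sprintf("g%03d", 1:100)
  pv <- setNames(rep(0.5, 100), genes)
  sets <- list(list(set_id = "s1", description = "", member_genes = genes[1:10]),
               list(set_id = "s2", description = "", member_genes = genes[11:30]))
  res <- gsa_snp_pathway(pv, sets)
  expect_equal(res$z, c(0, 0))                       # equal scores
  expect_equal(res$p, c(1, 1))

  set.seed(151)
  pv <- setNames(runif(100, 0.001, 1), genes)
  top <- names(sort(pv))[1:10]
  sets <- list(
    list(set_id = "top", description = "", member_genes = top),
    list(set_id = "rand1", description = "", member_genes = sample(genes, 10)),
    list(set_id = "rand2", description = "", member_genes = sample(genes, 10)),
    list(set_id = "none", description = "", member_genes = c("absent1", "absent2"))
  )
  expect_warning(res <- gsa_snp_pathway(pv, sets), "no scored gene")
  expect_equal(res$set_id[which.max(res$z)], "top")
  expect_false("none" %in% res$set_id)
  # z matches the direct construction for the top set
  score <- -log10(pv)
  z_oracle <- (mean(score[top]) - mean(score)) / (sd(score) / sqrt(10))
  expect_equal(res$z[res$set_id == "top"], z_oracle, tolerance = 1e-12)

  # BH-FDR equals the hand computation on a fixed p-vector
  ph <- c(0.01, 0.02, 0.04, 0.8)
  sets4 <- lapply(1:4, function(i) list(set_id = paste0("b", i), description = "",
                                        member_genes = genes[i]))
  res4 <- gsa_snp_pathway(pv, sets4)
  bh <- res4$bh_fdr[order(res4$p)]
  expect_equal(bh, rev(cummin(rev(sort(res4$p) * 4 / 1:4))), tolerance = 1e-12)
  expect_true(all(res4$bh_fdr >= res4$p - 1e-12))
})
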