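test_that("EM equals exact counting when phase is unambiguous", {
  # no sample heterozygous at more than one window SNP
  G <- rbind(c(2L, 0L), c(1L, 0L), c(2L, 1L), c(0L, 0L), c(2L, 2L), c(0L, 1L))
  gm <- toy_gm(G, rep(c(1L, 0L), 3))
  em <- em_haplotype_frequencies(gm, gm$variants$snp_id[1:2])
  # direct phased counts over 12 chromosomes: haplotypes are readable off
  # each genotype because at most one site is heterozygous
  counts <- c(0, 0, 0, 0)  # order: a2a2, a1(snp1)a2, a2a1(snp2), a1a1
  for (i in seq_len(nrow(G))) {
    g <- G[i, ]
    het <- which(g == 1L)
    h_base <- as.integer(g >= 1L); h_other <- as.integer(g == 2L)
    if (length(het)) h_base[het] <- 1L
    if (length(het)) h_other[het] <- 0L
    for (h in list(h_base, h_other)) {
      counts[1 + h[1] + 2 * h[2]] <- counts[1 + h[1] + 2 * h[2]] + 1
    }
  }
  expect_equal(unname(em$freq), counts / 12, tolerance = 1e-9)
  expect_equal(sum(em$freq), 1, tolerance = 1e-8)
})

test_that("EM in complete LD keeps only the two observed haplotypes", {
  set.seed(81)
  g <- rbinom(40, 2, 0.4)
  gm <- toy_gm(cbind(g, g), rep(c(1L, 0L), 20))
  em <- em_haplotype_frequencies(gm, gm$variants$snp_id)
  expect_equal(sum(em$freq > 1e-9), 2)
  expect_true(all(diff(em$loglik_trace) >= -1e-9))  # monotone EM
})

test_that("EM log-likelihood matches the simplex grid-search oracle on a 3-SNP toy", {
  G <- rbind(
    matrix(rep(c(1L, 1L, 0L), 6), ncol = 3, byrow = TRUE),
    matrix(rep(c(2L, 1L, 0L), 2), ncol = 3, byrow = TRUE),
    matrix(rep(c(1L, 2L, 0L), 2), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 0L, 0L), 3), ncol = 3, byrow = TRUE),
    matrix(rep(c(2L, 2L, 0L), 2), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 0L, 1L), 3), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 0L, 2L), 2), ncol = 3, byrow = TRUE)
  )
  gm <- toy_gm(G, rep(c(1L, 0L), 10))
  em <- em_haplotype_frequencies(gm, gm$variants$snp_id)

  # support haplotypes as (site1, site2, site3) a1-indicator triples
  haps <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))
  # compatible (h1, h2) index pairs per sample genotype
  pair_list <- lapply(seq_len(nrow(G)), function(i) {
    prs <- NULL
    for (h1 in seq_len(nrow(haps))) for (h2 in h1:nrow(haps)) {
      if (all(haps[h1, ] + haps[h2, ] == G[i, ])) prs <- rbind(prs, c(h1, h2))
    }
    prs
  })
  loglik_of <- function(f) {
    sum(vapply(pair_list, function(prs) {
      log(sum(f[prs[, 1]] * f[prs[, 2]] * ifelse(prs[, 1] == prs[, 2], 1, 2)))
    }, numeric(1)))
  }
  # exhaustive grid over the 4-simplex (step 0.02), then a local polish of
  # the best grid point with a generic optimizer on the softmax scale
  step <- 0.02
  grid <- as.matrix(expand.grid(a = seq(0, 1, step), b = seq(0, 1, step),
                                c = seq(0, 1, step), d = seq(0, 1, step)))
  grid <- grid[rowSums(grid) <= 1 + 1e-9, , drop = FALSE]
  grid <- cbind(grid, pmax(0, 1 - rowSums(grid)))
  best <- -Inf; best_f <- NULL
  for (r in seq_len(nrow(grid))) {
    ll <- loglik_of(grid[r, ])
    if (is.finite(ll) && ll > best) { best <- ll; best_f <- grid[r, ] }
  }
  expect_gte(em$loglik, best - 1e-8)   # EM beats every raw grid point
  soft <- function(theta) { e <- exp(c(theta, 0)); e / sum(e) }
  polish <- optim(log(pmax(best_f[-5], 1e-6) / max(best_f[5], 1e-6)),
                  function(th) -loglik_of(soft(th)),
                  method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(em$loglik, -polish$value, tolerance = 1e-4)
})

test_that("D-prime: complete LD, independence, and parameter recovery", {
  set.seed(91)
  g <- rbinom(200, 2, 0.3)
  gm <- toy_gm(cbind(g, g), rep(c(1L, 0L), 100))
  expect_equal(dprime(gm, "rsT001", "rsT002"), 1, tolerance = 1e-6)

  # independent SNPs at n = 5000
  gi <- toy_gm(cbind(rbinom(5000, 2, 0.3), rbinom(5000, 2, 0.4)),
               rep(c(1L, 0L), 2500))
  expect_lt(dprime(gi, "rsT001", "rsT002"), 0.1)

  # haplotypes with known D: pA=0.3, pB=0.4, D=0.1 -> D' = 0.1/0.18
  spec <- ld_block_spec(c(AC = 0.22, AT = 0.08, GC = 0.18, GT = 0.52))
  bm <- simulate_ld_block(spec, 1000, 1000, seed = 92)
  expect_equal(dprime(bm, "blk01", "blk02"), 0.1 / 0.18, tolerance = 0.05)
  # symmetry in the two SNPs
  expect_equal(dprime(bm, "blk01", "blk02"), dprime(bm, "blk02", "blk01"),
               tolerance = 1e-9)

  mono <- toy_gm(cbind(rep(0L, 10), rbinom(10, 2, 0.5)), rep(c(1L, 0L), 5))
  expect_error(dprime(mono, "rsT001", "rsT002"), "monomorphic")
})

test_that("per-haplotype chi-square follows the textbook 2x2 construction", {
  win <- c("w1", "w2")
  mk <- function(freqs) {
    structure(list(window_snps = win, haplotypes = names(freqs), freq = freqs),
              class = "haplotype_table")
  }
  fa <- c(AC = 0.036, AG = 0.964)
  fu <- c(AC = 0.015, AG = 0.985)
  res <- haplotype_case_control_test(mk(fa), mk(fu), 493, 537)
  # independent textbook Pearson computation on expected chromosome counts
  a <- 2 * 493 * 0.036; b <- 2 * 493 * 0.964
  cc <- 2 * 537 * 0.015; d <- 2 * 537 * 0.985
  n <- a + b + cc + d
  oracle <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(res$chi2[res$haplotype == "AC"], oracle, tolerance = 1e-12)
  expect_equal(res$p[res$haplotype == "AC"], chisq_p(oracle, 1), tolerance = 1e-12)

  # equal frequencies -> chi2 = 0, P = 1
  same <- haplotype_case_control_test(mk(fa), mk(fa), 493, 537)
  expect_equal(same$chi2, c(0, 0), tolerance = 1e-12)
  expect_equal(same$p, c(1, 1))

  # doubling both sample sizes doubles chi2 at fixed frequencies
  dbl <- haplotype_case_control_test(mk(fa), mk(fu), 986, 1074)
  expect_equal(dbl$chi2, 2 * res$chi2, tolerance = 1e-9)

  # rare haplotypes are skipped
  fa2 <- c(AC = 0.005, AG = 0.995); fu2 <- c(AC = 0.004, AG = 0.996)
  rare <- haplotype_case_control_test(mk(fa2), mk(fu2), 493, 537)
  expect_false("AC" %in% rare$haplotype)
})

test_that("chisq_p has the df=1 closed form and sane limits", {
  expect_equal(chisq_p(0, 1), 1)
  expect_equal(chisq_p(0, 5), 1)
  x <- c(0.3, 1, 3.84, 6.146, 10)
  expect_equal(chisq_p(x, 1), pchisq(x, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(chisq_p(x, 1), 2 * pnorm(-sqrt(x)), tolerance = 1e-15)
  expect_equal(chisq_p(6.146, 3), pchisq(6.146, 3, lower.tail = FALSE))
})

test_that("sliding windows enumerate every contiguous window", {
  ids <- sprintf("s%d", 1:5)
  expect_length(sliding_windows(ids, 2), 4)
  w <- sliding_windows(ids, c(2, 3, 4))
  expect_length(w, 9)
  brute <- list()
  for (s in 2:4) for (i in 1:(5 - s + 1)) {
    brute[[length(brute) + 1]] <- ids[i:(i + s - 1)]
  }
  expect_identical(w, brute)
  expect_error(sliding_windows(ids[1], 2), "at least 2")
})

test_that("a planted case/control haplotype shift is detected where planted", {
  spec <- ld_block_spec(
    c(ACG = 0.30, ATG = 0.25, GCG = 0.25, GTT = 0.20),
    case_shift = 0.12, shift_haplotype = "GTT"
  )
  bm <- simulate_ld_block(spec, 600, 600, seed = 101)
  scan <- haplotype_association_scan(bm, bm$variants$snp_id, sizes = c(2, 3))
  # within the full window, the shifted GTT haplotype is the most significant
  full <- scan[scan$window == "blk01|blk02|blk03", ]
  expect_equal(full$haplotype[which.min(full$p)], "GTT")
  top <- scan[which.min(scan$p), ]
  # the overall top haplotype is the GTT lineage restricted to its window
  first_snp <- as.integer(sub("blk0*(\\d+)\\|.*", "\\1", top$window))
  width <- nchar(top$haplotype)
  expect_equal(top$haplotype, substr("GTT", first_snp, first_snp + width - 1))
  expect_gt(top$f_a, top$f_u)
  em_ca <- em_haplotype_frequencies(bm, bm$variants$snp_id, stratum = "cases")
  em_co <- em_haplotype_frequencies(bm, bm$variants$snp_id, stratum = "controls")
  expect_equal(names(which.max(em_ca$freq - em_co$freq)), "GTT")
  # recovery of the planted frequency difference within 3 SE
  diff_hat <- max(em_ca$freq - em_co$freq)
  se <- sqrt(0.32 * 0.68 / (2 * 600) + 0.20 * 0.80 / (2 * 600))
  expect_lt(abs(diff_hat - 0.12), 3 * se)
})
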