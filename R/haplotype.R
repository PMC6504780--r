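#' EM estimation of haplotype frequencies over a SNP window
#'
#' Expectation-maximization over unphased multilocus genotypes for windows of
#' 2-4 SNPs. Haplotypes are allele strings over \{`allele_a1`, `allele_a2`\}
#' at each window SNP. The E-step distributes each individual over the
#' haplotype pairs compatible with its genotype with posterior weight
#' proportional to `f_h1 * f_h2` (doubled for heterozygous pairs); the M-step
#' re-estimates frequencies from expected counts. Initialization is uniform,
#' so the result is deterministic; convergence is declared when the largest
#' frequency change drops below `tol` (default 1e-8) or after `max_iter`
#' iterations.
#'
#' @param gm a [genotype_matrix()].
#' @param window_snps 2-4 snp ids, in window order.
#' @param stratum `"all"`, `"cases"` or `"controls"`.
#' @param tol convergence tolerance on frequencies.
#' @param max_iter iteration cap (default 1000).
#' @return list of class `haplotype_table`: `window_snps`, `haplotypes`
#'   (allele strings), `freq` (named frequencies), `loglik`, `loglik_trace`,
#'   `n_iterations`, `n_samples` (complete-data individuals used).
#' @export
em_haplotype_frequencies <- function(gm, window_snps,
                                     stratum = c("all", "cases", "controls"),
                                     tol = 1e-8, max_iter = 1000L) {
  stratum <- match.arg(stratum)
  k <- length(window_snps)
  if (k < 2L || k > 4L) stop("window must span 2-4 SNPs")
  idx <- match(window_snps, gm$variants$snp_id)
  if (anyNA(idx)) {
    stop("window SNP(s) absent from matrix: ",
         paste(window_snps[is.na(idx)], collapse = ", "))
  }
  rows <- switch(stratum,
    all = seq_along(gm$samples),
    cases = which(!is.na(gm$phenotype) & gm$phenotype == 1L),
    controls = which(!is.na(gm$phenotype) & gm$phenotype == 0L)
  )
  G <- gm$genotypes[rows, idx, drop = FALSE]
  G <- G[stats::complete.cases(G), , drop = FALSE]
  n <- nrow(G)
  if (!n) stop("no complete-data samples in stratum ", stratum)

  nh <- 2L^k
  # haplotype h (0-based) carries allele_a1 at site s iff bit s of h is set
  hap_bits <- t(vapply(0:(nh - 1L), function(h) bitwAnd(bitwShiftR(h, 0:(k - 1L)), 1L),
                       integer(k)))
  pairs_for <- compatible_pairs(G, hap_bits)   # per distinct genotype
  weights <- pairs_for$weights                 # multiplicity of each genotype
  plist <- pairs_for$pairs                     # list of 2-col matrices (1-based)

  f <- rep(1 / nh, nh)
  ll_trace <- numeric(0)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    newc <- numeric(nh)
    ll <- 0
    for (gidx in seq_along(plist)) {
      pr <- plist[[gidx]]
      w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
      tw <- sum(w)
      if (tw <= 0) {                            # support vanished; reseed uniform
        w <- rep(1, nrow(pr)); tw <- nrow(pr)
      }
      ll <- ll + weights[gidx] * log(tw)
      post <- weights[gidx] * w / tw
      for (r in seq_len(nrow(pr))) {
        newc[pr[r, 1L]] <- newc[pr[r, 1L]] + post[r]
        newc[pr[r, 2L]] <- newc[pr[r, 2L]] + post[r]
      }
    }
    ll_trace <- c(ll_trace, ll)
    fnew <- newc / (2 * n)
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }

  alle <- rbind(gm$variants$allele_a2[idx], gm$variants$allele_a1[idx])
  hap_str <- apply(hap_bits, 1L, function(b) {
    paste(alle[cbind(b + 1L, seq_len(k))], collapse = "")
  })
  names(f) <- hap_str
  structure(list(window_snps = window_snps, haplotypes = hap_str, freq = f,
                 loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
                 n_iterations = iters, n_samples = n),
            class = "haplotype_table")
}

# For each distinct multilocus genotype row, the list of compatible ordered
# haplotype pairs (h1 <= h2, 1-based indices into hap_bits rows).
compatible_pairs <- function(G, hap_bits) {
  keys <- apply(G, 1L, paste, collapse = ",")
  tab <- table(keys)
  uniq <- names(tab)
  k <- ncol(G)
  pairs <- lapply(uniq, function(key) {
    g <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    out <- NULL
    nh <- nrow(hap_bits)
    for (h1 in seq_len(nh)) {
      rem <- g - hap_bits[h1, ]
      if (any(rem < 0L | rem > 1L)) next
      h2 <- sum(rem * 2L^(seq_len(k) - 1L)) + 1L
      if (h2 >= h1) out <- rbind(out, c(h1, h2))
    }
    out
  })
  list(pairs = pairs, weights = as.integer(tab))
}

#' Normalized linkage disequilibrium D-prime between two SNPs
#'
#' Haplotype frequencies are estimated by the 2-SNP EM; with
#' `p11 = freq(a1 at A, a1 at B)`, `D = p11 - pA * pB` and
#' `D' = D / Dmax` where `Dmax = min(pA (1 - pB), (1 - pA) pB)` for `D > 0`
#' and `min(pA pB, (1 - pA)(1 - pB))` otherwise. The absolute value is
#' returned, so `D'` is in [0, 1] and symmetric in its arguments.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_a,snp_b snp ids.
#' @param stratum `"all"`, `"cases"` or `"controls"`.
#' @return `|D'|`.
#' @export
dprime <- function(gm, snp_a, snp_b, stratum = "all") {
  em <- em_haplotype_frequencies(gm, c(snp_a, snp_b), stratum = stratum)
  f <- em$freq
  # bit 0 = snp_a, bit 1 = snp_b (1-based index = h + 1)
  p11 <- f[[4L]]                               # a1 at both
  pa <- f[[2L]] + f[[4L]]                      # a1 at snp_a
  pb <- f[[3L]] + f[[4L]]                      # a1 at snp_b
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("D' undefined: monomorphic SNP in stratum")
  }
  d <- p11 - pa * pb
  dmax <- if (d > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) return(0)
  min(abs(d / dmax), 1)
}

#' Upper-tail chi-square P-value
#'
#' For `df = 1` the closed form via the normal tail (equivalently the
#' complementary error function) is used: `P = 2 * Phi(-sqrt(chi2))`;
#' other degrees of freedom fall back to the chi-square distribution
#' function.
#'
#' @param chi2 nonnegative statistic.
#' @param df positive integer degrees of freedom.
#' @return upper-tail probability.
#' @export
chisq_p <- function(chi2, df = 1L) {
  stopifnot(all(chi2 >= 0), df >= 1)
  if (df == 1L) 2 * stats::pnorm(-sqrt(chi2))
  else stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Per-haplotype case/control association tests
#'
#' For each haplotype, the EM-estimated case and control frequencies
#' (`F_A`, `F_U`) are expanded to expected chromosome counts
#' (`2 n F` vs `2 n (1 - F)`) forming a 2x2 haplotype-vs-others table, and a
#' Pearson chi-square with 1 df is computed. Haplotypes with overall
#' frequency below `min_freq` are skipped.
#'
#' @param table_cases,table_controls `haplotype_table`s for the same window
#'   from [em_haplotype_frequencies()].
#' @param n_cases,n_controls individuals per stratum.
#' @param min_freq rare-haplotype skip threshold on the pooled frequency
#'   (default 0.01).
#' @return data.frame: `haplotype`, `f_a`, `f_u`, `chi2`, `df`, `p`
#'   (`chi2`/`p` are `NA` for degenerate tables).
#' @export
haplotype_case_control_test <- function(table_cases, table_controls,
                                        n_cases, n_controls, min_freq = 0.01) {
  if (!identical(table_cases$window_snps, table_controls$window_snps)) {
    stop("case and control tables are for different windows")
  }
  haps <- table_cases$haplotypes
  fa <- table_cases$freq; fu <- table_controls$freq[haps]
  pooled <- (2 * n_cases * fa + 2 * n_controls * fu) /
    (2 * n_cases + 2 * n_controls)
  keep <- pooled >= min_freq
  out <- data.frame(haplotype = haps[keep], f_a = unname(fa[keep]),
                    f_u = unname(fu[keep]), chi2 = NA_real_, df = 1L,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    st <- pearson_2x2(2 * n_cases * out$f_a[i], 2 * n_cases * (1 - out$f_a[i]),
                      2 * n_controls * out$f_u[i], 2 * n_controls * (1 - out$f_u[i]))
    out$chi2[i] <- st
    if (!is.na(st)) out$p[i] <- chisq_p(st, 1L)
  }
  out
}

# Pearson chi-square for a 2x2 with cells (a b / c d); NA when a margin is 0.
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m <= 0)) return(NA_real_)
  n * (a * d - b * c)^2 / prod(m)
}

#' Contiguous sliding haplotype windows
#'
#' @param snp_ids ordered snp ids (positional order).
#' @param sizes window sizes, each in \{2, 3, 4\}.
#' @return list of character vectors, all contiguous windows of each size in
#'   positional order (sizes iterated in the given order).
#' @export
sliding_windows <- function(snp_ids, sizes = c(2L, 3L, 4L)) {
  if (length(snp_ids) < 2L) stop("need at least 2 SNPs")
  stopifnot(all(sizes %in% 2:4))
  out <- list()
  for (s in sizes) {
    if (s > length(snp_ids)) next
    for (i in seq_len(length(snp_ids) - s + 1L)) {
      out[[length(out) + 1L]] <- snp_ids[i:(i + s - 1L)]
    }
  }
  out
}

#' Haplotype association over sliding windows
#'
#' Convenience wrapper running [em_haplotype_frequencies()] per stratum and
#' [haplotype_case_control_test()] for every window.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_ids SNPs defining the windows (positional order).
#' @param sizes window sizes (default 2, 3, 4).
#' @param min_freq rare-haplotype threshold (default 0.01).
#' @return data.frame: `window`, `haplotype`, `f_a`, `f_u`, `chi2`, `df`, `p`.
#' @export
haplotype_association_scan <- function(gm, snp_ids, sizes = c(2L, 3L, 4L),
                                       min_freq = 0.01) {
  n_cases <- sum(gm$phenotype == 1L, na.rm = TRUE)
  n_controls <- sum(gm$phenotype == 0L, na.rm = TRUE)
  res <- lapply(sliding_windows(snp_ids, sizes), function(w) {
    ca <- em_haplotype_frequencies(gm, w, stratum = "cases")
    co <- em_haplotype_frequencies(gm, w, stratum = "controls")
    tests <- haplotype_case_control_test(ca, co, n_cases, n_controls,
                                         min_freq = min_freq)
    if (!nrow(tests)) return(NULL)
    cbind(window = paste(w, collapse = "|"), tests, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(window = character(), haplotype = character(),
                      f_a = numeric(), f_u = numeric(), chi2 = numeric(),
                      df = integer(), p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
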