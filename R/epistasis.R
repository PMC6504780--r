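#' Scan configuration for the pairwise interaction screen
#'
#' @param p_screen screening threshold on the Z-statistic P-value below which
#'   a pair is re-tested by dosage logistic regression (default 1e-8).
#' @param alpha family-wise significance level for the Bonferroni threshold
#'   (default 0.05).
#' @param continuity_correction value added to every cell of a 2x2 allele
#'   table that contains a zero cell (default 0.5, Haldane-Anscombe).
#' @param min_maf minimum MAF the input panel is expected to satisfy
#'   (default 0.05).
#' @param min_group_n minimum complete-data samples per phenotype group for
#'   the logistic refinement (default 10).
#' @return a `scan_config` list.
#' @export
scan_config <- function(p_screen = 1e-8, alpha = 0.05,
                        continuity_correction = 0.5, min_maf = 0.05,
                        min_group_n = 10L) {
  stopifnot(p_screen > 0, p_screen < 1, alpha > 0, alpha < 1,
            continuity_correction >= 0, min_maf >= 0, min_maf <= 0.5)
  structure(list(p_screen = p_screen, alpha = alpha,
                 continuity_correction = continuity_correction,
                 min_maf = min_maf, min_group_n = as.integer(min_group_n)),
            class = "scan_config")
}

#' 2x2 allele-pair contingency table for two SNPs in one phenotype group
#'
#' Each individual with complete data contributes its two chromosomes'
#' allele pairings under the phase-free cross-product convention:
#' `cell[j, k] = 0.5 * sum_i c_j(g1_i) * c_k(g2_i)` with `c_1(g) = g` and
#' `c_0(g) = 2 - g`. Unambiguous genotypes contribute integer counts; double
#' heterozygotes split evenly (0.5 per cell). Cells sum to twice the number
#' of complete-data individuals.
#'
#' @param g1,g2 genotype codes (same length).
#' @param mask logical/integer sample subset selecting one phenotype group.
#' @return 2x2 numeric matrix with rows = SNP1 allele (a1, a2), columns =
#'   SNP2 allele (a1, a2).
#' @export
allele_pair_table <- function(g1, g2, mask = NULL) {
  if (length(g1) != length(g2)) stop("g1 and g2 differ in length")
  if (!is.null(mask)) {
    g1 <- g1[mask]; g2 <- g2[mask]
  }
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no samples with complete data for this SNP pair")
  g1 <- g1[ok]; g2 <- g2[ok]
  tab <- matrix(0, 2L, 2L, dimnames = list(snp1 = c("a1", "a2"),
                                           snp2 = c("a1", "a2")))
  tab[1L, 1L] <- 0.5 * sum(g1 * g2)
  tab[1L, 2L] <- 0.5 * sum(g1 * (2 - g2))
  tab[2L, 1L] <- 0.5 * sum((2 - g1) * g2)
  tab[2L, 2L] <- 0.5 * sum((2 - g1) * (2 - g2))
  tab
}

# ln(OR) and its Woolf variance for a 2x2 table, with the continuity
# correction applied to every cell when any cell is zero.
log_or_and_var <- function(tab, cc) {
  if (any(tab == 0)) tab <- tab + cc
  if (any(tab <= 0)) stop("allele table degenerate after continuity correction")
  list(log_or = log(tab[1L, 1L]) + log(tab[2L, 2L]) -
         log(tab[1L, 2L]) - log(tab[2L, 1L]),
       var = sum(1 / tab))
}

#' Allele-based epistasis Z statistic
#'
#' The screening statistic compares the SNP1-SNP2 allelic odds ratio between
#' cases (R) and controls (S):
#' `Z = (ln R - ln S) / sqrt(Var(ln R) + Var(ln S))`. Each variance is the
#' Woolf estimate `sum(1/n_ij)` on the (possibly continuity-corrected)
#' allele-pair table, halved: the 0.5-split pseudo-pair table counts both
#' allele pairings of every individual, and the two pairings are not
#' independent -- the delta method under Hardy-Weinberg and between-SNP
#' independence gives exactly half the naive Woolf value. Without the
#' correction the screen is badly conservative (type-I error near 0.004 at
#' nominal 0.05); with it the null Z is standard normal, which is also the
#' behaviour of the corrected test in PLINK 1.9. The P-value is the
#' two-sided normal tail.
#'
#' @param table_cases,table_controls 2x2 allele-pair tables from
#'   [allele_pair_table()].
#' @param cc continuity correction for zero cells (default 0.5).
#' @return list with `z`, `p_z`, `log_r`, `log_s`.
#' @export
fast_epistasis_z <- function(table_cases, table_controls, cc = 0.5) {
  if (all(table_cases == 0) || all(table_controls == 0)) {
    stop("undefined statistic: an allele table is all zero")
  }
  r <- log_or_and_var(table_cases, cc)
  s <- log_or_and_var(table_controls, cc)
  z <- (r$log_or - s$log_or) / sqrt((r$var + s$var) / 2)
  list(z = z, p_z = 2 * stats::pnorm(-abs(z)), log_r = r$log_or, log_s = s$log_or)
}

#' Dosage logistic regression with an interaction term
#'
#' Fits `logit P(case) = b0 + b1 g1 + b2 g2 + b3 g1 g2` by iteratively
#' reweighted least squares with step-halving (so the log-likelihood is
#' non-decreasing across iterations), and returns the Wald test of the
#' interaction coefficient `b3`. Non-convergence within `max_iter` iterations
#' (gradient tolerance 1e-8) or separation is reported through
#' `converged = FALSE` with a missing P-value, not an error.
#'
#' @param g1,g2 genotype codes.
#' @param phenotype binary vector (1 = case, 0 = control, NA dropped).
#' @param min_group_n minimum complete-data samples required in each
#'   phenotype group (default 10).
#' @param max_iter iteration cap (default 100).
#' @param tol gradient convergence tolerance (default 1e-8).
#' @return list with `beta_int`, `se`, `p_dosage`, `converged`, `n_used`,
#'   `coefficients`, `loglik_trace`.
#' @export
dosage_logistic_interaction <- function(g1, g2, phenotype, min_group_n = 10L,
                                        max_iter = 100L, tol = 1e-8) {
  ok <- !is.na(g1) & !is.na(g2) & !is.na(phenotype)
  g1 <- as.numeric(g1[ok]); g2 <- as.numeric(g2[ok]); y <- phenotype[ok]
  if (sum(y == 1L) < min_group_n || sum(y == 0L) < min_group_n) {
    stop(sprintf("need at least %d complete-data samples per phenotype group",
                 min_group_n))
  }
  X <- unname(cbind(1, g1, g2, g1 * g2))
  fit <- irls_logistic(X, y, max_iter = max_iter, tol = tol)
  p <- if (fit$converged) 2 * stats::pnorm(-abs(fit$beta[4L] / fit$se[4L])) else NA_real_
  list(beta_int = fit$beta[4L], se = fit$se[4L], p_dosage = p,
       converged = fit$converged, n_used = length(y),
       coefficients = fit$beta, loglik_trace = fit$loglik_trace)
}

# Newton/IRLS for binomial logit with step-halving; flags (rather than
# errors on) non-convergence and quasi-separation.
irls_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * sqrt(w))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) break                   # singular information: separation
    s <- 1
    repeat {
      cand <- beta + s * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    beta <- beta + s * step
    ll <- loglik(beta)
    trace <- c(trace, ll)
    if (max(abs(beta)) > 50) break             # diverging: separation
  }
  # coefficients drifting to the boundary mean (quasi-)separation: the MLE
  # does not exist and the Wald test is meaningless, so flag it
  if (converged && max(abs(beta)) > 30) converged <- FALSE
  se <- rep(NA_real_, length(beta))
  if (converged) {
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) converged <- FALSE else se <- sqrt(diag(cov))
  }
  list(beta = beta, se = se, converged = converged, loglik_trace = trace)
}

#' Number of unordered SNP pairs
#'
#' @param m number of SNPs (>= 2).
#' @return `m * (m - 1) / 2`, exact (returned as a double; exact for any
#'   panel size of interest since the count stays far below 2^53).
#' @export
n_pairs <- function(m) {
  if (m < 2) stop("need at least 2 SNPs")
  m <- as.double(m)
  m * (m - 1) / 2
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Genome-wide pairwise epistasis scan
#'
#' Computes the allele-based Z statistic for every unordered SNP pair
#' (i < j in variant order), then refits pairs passing the screening
#' threshold (`p_z < p_screen`) with [dosage_logistic_interaction()].
#' The scan is vectorised through cross-products of the dosage matrix, so
#' missing genotypes are excluded pairwise.
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param config a [scan_config()].
#' @return data.frame of class `epistasis_scan` with columns `snp1`, `chr1`,
#'   `snp2`, `chr2`, `z`, `p_z`, `beta_int`, `p_dosage`, `n_used`, sorted by
#'   `p_z` ascending (ties by snp ids); attributes `n_tests` (total pairs),
#'   `n_skipped` (degenerate pairs) and `bonferroni` (alpha / n_tests).
#' @export
pairwise_scan <- function(gm, config = scan_config()) {
  m <- ncol(gm$genotypes)
  if (m < 2L) stop("need at least 2 SNPs to scan")
  ph <- gm$phenotype
  cc <- config$continuity_correction

  cells <- function(rows) {
    G <- gm$genotypes[rows, , drop = FALSE]
    M <- !is.na(G)
    Gz <- ifelse(M, G, 0L)
    Hz <- ifelse(M, 2L - G, 0L)
    list(
      aa = 0.5 * crossprod(Gz, Gz), ab = 0.5 * crossprod(Gz, Hz),
      ba = 0.5 * crossprod(Hz, Gz), bb = 0.5 * crossprod(Hz, Hz),
      n = crossprod(M * 1L, M * 1L)
    )
  }
  logor_var <- function(ce) {
    zero <- ce$aa == 0 | ce$ab == 0 | ce$ba == 0 | ce$bb == 0
    add <- ifelse(zero, cc, 0)
    aa <- ce$aa + add; ab <- ce$ab + add; ba <- ce$ba + add; bb <- ce$bb + add
    bad <- aa <= 0 | ab <= 0 | ba <= 0 | bb <= 0 | ce$n == 0
    lo <- log(aa) + log(bb) - log(ab) - log(ba)
    v <- 1 / aa + 1 / ab + 1 / ba + 1 / bb
    lo[bad] <- NA_real_; v[bad] <- NA_real_
    list(lo = lo, v = v, n = ce$n)
  }
  ca <- logor_var(cells(which(!is.na(ph) & ph == 1L)))
  co <- logor_var(cells(which(!is.na(ph) & ph == 0L)))
  zmat <- (ca$lo - co$lo) / sqrt((ca$v + co$v) / 2)  # see fast_epistasis_z

  ut <- upper.tri(zmat)
  idx <- which(ut, arr.ind = TRUE)
  z <- zmat[ut]
  skipped <- is.na(z)
  p_z <- 2 * stats::pnorm(-abs(z))
  v <- gm$variants
  res <- data.frame(
    snp1 = v$snp_id[idx[, 1L]], chr1 = v$chrom[idx[, 1L]],
    snp2 = v$snp_id[idx[, 2L]], chr2 = v$chrom[idx[, 2L]],
    z = z, p_z = p_z, beta_int = NA_real_, p_dosage = NA_real_,
    n_used = as.integer(ca$n[ut] + co$n[ut]), stringsAsFactors = FALSE
  )
  res <- res[!skipped, , drop = FALSE]
  if (sum(skipped)) {
    message(sprintf("pairwise_scan: %d degenerate pair(s) skipped", sum(skipped)))
  }

  hits <- which(res$p_z < config$p_screen)
  for (h in hits) {
    fit <- dosage_logistic_interaction(
      genotype_column(gm, res$snp1[h]), genotype_column(gm, res$snp2[h]), ph,
      min_group_n = config$min_group_n
    )
    res$beta_int[h] <- fit$beta_int
    res$p_dosage[h] <- fit$p_dosage
    res$n_used[h] <- fit$n_used
  }

  res <- res[order(res$p_z, res$snp1, res$snp2), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tests") <- n_pairs(m)
  attr(res, "n_skipped") <- sum(skipped)
  attr(res, "bonferroni") <- bonferroni_threshold(config$alpha, n_pairs(m))
  class(res) <- c("epistasis_scan", "data.frame")
  res
}
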