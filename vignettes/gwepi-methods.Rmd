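---
title: "Methods and design notes for gwepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gwepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwepi)
```

This vignette is the package's own account of its statistical machinery: the
models, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, the numerical choices, and the places where
the design was genuinely open and a choice had to be made.

## The analysis chain

The package targets case/control cohorts of the common-variant GWAS era —
the motivating design is an all-female cohort of 493 extremely obese cases
(BMI > 35) and 537 never-overweight controls (BMI < 25) genotyped on a
~550k SNP array — and runs, in order: per-SNP quality control; an exhaustive
pairwise interaction screen; logistic refinement of screened pairs; locus
clustering of the surviving interactions; EM haplotype association over the
clustered SNPs; and permutation-based pathway association.

## Quality control

Three per-SNP filters, applied jointly by `qc_filter()`:

* **MAF** (`maf_min`, default 0.05): the minor allele frequency computed
  from the data, `min(f, 1 - f)` over non-missing genotypes. The 0.05
  default is the interaction-scan convention; pathway-style analyses often
  relax it to 0.01 (set `maf_min = 0.01`).
* **Hardy–Weinberg** (`hwe_p_min`, default 0.001): an *exact* conditional
  test on heterozygote counts given allele counts, not the asymptotic χ².
  The threshold operates at P = 1e-3, deep enough in the tail that the
  asymptotic test is unreliable for rare alleles; the exact test costs
  nothing at these panel sizes. HWE is computed on all samples by default
  (`hwe_stratum = "controls"` is available); the convention used is logged
  with the drop counts, since case-enriched disequilibrium can otherwise
  silently remove signal.
* **Missingness** (`max_missing_per_snp`, default 0.05): no per-SNP
  missingness convention is universal; 0.05 is the common default and is
  exposed as configuration.

Missing genotypes are excluded pairwise per operation everywhere downstream;
no imputation is attempted. The minor allele is determined empirically at
read time; at an exact 0.5 frequency the incoming (ped/bim) designation is
kept — the only case where a text-format round trip is ambiguous, since the
ped format cannot record which allele was counted.

## The pairwise screen

Each phenotype group's 2×2 allele-pair table uses the phase-free
cross-product convention: an individual with codes (g1, g2) contributes
`0.5 * c_j(g1) * c_k(g2)` to cell (j, k), with `c_1(g) = g`,
`c_0(g) = 2 - g`. Unambiguous genotypes contribute integer pair counts; the
double heterozygote — whose two chromosome-level pairings are genuinely
unknowable without phase — splits 0.5 into every cell. Cells sum to two
pairings per complete-data individual.

The screening statistic is

$$Z = \frac{\ln R - \ln S}{\sqrt{(\widehat{Var}(\ln R) + \widehat{Var}(\ln S))/2}},$$

with R and S the case and control odds ratios and each variance the Woolf
estimate $\sum 1/n_{jk}$ on the (continuity-corrected) table, **halved**.
The halving is deliberate and load-bearing. The pseudo-pair table counts
both allele pairings of every individual, and those two pairings are
dependent; treating the table as 2N independent draws overstates the
variance by a factor of exactly 2 under Hardy–Weinberg and between-SNP
independence (a delta-method calculation on the per-individual outer
products, confirmed empirically: the measured ratio over 3000 null
replicates at n = 1000 was 0.489). With the naive variance the screen
rejects at ~0.004 when it should reject at 0.05 — a screen that silently
discards true signal. The corrected denominator makes the null Z standard
normal; this is also the behaviour of the dependence-corrected fast
epistasis test that modern PLINK releases run by default. The acceptance
suite verifies the calibration (2000 seeded null replicates, n = 1000,
type-I within 3 Monte-Carlo SD of 0.05).

Other screen choices: zero cells receive a 0.5 continuity correction added
to every cell of the affected table (Haldane–Anscombe, keeping ln OR
finite); the screening threshold defaults to 1e-8 and the family-wise α to
0.05; within-chromosome pairs are *included* (nothing in the analysis
design excludes them, and cross-region clusters are exactly what the locus
step looks for); scan output is sorted by P with ties broken by SNP ids so
runs are byte-reproducible.

Pairs passing the screen are refit by `logit P(case) = b0 + b1 g1 + b2 g2 +
b3 g1 g2`, estimated by an explicit IRLS with step-halving so the
log-likelihood trace is provably non-decreasing. The fit is authored rather
than delegated to `glm()` because the contract requires a monotone
likelihood trace, a hard iteration cap (100) with gradient tolerance 1e-8,
and a *flagged* (not thrown) non-convergence/separation outcome — a
coefficient drifting past 30 on the logit scale marks the pair as
separated, with a missing Wald P, since the MLE does not exist there. Tests
verify the coefficients against both `glm()` and a generic BFGS maximizer
of the same likelihood to 1e-6.

## Locus clustering

Screened interactions are mapped to loci — named genes and cytoband-style
regions supplied as ordinary BED4 intervals, so intergenic clusters can be
retained as regions. Two exclusion criteria are applied: interactions where
either SNP maps to no locus are dropped; and a locus pair is kept only when
it has at least `min_support` (default 2) supporting interactions *and* at
least two distinct SNPs on each side. The second criterion's published
phrasing ("either SNP exists independently in a gene") is ambiguous between
a per-interaction and a per-locus reading; the per-locus reading (a side
represented by a single SNP is insufficient) is implemented because it is
the one that keeps a multi-SNP, many-interaction cluster while discarding
singleton hits. This is recorded as an interpretation, not as the original
authors' certain intent. Unordered pairs are keyed with the
lexicographically smaller locus first.

## Haplotype analysis

`em_haplotype_frequencies()` runs EM over unphased multilocus genotypes for
2–4-SNP windows: the E-step distributes each individual over compatible
haplotype pairs with weight proportional to `f_h1 f_h2` (doubled for
heterozygous pairs), the M-step re-estimates frequencies from expected
counts. Initialization is uniform, making the run deterministic; with at
most 16 haplotypes, multiple restarts are unnecessary, and the test suite
guards against local optima by comparing the final log-likelihood with an
exhaustive simplex grid search (plus a BFGS polish) on a toy whose data
restrict the support to five haplotypes. Convergence is declared at a
maximum frequency change below 1e-8 or 1000 iterations.

D′ is computed from the 2-SNP EM frequencies, `D = p11 - pA pB` normalized
by its margin-constrained extreme, reported as |D′| ∈ [0, 1].

Per-haplotype tests are haplotype-vs-all-others: the stratum frequencies
F_A, F_U are expanded to expected chromosome counts (2N·F vs 2N·(1−F)),
forming a 2×2 Pearson χ² with df = 1 — matching the one-row-per-haplotype,
DF = 1 reporting convention of standard haplotype association output. No
omnibus test is run. Haplotypes below 1% pooled frequency are skipped
(configurable). The expected counts are EM posteriors and may be
fractional; the χ² is computed on them as-is. Windows are sliding
(every contiguous window of sizes 2, 3 and 4); a hand-picked window list
can be given instead. Chromosome counts are 2N throughout — autosomal
analysis of a single-sex cohort, X handling out of scope.

A note on reproducing printed tables: published per-haplotype χ² values
cannot in general be recovered from frequencies printed at two decimals
(the rounding error dwarfs the statistic's sensitivity), so the package's
exact targets go through the χ² → P transformation only, which reproduces
printed P-values (0.013, 0.018, 0.033 at df = 1) from the printed
statistics exactly.

## Pathway association

The genotype-level method is GSEA on gene statistics. Each SNP gets a 1-df
allelic χ² (2×2 allele-count by phenotype table; the Cochran–Armitage trend
test is the config alternative — the underlying program family defaults to
the allelic form, and nothing in the target analysis pins it down); each
gene covering at least one SNP within ±20 kb scores the maximum of its
SNPs' χ² (a SNP in two overlapping windows counts for both genes). Genes
are ranked descending, ties broken by gene id for determinism. The
enrichment score is the signed maximum deviation of the weighted KS running
sum (hits increment by stat^p normalized by the member total, p = 1;
misses decrement by 1/(N − N_members)).

Significance comes from phenotype-label permutations only — genotypes are
never permuted, so LD structure is preserved exactly. Per set,
NES = ES / mean(positive permuted ES); sets with non-positive ES get
NES ≤ 0 and empirical P near 1 (enrichment-direction-only, the convention
of the cited program family; a two-tailed treatment is *not* applied, and
whether the original analyses pooled signed or positive-only NES is not
recoverable — the positive-only convention is implemented and documented).
Empirical P uses the pseudo-count floor (1 + #{perm ≥ obs})/(n_perm + 1),
so it is never zero. FDR is the permutation ratio estimate (fraction of all
permuted NES above the observed NES, over the fraction of observed NES
above it, capped at 1); FWER is the fraction of permutation rounds whose
maximum NES reaches it. The permutation RNG is seeded explicitly and the
seed is required — runs are bit-reproducible.

Gene sets are size-filtered to [5, 200] *after* intersection with the
covered-gene universe (genes with ≥ 1 QC-passing SNP in their flanked
window). The replication-style method for summary statistics,
`gsa_snp_pathway()`, scores genes by −log₁₀ P and tests each set by
`z = (mean member score − mean all)/(sd all / sqrt(set size))` with BH-FDR
across sets; its k-th-best-SNP parameter is moot here because per-gene
P-values arrive precomputed.

## Synthetic data: what it emulates and what it does not

The generators state a world matching the analysis assumptions, with
defaults fixed at the motivating study's design: 493 cases / 537 controls,
MAF drawn uniformly on [0.05, 0.5], genotypes binomial(2, MAF) in
Hardy–Weinberg proportions, missingness Bernoulli (default 0).

* `simulate_epistatic_cohort()` draws genotypes under the null and assigns
  case status by the logistic penetrance `logit P = b0 + b1 g1 + b2 g2 +
  b3 g1 g2`, rejection-sampling to the exact case/control quotas
  (ascertainment, capped at 1e7 draws with an explicit failure). The
  penetrance model is the analysis model, which is what makes parameter
  recovery (b3 within ±0.25 at n = 4000) a meaningful acceptance surface —
  and also what it means: a green recovery test establishes correctness of
  the estimator under its own model, not robustness to model misfit.
* `simulate_ld_block()` draws two haplotypes per individual from a stated
  haplotype-frequency distribution, with an additive shift on one
  haplotype's case-stratum frequency (others renormalized proportionally);
  genotypes are unphased sums.
* `simulate_pathway_cohort()` tiles non-overlapping 20 kb gene bodies 50 kb
  apart, places 2–4 SNPs per body, applies a marginal logit effect to the
  planted set's SNPs (dosages centred at expectation so the population case
  rate stays near the quota ratio), and emits size-matched random competitor
  sets. The planted-set default of 19 genes mirrors the size of the small
  curated immune pathway the motivating analysis surfaced.

None of the generators model realistic genome-wide LD maps, population
structure, relatedness, or imputation uncertainty. A green end-to-end test
therefore establishes that the pipeline's statistics do what they claim on
data satisfying their assumptions — not that the pipeline is robust to the
confounders of a real cohort.

## Numerical and formatting choices

* χ² upper tails use the closed normal-tail form at df = 1 and the
  chi-square distribution function otherwise; the two agree to 1e-12.
* Exact HWE probabilities are computed in log-space with a 1e-12-relative
  slack when summing "at most as probable" outcomes, so ties are included
  regardless of rounding direction.
* The pair count m(m−1)/2 is computed in doubles: exact for any panel size
  of interest (counts stay far below 2^53), and a 32-bit integer would
  overflow at genome-wide m.
* Stage TSVs are written with 6 significant digits, "." decimal and a fixed
  column order; two runs with the same config and seed are byte-identical,
  which the pipeline tests assert with `readLines()` equality.
* The pipeline manifest (JSON) records package and R versions, parameters,
  seed, per-stage row counts and wall time; rerunning a directory reuses
  completed stage outputs unless forced, and the manifest flags the reuse.

## Known limitations

* The pairwise scan is O(m²) in memory as implemented (dense m×m
  cross-product matrices per phenotype group): designed for the
  reduced-panel regime the tests exercise, not for 500k SNPs in one call.
  Chunking over SNP blocks is the obvious extension.
* The locus step does not look up cytobands from a genome build; regions
  must be supplied as annotation intervals.
* Only biallelic autosomal SNPs are handled; VCF, dosage formats and X/Y/MT
  conventions are out of scope.
* The per-haplotype test treats EM frequency estimates as fixed when
  forming the 2×2 table, ignoring EM uncertainty — the standard convention
  for this output format, but anticonservative for poorly resolved phase.
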