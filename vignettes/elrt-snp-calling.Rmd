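---
title: "Calling SNPs from multi-sample read counts with a calibrated eLRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling SNPs from multi-sample read counts with a calibrated eLRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elrtcall)
```

## The problem

Given short-read sequencing data from $n$ unrelated diploid individuals, a
locus is a SNP exactly when its variant-allele population frequency $p$ is
positive. Bayesian multi-sample callers report posterior probabilities or
quality scores, which are awkward to threshold at a chosen false discovery
rate. `elrtcall` instead treats calling as the boundary hypothesis test

$$H_0: p = 0 \quad \text{vs} \quad H_a: p > 0,$$

producing a per-locus p-value, so genomewide FDR control reduces to ordinary
Benjamini–Hochberg adjustment. The only input is a table of per-sample read
counts — total reads $N_{ij}$ and variant-allele reads $X_{ij}$ at locus $j$
in sample $i$ — so the method is agnostic to platform and upstream aligner.

## Model

Under Hardy–Weinberg equilibrium the genotype of a sample carries 0, 1 or 2
variant copies with probabilities $(1-p)^2$, $2p(1-p)$, $p^2$. Conditional on
genotype and coverage, the variant-read count is binomial with success
probability $e$, $1/2$, or $1-e$, where $e$ is a single per-locus symmetric
mapping/sequencing error rate. The per-locus log-likelihood is therefore a
sum over samples of the log of a three-component binomial mixture
(`mixture_loglik()`). Zero-coverage samples contribute $\log 1 = 0$ and are
retained, so sample bookkeeping stays honest.

Under $H_0$ the error-rate MLE has the closed form
$\tilde e = \sum_i X_{ij} / \sum_i N_{ij}$ (`null_error_mle()`). Rather than
maximizing jointly over $(e, p)$ — slow, and numerically touchy at the
boundary — the *estimated* likelihood-ratio statistic plugs $\tilde e$ in and
profiles only over $p$:

$$T_j = 2\left\{\max_{p}\, l(\tilde e_j, p) - l(\tilde e_j, 0)\right\}.$$

`full_lrt_stat()` implements the jointly maximized statistic as a validation
oracle; on simulated data, calls based on the two statistics disagree on well
under 2% of loci, while the profiled form is far cheaper.

### Numerical choices

* Profile maximization over $p \in [0, 1]$ uses a 50-point warm-start grid
  followed by Brent refinement (absolute tolerance $10^{-8}$) on the
  bracketing interval, with explicit endpoint checks. The warm grid is
  log-spaced on $[10^{-5}, 0.02]$ and linear above, because rare-variant
  optima sit within a few multiples of $10^{-3}$ of the boundary where a
  uniform grid has no resolution.
* $p$ ranges over $[0, 1]$, not $[0, 0.5]$: the tested frequency is the
  variant-allele frequency, and real loci where the reference carries the
  minor allele should not be truncated.
* A locus is an *exact zero* when the profiled likelihood cannot beat
  $l(\tilde e, 0)$: the score at $p = 0$ is non-positive and no warm-grid
  point improves on the null. Numerically, any statistic below
  `zero_epsilon = 1e-8` is treated as zero — boundary maximization leaves
  $O(10^{-10})$ residue at true-zero loci, and the zero count feeds the null
  calibration below, so the threshold matters.
* Binomial pmfs are evaluated in log space and rescaled per (N, X) pair, so
  coverage in the hundreds cannot underflow the mixture.
* Loci with $\tilde e \ge 0.5$ (nearly all reads variant, e.g. a monomorphic
  variant site) are still scored, with a warning: the symmetric-error model
  is strained there, and with $\tilde e = 0.5$ exactly the three mixture
  components coincide and the statistic is identically zero — such loci carry
  no testable signal under this model.

## Null calibration

Because $p = 0$ lies on the boundary of the parameter space, the textbook
large-sample null for $T_j$ is the half-and-half mixture
$D_{0.5,1} = 0.5\cdot 0 + 0.5\cdot\chi^2_1$. With realistic error rates
($e \approx 0.01$) the finite-sample null deviates drastically: far more than
half of the null statistics are *exactly* zero, and the positive part is
mildly rescaled. The package models the null as

$$D_{a,k} = a\cdot 0 + (1-a)\cdot k\chi^2_1,$$

estimating $a$ as the fraction $J_0/J$ of presumed-null loci with $T = 0$ and
$k$ as the mean of the positive null statistics after discarding values above
15 (about the upper $10^{-4}$ quantile of $\chi^2_1$, so trimming removes
outliers, not signal; the threshold is configurable, and a statistic exactly
at it is kept). The p-value of a positive statistic is
$(1-a)\Pr(\chi^2_1 \ge T/k)$; we read the scaled chi-square factor as its
survival function, the only interpretation that yields a probability. A zero
statistic gets p-value 1, since the whole mixture mass lies at or above zero.

By default *all* loci enter the calibration — genomewide, the overwhelming
majority of candidate loci are not SNPs — and a known-SNP exclusion list
(e.g. database positions) refines the null set. Degenerate boundary: if no
positive null statistic survives, $a$ is continuity-corrected to $J_0/(J+1)$
and $k$ falls back to the limiting value 1, so $(1-a)$ never becomes exactly
zero and positive statistics never get p-value 0.

`call_snps()` composes the pipeline: statistics, calibration (or the fixed
$D_{0.5,1}$ via `null_model = "limiting"`), p-values, BH adjustment
(`p.adjust(method = "BH")` — an explicit choice, not the function's default),
and calls at `q <= fdr`.

```{r example}
sim_snp <- simulate_counts(n_loci = 100, n_samples = 100, coverage_mean = 10,
                           maf_range = c(0.05, 0.1), id_prefix = "S", seed = 7)
sim_nul <- simulate_counts(n_loci = 5000, n_samples = 100, coverage_mean = 10,
                           maf_range = c(0, 0), id_prefix = "N", seed = 8)
counts <- dplyr::bind_rows(sim_snp$counts, sim_nul$counts)
res <- call_snps(counts, fdr = 0.05, quiet = TRUE)
glance(res)
```

## What the simulator emulates — and what it does not

`simulate_counts()` reproduces the generative model used to study the
caller's operating characteristics:

* **Error rates** per locus from a clamped normal
  $e = \max\{0, N(\mu_e, \sigma^2)\}$ with $\sigma^2 = 10^{-6}$; clamping
  (rather than redrawing) follows the model's own definition. Platform-like
  means are $10^{-2}$ (HiSeq-class) and $10^{-3}$.
* **MAFs** uniform on a stratum: $U(0.001, 0.01)$ rare, $U(0.01, 0.05)$ less
  rare, $U(0.05, 0.1)$ common; exactly 0 for null loci.
* **Coverage** generalized Poisson with mean $\mu$ and dispersion
  $\lambda = $ mean/variance, defaulting to $\lambda = 0.4$ (over-dispersion
  as estimated from low-coverage human resequencing data); $\lambda = 1$
  reduces exactly to Poisson. Internally this is Consul's family with
  $\theta = \mu\sqrt\lambda$, $\delta = 1 - \sqrt\lambda$ (mean
  $\theta/(1-\delta)$, variance $\theta/(1-\delta)^3$). `rgpois()` draws
  from the exact pmf truncated at $10^{-12}$ upper-tail mass by default —
  the branching-process (Poisson cascade) sampler is also provided and
  distributionally indistinguishable, but an order of magnitude slower at
  the $10^8$ draws a full grid requires.
* **Genotypes** independent per sample (unrelated individuals, HWE), fixed
  per locus; **reads** binomial given genotype, coverage and the locus error
  rate. Zero-coverage samples are kept.

`study_grid()` enumerates the benchmark: 96 SNP combinations (2 error means
× 3 MAF strata × n ∈ {50, 100, 200, 500} × coverage ∈ {5, 10, 20, 30}) of
5×10³ SNP loci each, and 32 null combinations of 5×10⁵ loci each (SNPs are
roughly 1% of loci genomewide), with a `scale` multiplier for smaller runs.

The simulator works at the read-count level. It does **not** emulate
sequence-level artifacts: alignment and mapping biases, base-quality
variation within a locus, strand effects, indels, duplicated reads, linkage
disequilibrium between loci, or related individuals. Tests passing on this
generator therefore validate the statistical machinery under its own model
assumptions; they do not certify performance on real alignments, where error
symmetry and the single-per-locus error rate are approximations.

## Benchmark studies and the problem sizes used

Two study drivers reproduce the method's headline operating characteristics:

* `run_fdr_study()` runs all 96 SNP combinations, each with 500 SNP loci
  plus 2×10⁴ matching null loci (a 1/10 and 1/25 reduction of the full-scale
  design — medians across 96 datasets are stable at this size and the whole
  study runs in a few minutes on one CPU). Calibration excludes the true SNP
  loci via the exclusion mechanism, the simulation analogue of masking
  database-known SNPs. Expected behaviour: adaptive-null median empirical
  FDRs close to the nominal 0.01/0.05/0.1, limiting-null medians near zero
  with visibly lower power.
* `run_null_study()` fits $(\hat a, \hat k)$ on each of the 32 null
  combinations with 5×10⁴ loci each — at high coverage positive null
  statistics are rare (a few per 10⁴ loci), so this size keeps the trimmed
  mean usable. Expected behaviour: $\hat a$ far above the limiting 0.5,
  averaging near 0.98 and increasing with coverage; $\hat k$ near 1.

`scripts/acceptance.R` in the source repository recomputes both studies plus
the constant-coverage-2 zero-mass check from scratch and writes the summary
numbers as JSON.

## Design notes

* The eLRT is computed in compiled code (a per-locus collapse to unique
  (N, X) pairs, then grid + Brent profile maximization); a genomewide run of
  ~2×10⁶ loci scores in about a minute per 100 samples.
* Choosing the variant allele from pileup input is a convention of this
  package (most frequent pooled non-reference base, ties broken A<C<G<T;
  third-allele reads excluded from both X and N to keep the biallelic model
  honest; base quality below 13 dropped). Count-table input sidesteps all of
  this and is the preferred interface.
* Empirical FDR of a call set with zero calls is reported as 0: a caller
  that calls nothing makes no false discoveries. Medians across benchmark
  datasets depend on this convention only when a method calls almost
  nothing.
* Ti/Tv with zero transversions is reported as NaN rather than Inf, flagging
  an undefined ratio.

## Known limitations

* One error rate per locus: per-base qualities are not used.
* Biallelic, diploid loci only; no indels; no per-individual genotype calls.
* The calibration assumes the presumed-null set is overwhelmingly null;
  in small targeted panels with dense signal, supply an exclusion list or
  expect conservative $\hat k$ and slightly inflated $\hat a$ contamination.
* With very low information (e.g. constant coverage 2), the positive part of
  the null statistic is markedly discrete and the scaled-chi-square fit is
  rougher; the zero fraction $a$ then carries most of the calibration.
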