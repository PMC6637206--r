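---
title: "Conditional FDR for pleiotropy-informed GWAS discovery: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional FDR for pleiotropy-informed GWAS discovery: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two complex traits that share genetic architecture — the motivating example
is coronary artery disease and blood pressure — each have many true
susceptibility variants hiding below the genome-wide significance threshold
of their individual GWAS. When a variant is associated with both traits
(pleiotropy), its p-value in the second trait carries information about the
first. The conditional false discovery rate turns that information into a
per-SNP significance measure: SNPs that are nominally sub-threshold in the
principal trait but strongly associated with the secondary trait can be
declared at a controlled error rate, while SNPs with no secondary support
are held to the usual standard.

All the package needs is two summary-statistics files sharing SNP
identifiers; no individual-level genotypes are touched.

## The estimator

Write `p_i` for the principal trait's p-value at a SNP and `p_j` for the
conditioning trait's. The conditional FDR is the posterior probability that
the SNP is null for trait `i` given that both p-values are at or below the
observed pair,

    cFDR(p_i | p_j) = Pr(H0_i | P_i <= p_i, P_j <= p_j),

estimated from the joint empirical CDF of the panel by the count ratio

    cFDR^(p_i | p_j) = p_i * #{p_j' <= p_j} / #{p_i' <= p_i and p_j' <= p_j},

capped at 1. The numerator `p_i * N_j` is the expected count of nulls in the
lower-left quadrant if trait-i p-values were uniform among SNPs passing the
conditioning cut; the denominator is the observed count. All counts use
`<=`, the query SNP included, so the denominator is at least 1 and the
estimator is bounded below by `p_i` exactly. The conjunctional cFDR, which
flags SNPs associated with *both* traits, is the maximum of the two
conditioning directions:

    ccFDR = max(cFDR(p_i | p_j), cFDR(p_j | p_i)).

Loci are declared at cFDR < 0.05 (the `-log10` Manhattan line at 1.3010);
the comparison is strict, so a value exactly at 0.05 is excluded.

Conditioning at `p_j = 1` collapses the estimator to `p_i * n / rank(p_i)`,
the raw Benjamini–Hochberg quantity; after the standard suffix-minimum
regularisation it *is* the BH-adjusted p-value, which the test suite checks
against `p.adjust` on a tie-free panel. This is the sense in which the
method is a strict generalisation of unconditional FDR control.

### Numerical choices

* Per-SNP values are computed by exact counting at the observed pairs (a
  Fenwick-tree dominance count, O(n log n)), never by interpolating the
  exported look-up tables; interpolation error is thereby avoided entirely.
* The count ratio is formed before multiplying by `p_i`, so a ratio of
  exactly 1 returns `p_i` to the last bit and the `cFDR >= p_i` bound is
  exact rather than approximate.
* Per-SNP values are reported raw by default. Raw values are unambiguous
  and reproducible; an optional switch (`assign_cfdr(monotonize_snps =
  TRUE)`) applies the BH-style suffix-minimum within conditioning strata for
  users who want monotone significance along ranked p-values. Exported
  look-up tables are always monotonized, since their role is presentation.
* p-values below 1e-300 are clamped there by default (or rejected, per
  configuration): the estimator divides by counts and log-scale outputs need
  finite values.
* Ties in p-values need no tie-breaking: `<=` counting treats tied SNPs
  identically.
* Off-panel queries whose quadrant contains no observed SNP return 1, the
  most conservative value, with a warning.

## Enrichment diagnostics

Before conditioning is worth anything, the pleiotropic enrichment should be
visible. Three stratified diagnostics are computed over the nested strata
`p_j <= 1, 0.1, 0.01, 1e-3, 1e-4` (the `-log10(P) > 0 ... > 4` ladder):

* **Stratified Q-Q curves** plot nominal `-log10 p` against `-log10` of the
  empirical quantile `q(t)` (the proportion of stratum SNPs with
  `p_i <= t`). Under independence every curve sits on the identity; under
  enrichment the strict-stratum curves shift left (larger `q`, smaller
  `-log10 q`), with greater spacing indicating stronger enrichment.
* **Fold-enrichment curves** report `q_stratum(t) / q_all(t)`; the all-SNP
  stratum is identically 1, and points where `q_all(t) = 0` are reported as
  missing rather than infinite.
* **Conditional TDR curves** report `1 - cFDR(t | cutoff)`, the
  true-discovery-rate gain from conditioning, clipped to [0, 1].

Strata below 100 SNPs (configurable) are skipped: quantile estimates from
a few dozen points are noise. The nominal grid is 1,000 points equally
spaced in `-log10 p` over [0, 10], matching the resolution such plots are
drawn at. Genomic-control correction of the inputs is available
(`gc_correct`) but off by default, because the intended inputs are
meta-analysis files that arrive already GC-corrected; the lambda_GC of both
inputs is always estimated and logged as a diagnostic, using the chi-square
quantile transform with the chi-square(1) median fixed at 0.4549. No LD
pruning is applied before curve construction by default; the curves are
defined on marginal p-values.

## The synthetic cohort generator

Real use consumes consortium files; testing cannot. The generator draws,
per SNP, a component from a four-part mixture — null, trait-1-only,
trait-2-only, pleiotropic, with proportions `(pi0, pi1, pi2, pi12)` — and a
bivariate z-score: unit-variance noise with correlation `rho_null`
(a surrogate for cohort sample overlap, which shows up exactly as null
correlation in summary statistics), plus component-specific effects with
variances `sigma1_sq`, `sigma2_sq` and shared-effect correlation
`rho_pleio`. An optional `lambda_inflation >= 1` multiplies total variance,
emulating uncorrected population structure; the lambda_GC estimator recovers
it, which the tests verify. P-values are `2 * pnorm(-|z|)`.

Defaults — 1e5 SNPs over 22 chromosomes, `(0.97, 0.01, 0.01, 0.01)`,
`sigma^2 = 16`, `rho_pleio = 0.5`, `rho_null = 0` — are chosen once to
emulate a strongly genetically-correlated disease pair at a desk-testable
scale: about 3% of SNPs carry effects, a third of those on both traits, and
roughly a third of effect-bearing SNPs reach `p < 5e-8` (effect variance 16
puts the median non-null |z| near 2.8 and the upper tail well past 5.45).
`rho_null = 0` reflects the motivating datasets, whose ~1,100 shared
individuals out of cohorts of 70–90 thousand induce negligible correlation;
the parameter exists to study larger overlaps. The FDR-calibration study
(`analysis/05`) uses the sparser mixture `(0.979, 0.01, 0.01, 0.001)` so
that conditioning is tested where pleiotropy is rare rather than abundant.

A **replication cohort** is generated by passing the discovery run's truth
table back as `map`: the SNP panel, coordinates and mixture components are
reused and only cohort-level randomness — effect sizes and sampling noise —
is redrawn. Redrawing effects (rather than fixing them in the map) models
between-cohort heterogeneity; it makes synthetic replication somewhat harder
than a fixed-effects world and is the conservative choice. The generator is
bit-reproducible given a seed.

What the generator deliberately does not emulate: realistic LD structure
(an optional block-exchangeable noise mode exists solely to exercise
clumping — blocks of `B` consecutive SNPs with exchangeable correlation
`r` — and is not a genome LD map), allele-frequency-dependent power,
case/control ascertainment, and genome-calibrated SNP densities. Passing
tests on this generator therefore demonstrates correctness of the
estimators and control under the stated mixture model, not performance on
any particular real cohort, where LD-induced dependence between nearby
test statistics will make locus counts (not per-SNP estimates) the
meaningful unit.

## Loci and replication

Significant SNPs are reduced to independent loci by greedy clumping: the
most significant unassigned SNP seeds a locus and absorbs all unassigned
significant SNPs within a 1 Mb window on its chromosome (and with
`r2 >= r2_clump` to the lead when an LD table is supplied). Ties on the
statistic break by chromosome and position, making the procedure
deterministic; the assignment is a partition of the significant set.
Distance-only clumping is the default because no LD reference is bundled;
1 Mb is the conventional physical window for reporting independent GWAS
loci. When one principal trait is conditioned on two secondary phenotypes,
the two runs' hits are pooled, each SNP keeping its smaller statistic, and
the pooled set is clumped once (`union_clump`) — so the same region hit in
both runs counts as one locus.

A discovery locus is **replicated** when its lead SNP, or any SNP in high
LD with the lead (`r2 > 0.6`, strictly, and never across chromosomes),
passes the significance threshold in the replication analysis. Without an
LD table only exact-id matching is performed and the output says so. The
0.6 threshold is the conventional high-LD proxy criterion for treating two
markers as tagging the same signal.

## What the simulations show

The `analysis/` drivers and the acceptance script compute, at the problem
sizes above (1e5 SNPs; 20–50 simulation seeds, a scale chosen so the whole
study re-runs in minutes on one core):

* realised false-discovery proportion of conditional cFDR < 0.05
  declarations, averaged over seeds, against the 0.10 control bound;
* the count of true principal-trait discoveries under conditioning versus
  the unconditional empirical FDR at the same threshold, per seed;
* fold-enrichment ordering across the stratum ladder at `-log10 p = 4`,
  and flatness of the fold curves when `pi12 = 0` and `rho_null = 0`;
* locus and replication counts for the default pleiotropic architecture.

None of these numbers is asserted anywhere except where the tests and
`scripts/acceptance.R` compute them at run time.

## Known limitations

* The estimator is the raw empirical count-ratio; no kernel smoothing of
  the joint CDF is applied. Smoothing changes values in the sparse extreme
  tail where counts are small; the raw estimator is exactly reproducible
  and its conservative failure mode (returning values near 1 on empty
  quadrants) is the safe direction.
* Per-SNP cFDR values on LD-correlated panels are themselves correlated;
  error control should then be interpreted at the locus level.
* Sample overlap between cohorts is exposed as a generator parameter and
  checked diagnostically, but no analytic correction is applied to real
  inputs — the estimator inherits whatever null correlation the inputs
  carry, which inflates it anti-conservatively for large overlaps.
* Allele harmonisation is out of scope: only p-values are consumed, and
  the estimator is sign-free.
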