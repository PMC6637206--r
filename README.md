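# pleiocfdr

Pleiotropy-informed conditional false discovery rate (cFDR) analysis of two
GWAS summary-statistics sets.

Genome-wide association studies of genetically correlated traits — the
motivating pair is coronary artery disease and blood pressure — each leave
many true variants below the genome-wide significance threshold. When a
variant affects both traits, its p-value in one trait is evidence about the
other. The cFDR of a SNP is the posterior probability that it is null for
the principal trait given that the p-values of *both* traits are at or below
the observed pair:

    cFDR(p_i | p_j) = Pr(H0_i | P_i <= p_i, P_j <= p_j)
                    ≈ p_i · #{p_j' <= p_j} / #{p_i' <= p_i & p_j' <= p_j}

and the conjunctional cFDR, which flags SNPs shared by both traits, is

    ccFDR = max( cFDR(p_i | p_j), cFDR(p_j | p_i) ).

SNPs are declared at cFDR < 0.05 (the Manhattan-plot line at
−log10 = 1.3010). Conditioning at `p_j = 1` reduces the estimator exactly to
the Benjamini–Hochberg quantity `n·p/rank`, so the method strictly
generalises unconditional FDR control.

The package provides:

* **`read_sumstats` / `merge_on_snp`** — delimited-text readers with
  column-dialect mapping, validation, genomic-control diagnostics
  (`estimate_lambda_gc`, `apply_genomic_control`), and SNP-id merging;
* **`generate_pair`** — a four-component mixture simulator (null /
  trait-1-only / trait-2-only / pleiotropic) of paired z-scores with known
  ground truth, sample-overlap correlation, variance inflation, and
  independent replication cohorts on a shared SNP map;
* **`stratified_qq` / `fold_enrichment` / `stratified_tdr`** — the
  stratified enrichment diagnostics over the `p_j ≤ 1, 0.1, …, 1e-4` ladder;
* **`assign_cfdr` / `build_lookup_table` / `significant_set`** — exact
  per-SNP cFDR/ccFDR (O(n log n) dominance counting in C++) and the exported
  look-up tables;
* **`clump` / `replication_check`** — greedy 1 Mb locus clumping and the
  strict `r² > 0.6` high-LD proxy replication rule;
* **`run_discovery` / `run_replication`** — one-call orchestration writing
  all tables, Manhattan data and a JSON run manifest.

## Worked example

The `analysis/` scripts run the whole study on a synthetic 100,000-SNP panel
(97% null, 1% per-trait, 1% pleiotropic, effect variance 16):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_enrichment.R
Rscript analysis/03_cfdr_discovery.R
Rscript analysis/04_replication.R
Rscript analysis/05_fdr_calibration.R
```

`02` prints the fold enrichment of genome-wide-significant principal-trait
SNPs by conditioning stratum — the upward ordering that licenses
conditioning:

```
fold enrichment at p_i = 5e-8 by conditioning stratum:
   stratum  fold n_in_stratum
1:   1e+00   1.0       100000
2:   1e-01   4.2        11218
3:   1e-02  17.0         2065
4:   1e-03  30.0          991
5:   1e-04  35.5          743
```

`03` and `04` report discovery and replication (exact-id rule, since the
synthetic panel carries no LD reference):

```
SNPs significant at cFDR < 0.05:
  cfdr_i_given_j     991 SNPs  ->  832 independent loci
  cfdr_j_given_i    1069 SNPs  ->  890 independent loci
  ccfdr              359 SNPs  ->  336 independent loci

true false-discovery proportion of the ccFDR < 0.05 set: 0.056

loci replicated at cFDR < 0.05 in the independent cohort:
  cfdr_i_given_j    342 of  832
  cfdr_j_given_i    819 of  890
  ccfdr             165 of  336
```

(The conditioning trait's data is shared between the two arms, as when a
blood-pressure study is reused while the disease cohort is replaced, hence
its direction replicates almost completely.) `05` checks calibration: over
20 simulated panels with sparse signal, declaring at conditional
cFDR < 0.05 gave a mean realised false-discovery proportion of 0.063, and
conditioning matched or beat the unconditional FDR's true-discovery count
on 20 of 20 seeds (means 426.3 vs 413.9).

In code, the core loop is three calls:

```r
library(pleiocfdr)
pair   <- generate_pair(generator_config(seed = 1))
merged <- merge_on_snp(pair$trait1, pair$trait2)
res    <- assign_cfdr(merged)            # cfdr_i_given_j, cfdr_j_given_i, ccfdr
loci   <- clump(res, "ccfdr", alpha = 0.05, window_kb = 1000)
```

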