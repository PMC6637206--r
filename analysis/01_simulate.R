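#!/usr/bin/env Rscript
# Simulate the paired GWAS summary statistics the rest of the workflow
# analyses: a discovery cohort and an independent replication cohort measuring
# the same 100,000-SNP panel under the four-component pleiotropy mixture
# (97% null, 1% trait-1-only, 1% trait-2-only, 1% pleiotropic; effect
# variance 16, shared-effect correlation 0.5). Writes the TSVs that
# 02-04 read back through the standard reader.

suppressPackageStartupMessages(library(pleiocfdr))

seed <- 20260927L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

discovery_cfg <- generator_config(seed = seed)
discovery <- generate_pair(discovery_cfg)
write_pair(discovery, "results/data/discovery")

# same SNP panel and truth, fresh cohort-level effect and noise draws
replication_cfg <- generator_config(seed = seed + 1L)
replication <- generate_pair(replication_cfg, map = discovery$truth)
write_pair(replication, "results/data/replication")

comp <- table(discovery$truth$component)
cat("simulated", nrow(discovery$truth), "SNPs:\n")
print(comp)
cat("\nlambda_GC  trait 1:",
    round(estimate_lambda_gc(discovery$trait1)$lambda_gc, 3),
    "  trait 2:", round(estimate_lambda_gc(discovery$trait2)$lambda_gc, 3), "\n")
cat("genome-wide significant (p < 5e-8)  trait 1:",
    sum(discovery$trait1$pvalue < 5e-8),
    "  trait 2:", sum(discovery$trait2$pvalue < 5e-8), "\n")
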