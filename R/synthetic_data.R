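#' Configuration for the paired-trait summary-statistics simulator
#'
#' The simulator draws, for each SNP, a latent component from a four-part
#' mixture — null for both traits, trait-1-only, trait-2-only, or pleiotropic —
#' and then a bivariate z-score whose covariance is the unit-variance null part
#' (with optional correlation `rho_null`, a surrogate for shared samples
#' between cohorts) plus a component-specific effect part:
#' trait-1-only adds `sigma1_sq` to the first trait's variance, trait-2-only
#' adds `sigma2_sq` to the second, and pleiotropic SNPs add both plus a
#' cross-covariance `rho_pleio * sigma1 * sigma2`. An optional multiplicative
#' inflation `lambda_inflation` scales the total variance, mimicking the
#' genomic inflation uncorrected population structure produces. Two-sided
#' p-values are `2 * pnorm(-|z|)`.
#'
#' Defaults emulate a strongly genetically-correlated disease pair (in the
#' spirit of coronary artery disease and blood pressure) at a desk-scale panel
#' of 1e5 SNPs: 3% of SNPs carry an effect, a third of those on both traits,
#' with effect variance 16 (typical large-meta-analysis power: roughly a third
#' of pleiotropic SNPs reach p < 5e-8) and positively correlated shared
#' effects.
#'
#' @param n_snps number of SNPs.
#' @param pi0,pi1,pi2,pi12 mixture proportions (null, trait-1-only,
#'   trait-2-only, pleiotropic); must be nonnegative and sum to 1.
#' @param sigma1_sq,sigma2_sq non-null effect variances added to the unit
#'   noise variance.
#' @param rho_null correlation of the null z-score components, in `[0, 1)`;
#'   a sample-overlap surrogate.
#' @param rho_pleio correlation of pleiotropic effect sizes, in `[-1, 1]`.
#' @param lambda_inflation multiplicative variance inflation, `>= 1`.
#' @param n_chrom chromosomes the SNPs are spread over.
#' @param ld_block_size,ld_block_r optional block-exchangeable correlation of
#'   the null noise (one block = `ld_block_size` consecutive SNPs on a
#'   chromosome sharing pairwise correlation `ld_block_r`); off by default.
#'   This exists only to exercise locus clumping — it is not a realistic LD map.
#' @param seed RNG seed (mandatory for reproducible pipeline runs).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_snps = 1e5,
                             pi0 = 0.97, pi1 = 0.01, pi2 = 0.01, pi12 = 0.01,
                             sigma1_sq = 16, sigma2_sq = 16,
                             rho_null = 0, rho_pleio = 0.5,
                             lambda_inflation = 1,
                             n_chrom = 22,
                             ld_block_size = NULL, ld_block_r = 0,
                             seed = 1L) {
  props <- c(pi0, pi1, pi2, pi12)
  if (any(props < 0) || abs(sum(props) - 1) > 1e-12)
    stop("mixture proportions must be nonnegative and sum to 1", call. = FALSE)
  if (sigma1_sq < 0 || sigma2_sq < 0)
    stop("effect variances must be nonnegative", call. = FALSE)
  if (rho_null < 0 || rho_null >= 1)
    stop("rho_null must lie in [0, 1)", call. = FALSE)
  if (abs(rho_pleio) > 1)
    stop("rho_pleio must lie in [-1, 1]", call. = FALSE)
  if (lambda_inflation < 1)
    stop("lambda_inflation must be >= 1", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps),
                 pi0 = pi0, pi1 = pi1, pi2 = pi2, pi12 = pi12,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                 rho_null = rho_null, rho_pleio = rho_pleio,
                 lambda_inflation = lambda_inflation,
                 n_chrom = as.integer(n_chrom),
                 ld_block_size = ld_block_size, ld_block_r = ld_block_r,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a pair of summary-statistics sets with known ground truth
#'
#' See [generator_config()] for the model. SNP identifiers are synthetic
#' rs-style ids; positions are drawn uniformly over each chromosome and the
#' panel is returned sorted by (chrom, pos). Output is bit-identical for a
#' given seed.
#'
#' @param config a [generator_config()].
#' @param map optional truth table from a previous [generate_pair()] call
#'   (`snp_id`, `chrom`, `pos`, `component`). When supplied, the SNP panel
#'   and mixture components are reused and only cohort-level randomness
#'   (effect sizes and sampling noise) is redrawn — the synthetic analogue of
#'   measuring the same genome in an independent cohort, as a replication
#'   dataset does.
#' @return list with elements `trait1`, `trait2` (validated `sumstats` tables
#'   sharing `snp_id`, `chrom`, `pos`, with both `pvalue` and `zscore`) and
#'   `truth` (data.table: `snp_id`, `chrom`, `pos`, `component` in
#'   `{"null","trait1","trait2","pleiotropic"}`).
#' @export
generate_pair <- function(config, map = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  if (is.null(map)) {
    n <- config$n_snps
    component <- sample(c("null", "trait1", "trait2", "pleiotropic"), n,
                        replace = TRUE,
                        prob = c(config$pi0, config$pi1, config$pi2, config$pi12))
    # map: chromosome, position, ids (ids assigned in coordinate order)
    chrom <- sample.int(config$n_chrom, n, replace = TRUE)
    pos <- sample.int(2.4e8, n, replace = TRUE)
    ord <- order(chrom, pos, seq_len(n))
    chrom <- chrom[ord]; pos <- pos[ord]; component <- component[ord]
    snp_id <- sprintf("rs%08d", seq_len(n))
  } else {
    n <- nrow(map)
    snp_id <- map$snp_id; chrom <- map$chrom
    pos <- map$pos; component <- map$component
  }

  # null (noise) part: unit variance, correlation rho_null across traits
  if (!is.null(config$ld_block_size) && config$ld_block_r > 0) {
    B <- as.integer(config$ld_block_size)
    r <- config$ld_block_r
    ch <- chrom_order(as.character(chrom))
    block <- cumsum(c(TRUE, diff(ch) != 0 | (seq_len(n)[-1] %% B) == 1L))
    u1 <- stats::rnorm(max(block))[block]
    u2 <- stats::rnorm(max(block))[block]
    e1 <- sqrt(r) * u1 + sqrt(1 - r) * stats::rnorm(n)
    e2 <- sqrt(r) * u2 + sqrt(1 - r) * stats::rnorm(n)
  } else {
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
  }
  rho <- config$rho_null
  z1 <- e1
  z2 <- rho * e1 + sqrt(1 - rho^2) * e2

  # effect part by component
  s1 <- sqrt(config$sigma1_sq); s2 <- sqrt(config$sigma2_sq)
  i1 <- component == "trait1"
  i2 <- component == "trait2"
  ip <- component == "pleiotropic"
  if (any(i1)) z1[i1] <- z1[i1] + s1 * stats::rnorm(sum(i1))
  if (any(i2)) z2[i2] <- z2[i2] + s2 * stats::rnorm(sum(i2))
  if (any(ip)) {
    np <- sum(ip)
    g1 <- stats::rnorm(np); g2 <- stats::rnorm(np)
    rp <- config$rho_pleio
    b1 <- s1 * g1
    b2 <- s2 * (rp * g1 + sqrt(1 - rp^2) * g2)
    z1[ip] <- z1[ip] + b1
    z2[ip] <- z2[ip] + b2
  }

  if (config$lambda_inflation > 1) {
    z1 <- z1 * sqrt(config$lambda_inflation)
    z2 <- z2 * sqrt(config$lambda_inflation)
  }

  mk <- function(z) {
    validate_sumstats(
      data.table::data.table(snp_id = snp_id, chrom = as.character(chrom),
                             pos = pos, pvalue = 2 * stats::pnorm(-abs(z)),
                             zscore = z),
      source = "synthetic")
  }
  list(trait1 = mk(z1), trait2 = mk(z2),
       truth = data.table::data.table(snp_id = snp_id,
                                      chrom = as.character(chrom), pos = pos,
                                      component = component))
}

#' Write a generated pair to disk in the pipeline's TSV dialect
#'
#' @param pair result of [generate_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trait1 = file.path(dir, "trait1.tsv"),
             trait2 = file.path(dir, "trait2.tsv"),
             truth = file.path(dir, "truth.tsv"))
  data.table::fwrite(pair$trait1, paths["trait1"], sep = "\t")
  data.table::fwrite(pair$trait2, paths["trait2"], sep = "\t")
  data.table::fwrite(pair$truth, paths["truth"], sep = "\t")
  invisible(paths)
}

#' True false-discovery proportion of a declared SNP set
#'
#' Evaluates a declared significant set against the generator's ground truth:
#' the fraction of declared SNPs that are truly null for the stated trait.
#' For trait 1 the null holds unless the component is `trait1` or
#' `pleiotropic`; symmetrically for trait 2; for the conjunction the null
#' holds unless the component is `pleiotropic`.
#'
#' @param declared character vector of declared snp_ids (may be empty).
#' @param truth the `truth` table from [generate_pair()].
#' @param trait one of `"trait1"`, `"trait2"`, `"conjunction"`.
#' @return the false-discovery proportion in `[0, 1]`; 0 for an empty set.
#' @export
truth_fdp <- function(declared, truth, trait = c("trait1", "trait2", "conjunction")) {
  trait <- match.arg(trait)
  if (length(declared) == 0L) return(0)
  idx <- match(declared, truth$snp_id)
  if (anyNA(idx))
    stop("declared set contains unknown snp_id(s): ",
         paste(utils::head(declared[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  comp <- truth$component[idx]
  h0 <- switch(trait,
               trait1 = !(comp %in% c("trait1", "pleiotropic")),
               trait2 = !(comp %in% c("trait2", "pleiotropic")),
               conjunction = comp != "pleiotropic")
  mean(h0)
}
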