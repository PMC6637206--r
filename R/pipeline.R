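#' Configuration for a full discovery/replication run
#'
#' Either file-based (paths plus dialects for the principal, conditioning and
#' optional replication summary files) or synthetic (generator configs for a
#' discovery pair and optionally a replication pair sharing the SNP panel).
#'
#' @param principal,conditioning,replication file paths (file mode) or NULL.
#' @param dialect a [sumstats_dialect()] shared by the input files.
#' @param generator,generator_replication [generator_config()]s for synthetic
#'   mode; `generator_replication` defaults to the discovery generator with a
#'   shifted seed, mimicking an independent cohort of the same architecture.
#' @param strata a [stratum_spec()].
#' @param alpha significance threshold; default 0.05.
#' @param window_kb clump window in kb; default 1000.
#' @param ld_path optional LD-table TSV path.
#' @param gc_correct apply genomic-control correction to the inputs before
#'   analysis; default FALSE (the study's source files arrive GC-corrected).
#' @param out_dir output directory for tables and the run manifest.
#' @param seed run seed (also forwarded to the generators when they carry
#'   none of their own).
#' @return a `run_config` list.
#' @export
run_config <- function(principal = NULL, conditioning = NULL, replication = NULL,
                       dialect = sumstats_dialect(),
                       generator = NULL, generator_replication = NULL,
                       strata = stratum_spec(), alpha = 0.05,
                       window_kb = 1000, ld_path = NULL, gc_correct = FALSE,
                       out_dir = tempfile("pleiocfdr_run_"), seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  synthetic <- !is.null(generator)
  if (!synthetic && (is.null(principal) || is.null(conditioning)))
    stop("provide either file paths or a generator config", call. = FALSE)
  if (synthetic && is.null(generator_replication)) {
    generator_replication <- generator
    generator_replication$seed <- generator$seed + 10000L
  }
  structure(list(principal = principal, conditioning = conditioning,
                 replication = replication, dialect = dialect,
                 generator = generator,
                 generator_replication = generator_replication,
                 strata = strata, alpha = alpha, window_kb = window_kb,
                 ld_path = ld_path, gc_correct = gc_correct,
                 out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic),
            class = "run_config")
}

# -log10 threshold line drawn on Manhattan plots for alpha
neglog_threshold <- function(alpha) -log10(alpha)

manhattan_table <- function(results, field, alpha) {
  data.table::data.table(
    snp_id = results$snp_id, chrom = results$chrom, pos = results$pos,
    neglog10 = -log10(results[[field]]),
    above_threshold = results[[field]] < alpha)
}

#' Run the discovery arm of the workflow
#'
#' Loads (or generates) the two summary-statistics sets, merges them, builds
#' the enrichment diagnostics (stratified Q-Q, fold-enrichment, conditional
#' TDR), computes per-SNP cFDR in both directions plus the ccFDR, exports
#' the two directional look-up tables, writes conditional and conjunctional
#' Manhattan tables annotated with the `-log10(alpha)` line (1.3010 at the
#' default 0.05), and clumps significant SNPs into independent loci.
#'
#' All tables land under `config$out_dir`; every stage logs its counts into
#' the returned bundle and the JSON run manifest.
#'
#' @param config a [run_config()].
#' @return invisible list (`discovery_bundle`): `merged`, `results`, `loci`
#'   (per statistic), `curves`, `truth` (synthetic mode), `counts`, `paths`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  if (config$synthetic) {
    pair <- generate_pair(config$generator)
    principal <- pair$trait1; conditioning <- pair$trait2; truth <- pair$truth
  } else {
    principal <- read_sumstats(config$principal, config$dialect)
    conditioning <- read_sumstats(config$conditioning, config$dialect)
    truth <- NULL
  }
  counts$n_principal <- nrow(principal)
  counts$n_conditioning <- nrow(conditioning)

  gc_i <- estimate_lambda_gc(principal)
  gc_j <- estimate_lambda_gc(conditioning)
  counts$lambda_gc_principal <- gc_i$lambda_gc
  counts$lambda_gc_conditioning <- gc_j$lambda_gc
  if (config$gc_correct) {
    principal <- apply_genomic_control(principal, gc_i$lambda_gc)
    conditioning <- apply_genomic_control(conditioning, gc_j$lambda_gc)
  }

  merged <- merge_on_snp(principal, conditioning)
  counts$n_merged <- nrow(merged)

  curves <- list(qq = stratified_qq(merged, config$strata),
                 fold = fold_enrichment(merged, config$strata),
                 tdr = stratified_tdr(merged, config$strata))
  counts$stratum_sizes <- unique(curves$qq[, .(stratum, n_in_stratum)])

  results <- assign_cfdr(merged)
  for (f in c("cfdr_i_given_j", "cfdr_j_given_i", "ccfdr"))
    counts[[paste0("n_sig_", f)]] <- length(significant_set(results, f, config$alpha))

  swapped <- data.table::copy(merged)
  data.table::setnames(swapped, c("p_i", "p_j"), c("p_j", "p_i"))
  tab_ij <- monotonize(build_lookup_table(merged))
  tab_ji <- monotonize(build_lookup_table(swapped))

  ld <- if (!is.null(config$ld_path)) read_ld_table(config$ld_path) else NULL
  loci <- lapply(stats::setNames(nm = c("cfdr_i_given_j", "cfdr_j_given_i", "ccfdr")),
                 function(f) clump(results, f, config$alpha, config$window_kb, ld))
  counts$n_loci <- vapply(loci, nrow, integer(1))

  paths <- write_discovery_bundle(config, merged, curves, results,
                                  tab_ij, tab_ji, loci, counts)
  invisible(list(merged = merged, results = results, curves = curves,
                 loci = loci, truth = truth, ld = ld,
                 counts = counts, paths = paths, config = config))
}

write_discovery_bundle <- function(config, merged, curves, results,
                                   tab_ij, tab_ji, loci, counts) {
  od <- config$out_dir
  paths <- list()
  for (nm in names(curves)) {
    paths[[nm]] <- file.path(od, paste0(nm, "_curves.tsv"))
    data.table::fwrite(curves[[nm]], paths[[nm]], sep = "\t")
  }
  paths$per_snp <- file.path(od, "per_snp_cfdr.tsv")
  out <- data.table::copy(results)
  for (col in c("p_i", "p_j", "cfdr_i_given_j", "cfdr_j_given_i", "ccfdr"))
    out[[col]] <- format_sci(out[[col]])
  data.table::fwrite(out, paths$per_snp, sep = "\t")

  paths$lookup_ij <- write_lookup_table(tab_ij, file.path(od, "cfdr_table_i_given_j.tsv"))
  paths$lookup_ji <- write_lookup_table(tab_ji, file.path(od, "cfdr_table_j_given_i.tsv"))

  paths$manhattan_conditional <- file.path(od, "manhattan_conditional.tsv")
  data.table::fwrite(manhattan_table(results, "cfdr_i_given_j", config$alpha),
                     paths$manhattan_conditional, sep = "\t")
  paths$manhattan_conjunction <- file.path(od, "manhattan_conjunction.tsv")
  data.table::fwrite(manhattan_table(results, "ccfdr", config$alpha),
                     paths$manhattan_conjunction, sep = "\t")

  for (f in names(loci)) {
    paths[[paste0("loci_", f)]] <- file.path(od, paste0("loci_", f, ".tsv"))
    write_loci(loci[[f]], paths[[paste0("loci_", f)]])
  }

  paths$manifest <- file.path(od, "run_manifest.json")
  manifest <- list(alpha = config$alpha,
                   neglog10_threshold = round(neglog_threshold(config$alpha), 4),
                   strata = config$strata$thresholds,
                   window_kb = config$window_kb, seed = config$seed,
                   synthetic = config$synthetic,
                   counts = counts[!vapply(counts, is.data.frame, logical(1))])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  paths
}

#' Run the replication arm and cross-check discovery loci
#'
#' Repeats the cFDR analysis with the replication principal dataset against
#' the same conditioning trait, then applies the LD-proxy replication rule
#' ([replication_check()]) to the discovery loci of each statistic.
#'
#' @param config the [run_config()] used for discovery.
#' @param discovery_bundle return value of [run_discovery()].
#' @return invisible list: `results` (replication per-SNP cFDR), `status`
#'   (per-locus replication tables keyed by statistic), `summary` (counts of
#'   replicated loci), `paths`.
#' @export
run_replication <- function(config, discovery_bundle) {
  stopifnot(inherits(config, "run_config"))
  if (config$synthetic) {
    # same SNP panel and truth as discovery, independent cohort-level draws
    pair <- generate_pair(config$generator_replication,
                          map = discovery_bundle$truth)
    principal <- pair$trait1; conditioning <- pair$trait2
  } else {
    if (is.null(config$replication))
      stop("no replication dataset configured", call. = FALSE)
    principal <- read_sumstats(config$replication, config$dialect)
    conditioning <- read_sumstats(config$conditioning, config$dialect)
  }
  merged <- merge_on_snp(principal, conditioning)
  overlap <- mean(discovery_bundle$merged$snp_id %in% merged$snp_id)
  if (overlap < 0.5)
    warning(sprintf("only %.1f%% of discovery SNPs present in replication panel",
                    100 * overlap), call. = FALSE)
  results <- assign_cfdr(merged)

  status <- lapply(names(discovery_bundle$loci), function(f) {
    replication_check(discovery_bundle$loci[[f]], results, f,
                      alpha = config$alpha, ld = discovery_bundle$ld)
  })
  names(status) <- names(discovery_bundle$loci)
  summary <- vapply(status, function(s) sum(s$replicated), integer(1))

  paths <- list()
  for (f in names(status)) {
    paths[[f]] <- file.path(config$out_dir, paste0("replication_", f, ".tsv"))
    write_loci(status[[f]], paths[[f]])
  }
  invisible(list(results = results, status = status, summary = summary,
                 paths = paths))
}

#' Union-then-clump bookkeeping for several conditioning runs
#'
#' When a principal trait is conditioned on more than one secondary trait
#' (e.g. two blood-pressure phenotypes), the per-run significant SNPs are
#' pooled, each SNP keeps its smallest statistic across runs, and the pooled
#' set is clumped once — so overlapping hits from the two runs collapse into
#' one independent locus.
#'
#' @param results_list list of `cfdr_result` tables sharing an id space.
#' @param field,alpha,window_kb,ld,r2_clump as in [clump()].
#' @return a `locus_set` over the pooled significant SNPs.
#' @export
union_clump <- function(results_list,
                        field = c("ccfdr", "cfdr_i_given_j", "cfdr_j_given_i"),
                        alpha = 0.05, window_kb = 1000, ld = NULL,
                        r2_clump = 0.1) {
  field <- match.arg(field)
  pooled <- data.table::rbindlist(lapply(results_list, data.table::as.data.table))
  pooled <- pooled[order(pooled[[field]])]
  pooled <- pooled[!duplicated(snp_id)]
  clump(pooled, field, alpha, window_kb, ld, r2_clump)
}
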