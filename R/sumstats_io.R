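#' @useDynLib pleiocfdr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# median of the chi-square(1 df) distribution, fixed to 4 decimals
CHISQ1_MEDIAN <- 0.4549

# smallest p-value retained; smaller values are clamped (or the row rejected)
P_FLOOR <- 1e-300

#' Column dialect for a summary-statistics file
#'
#' Maps source column names onto the fields the pipeline uses. GWAS consortia
#' release summary statistics under many header conventions; a dialect names
#' the columns holding the SNP identifier, chromosome, base-pair position and
#' two-sided association p-value (optionally a signed z-score).
#'
#' @param snp_id,chrom,pos,pvalue source column names (required).
#' @param zscore optional source column holding a signed normal deviate; when
#'   present, rows where `2*pnorm(-|z|)` disagrees with `pvalue` by more than
#'   `1e-6` relative are dropped on load.
#' @return a `sumstats_dialect` list.
#' @export
sumstats_dialect <- function(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                             pvalue = "pvalue", zscore = NULL) {
  d <- list(snp_id = snp_id, chrom = chrom, pos = pos,
            pvalue = pvalue, zscore = zscore)
  for (f in c("snp_id", "chrom", "pos", "pvalue"))
    if (!is.character(d[[f]]) || length(d[[f]]) != 1L)
      stop("dialect field '", f, "' must be a single column name", call. = FALSE)
  structure(d, class = "sumstats_dialect")
}

#' Read and validate one GWAS summary-statistics file
#'
#' Reads a delimited text file with header (separator sniffed by
#' [data.table::fread()]), renames columns per the dialect, and validates:
#' p-values must lie in (0, 1] after the sub-minimal clamp, positions must be
#' positive integers, chromosome labels are normalised by stripping a "chr"
#' prefix. Rows failing validation are dropped and counted; duplicated SNP
#' identifiers keep the smallest p-value (conservative and deterministic).
#'
#' @param path file path to delimited text with a header row.
#' @param dialect a [sumstats_dialect()]; defaults to the package's own column
#'   names (`snp_id`, `chrom`, `pos`, `pvalue`).
#' @param zero_policy `"clamp"` replaces p below `1e-300` (including exact
#'   zeros) by `1e-300`; `"reject"` drops such rows.
#' @param autosomes_only drop non-autosomal chromosomes (X, Y, MT); default TRUE.
#' @return a `data.table` of class `sumstats` with columns
#'   `snp_id`, `chrom`, `pos`, `pvalue` (and `zscore` if mapped), ordered by
#'   (chrom, pos). The number of rows dropped at each step is recorded in
#'   `attr(, "log")`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          zero_policy = c("clamp", "reject"),
                          autosomes_only = TRUE) {
  zero_policy <- match.arg(zero_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, data.table = TRUE)
  cols <- unlist(dialect[!vapply(dialect, is.null, logical(1))])
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt <- raw[, cols, with = FALSE]
  data.table::setnames(dt, cols, names(dialect)[!vapply(dialect, is.null, logical(1))])
  validate_sumstats(dt, zero_policy = zero_policy, autosomes_only = autosomes_only,
                    source = path)
}

#' Validate an in-memory summary-statistics table
#'
#' Same validation as [read_sumstats()] applied to a data.frame already in
#' memory (e.g. from the synthetic generator or a unit test).
#'
#' @inheritParams read_sumstats
#' @param dt data.frame with columns `snp_id`, `chrom`, `pos`, `pvalue`
#'   (optionally `zscore`).
#' @param source label used in messages.
#' @return validated `sumstats` data.table; see [read_sumstats()].
#' @export
validate_sumstats <- function(dt, zero_policy = c("clamp", "reject"),
                              autosomes_only = TRUE, source = "input") {
  zero_policy <- match.arg(zero_policy)
  dt <- data.table::as.data.table(dt)
  n0 <- nrow(dt)
  log <- list(n_input = n0)

  dt[, snp_id := as.character(snp_id)]
  dt[, chrom := sub("^chr", "", as.character(chrom), ignore.case = TRUE)]
  suppressWarnings(dt[, pos := as.integer(pos)])
  suppressWarnings(dt[, pvalue := as.numeric(pvalue)])

  if (autosomes_only) {
    keep <- dt$chrom %in% as.character(1:22)
    log$n_non_autosomal <- sum(!keep)
    dt <- dt[keep]
  }

  bad_pos <- is.na(dt$pos) | dt$pos < 1L
  log$n_bad_position <- sum(bad_pos)
  dt <- dt[!bad_pos]

  if (zero_policy == "clamp") {
    n_clamped <- sum(!is.na(dt$pvalue) & dt$pvalue < P_FLOOR & dt$pvalue >= 0)
    dt[!is.na(pvalue) & pvalue < P_FLOOR & pvalue >= 0, pvalue := P_FLOOR]
    log$n_clamped <- n_clamped
  }
  bad_p <- is.na(dt$pvalue) | dt$pvalue < P_FLOOR | dt$pvalue > 1
  log$n_bad_pvalue <- sum(bad_p)
  dt <- dt[!bad_p]

  if ("zscore" %in% names(dt)) {
    suppressWarnings(dt[, zscore := as.numeric(zscore)])
    pz <- 2 * stats::pnorm(-abs(dt$zscore))
    inconsistent <- !is.na(dt$zscore) &
      abs(pz - dt$pvalue) > 1e-6 * pmax(dt$pvalue, pz)
    log$n_z_inconsistent <- sum(inconsistent)
    dt <- dt[!inconsistent]
  }

  # duplicate ids keep the smallest p-value
  data.table::setorder(dt, snp_id, pvalue)
  dup <- duplicated(dt$snp_id)
  log$n_duplicate_id <- sum(dup)
  dt <- dt[!dup]

  if (nrow(dt) == 0L)
    stop("no rows of ", source, " survived validation", call. = FALSE)
  log$n_retained <- nrow(dt)
  if (n0 > nrow(dt))
    message(sprintf("%s: retained %d of %d rows (%d dropped)",
                    source, nrow(dt), n0, n0 - nrow(dt)))

  data.table::setorderv(dt[, .ord := chrom_order(chrom)], c(".ord", "pos"))
  dt[, .ord := NULL]
  data.table::setattr(dt, "log", log)
  data.table::setattr(dt, "class", unique(c("sumstats", class(dt))))
  dt[]
}

# numeric sort key for chromosome labels (1..22 then X, Y, MT)
chrom_order <- function(chrom) {
  suppressWarnings(k <- as.integer(chrom))
  k[chrom %in% "X"] <- 23L
  k[chrom %in% "Y"] <- 24L
  k[chrom %in% c("MT", "M")] <- 25L
  k[is.na(k)] <- 26L
  k
}

#' Estimate the genomic-inflation factor lambda_GC
#'
#' Converts p-values to 1-df chi-square deviates by the quantile transform and
#' divides their median by 0.4549, the median of the chi-square(1)
#' distribution. Under a well-calibrated null, lambda is 1; population
#' stratification or cryptic relatedness inflates it above 1.
#'
#' @param stats a `sumstats` table (or anything with a `pvalue` column).
#' @return list of class `gc_report`: `lambda_gc`, `n_snps`, `applied = FALSE`.
#' @export
estimate_lambda_gc <- function(stats) {
  p <- stats$pvalue
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p <= 0)) stop("p-values must be positive for lambda estimation",
                        call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  structure(list(lambda_gc = stats::median(chisq) / CHISQ1_MEDIAN,
                 n_snps = length(p), applied = FALSE),
            class = "gc_report")
}

#' Apply genomic-control correction to p-values
#'
#' Divides the implied 1-df chi-square statistic of every SNP by `lambda_gc`
#' and maps back to a tail probability. For lambda > 1 corrected p-values are
#' larger (more conservative); lambda below 1 leaves the input unchanged. The
#' transform is strictly monotone, so the ranking of SNPs is preserved.
#'
#' The study's source datasets arrive already GC-corrected, so the pipeline
#' never applies this by default; it is exposed for diagnostics and for
#' inflated synthetic panels.
#'
#' @param stats a `sumstats` table.
#' @param lambda_gc inflation factor, typically from [estimate_lambda_gc()].
#' @return a `sumstats` table with corrected `pvalue`.
#' @export
apply_genomic_control <- function(stats, lambda_gc) {
  stopifnot(is.numeric(lambda_gc), length(lambda_gc) == 1L, lambda_gc > 0)
  out <- data.table::copy(data.table::as.data.table(stats))
  if (lambda_gc > 1) {
    chisq <- stats::qchisq(out$pvalue, df = 1, lower.tail = FALSE)
    out[, pvalue := stats::pchisq(chisq / lambda_gc, df = 1, lower.tail = FALSE)]
    out[pvalue > 1, pvalue := 1]
  }
  data.table::setattr(out, "class", c("sumstats", class(data.table::data.table())))
  out[]
}

#' Merge two summary-statistics sets on shared SNP identifiers
#'
#' Inner join on `snp_id`: only SNPs present in both inputs are retained. The
#' principal trait supplies coordinates and its p-value becomes `p_i`; the
#' conditioning trait's p-value becomes `p_j`. The result is ordered by
#' (chrom, pos), and intersection / exclusion counts are logged.
#'
#' @param principal,conditioning validated `sumstats` tables.
#' @return a `data.table` of class `merged_stats` with columns `snp_id`,
#'   `chrom`, `pos`, `p_i`, `p_j`; counts in `attr(, "log")`.
#' @export
merge_on_snp <- function(principal, conditioning) {
  a <- data.table::as.data.table(principal)
  b <- data.table::as.data.table(conditioning)
  m <- merge(a[, .(snp_id, chrom, pos, p_i = pvalue)],
             b[, .(snp_id, p_j = pvalue)],
             by = "snp_id")
  if (nrow(m) == 0L)
    stop("no SNPs shared between the two datasets", call. = FALSE)
  data.table::setorderv(m[, .ord := chrom_order(chrom)], c(".ord", "pos"))
  m[, .ord := NULL]
  log <- list(n_principal = nrow(a), n_conditioning = nrow(b),
              n_shared = nrow(m),
              n_principal_only = nrow(a) - nrow(m),
              n_conditioning_only = nrow(b) - nrow(m))
  message(sprintf("merged: %d shared SNPs (%d principal-only, %d conditioning-only dropped)",
                  log$n_shared, log$n_principal_only, log$n_conditioning_only))
  data.table::setattr(m, "log", log)
  data.table::setattr(m, "class", c("merged_stats", class(m)))
  m[]
}

#' Write a merged table as TSV
#'
#' @param merged a `merged_stats` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_merged <- function(merged, path) {
  data.table::fwrite(merged[, .(snp_id, chrom, pos, p_i, p_j)], path, sep = "\t")
  invisible(path)
}
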