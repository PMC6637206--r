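# count of values <= each threshold (ties counted, <= convention throughout)
count_leq <- function(values, thresholds) {
  findInterval(thresholds, sort(values))
}

#' Empirical conditional false discovery rate at query points
#'
#' The cFDR of the principal trait at `(p_i*, p_j*)` is the posterior
#' probability that a SNP is null for the principal trait given that both
#' p-values are at or below the observed pair. Its empirical-Bayes estimate
#' from the joint empirical CDF of the panel is
#'
#'   `cFDR(p_i* | p_j*) = p_i* * N(p_j <= p_j*) / N(p_i <= p_i* & p_j <= p_j*)`
#'
#' capped at 1 (it estimates a probability). Counts use `<=`, so a query at
#' an observed SNP includes the SNP itself and the denominator is at least 1.
#' Off-panel queries with an empty denominator return 1 — the most
#' conservative value — with a warning.
#'
#' @param merged a `merged_stats` table.
#' @param p_i_star,p_j_star query p-values in (0, 1], recycled to a common
#'   length.
#' @return numeric vector of cFDR estimates in (0, 1].
#' @export
empirical_cfdr <- function(merged, p_i_star, p_j_star) {
  stopifnot(nrow(merged) > 0)
  q <- data.table::data.table(a = p_i_star, b = p_j_star) # recycles
  if (any(q$a <= 0 | q$a > 1 | q$b <= 0 | q$b > 1))
    stop("query p-values must lie in (0, 1]", call. = FALSE)
  n_j <- count_leq(merged$p_j, q$b)
  n_ij <- mapply(function(a, b) sum(merged$p_i <= a & merged$p_j <= b),
                 q$a, q$b)
  if (any(n_ij == 0))
    warning("query point(s) dominate no observed SNP; returning cFDR = 1",
            call. = FALSE)
  # ratio computed first so a ratio of exactly 1 leaves the p-value untouched
  ifelse(n_ij > 0, pmin(1, q$a * (n_j / n_ij)), 1)
}

#' Build a cFDR look-up table over threshold grids
#'
#' Evaluates the empirical cFDR estimator at every pair of grid thresholds,
#' giving the 2-D look-up table the original method exports for each
#' conditioning direction. Joint counts come from a binned 2-D cumulative
#' histogram, so every cell equals the pointwise [empirical_cfdr()] value
#' exactly.
#'
#' @param merged a `merged_stats` table.
#' @param pi_grid,pj_grid threshold grids in (0, 1] for the principal and
#'   conditioning p-values.
#' @return a `cfdr_table` list: `pi_grid`, `pj_grid` (as given), `values`
#'   matrix (rows = `pi_grid`, columns = `pj_grid`), `monotonized = FALSE`.
#' @export
build_lookup_table <- function(merged,
                               pi_grid = 10^(-seq(0, 8, by = 0.1)),
                               pj_grid = 10^(-seq(0, 8, by = 0.1))) {
  stopifnot(nrow(merged) > 0)
  if (length(pi_grid) == 0 || length(pj_grid) == 0)
    stop("threshold grids must be non-empty", call. = FALSE)
  if (any(pi_grid <= 0 | pi_grid > 1) || any(pj_grid <= 0 | pj_grid > 1))
    stop("grid thresholds must lie in (0, 1]", call. = FALSE)

  ug_i <- sort(unique(pi_grid))
  ug_j <- sort(unique(pj_grid))
  # bin index = number of unique thresholds strictly below the value, so
  # value <= ug[k] iff bin <= k - 1
  bi <- findInterval(merged$p_i, ug_i, left.open = TRUE)
  bj <- findInterval(merged$p_j, ug_j, left.open = TRUE)
  tab <- matrix(0, nrow = length(ug_i) + 1L, ncol = length(ug_j) + 1L)
  counts <- table(factor(bi, levels = 0:length(ug_i)),
                  factor(bj, levels = 0:length(ug_j)))
  tab[] <- as.numeric(counts)
  cum <- apply(apply(tab, 2, cumsum), 1, cumsum)  # transposed double cumsum
  # n_ij[r, c] = #{p_i <= ug_i[r] & p_j <= ug_j[c]}
  n_ij_u <- t(cum)[seq_along(ug_i), seq_along(ug_j), drop = FALSE]
  n_j_u <- count_leq(merged$p_j, ug_j)

  ri <- match(pi_grid, ug_i)
  rj <- match(pj_grid, ug_j)
  n_ij <- n_ij_u[ri, rj, drop = FALSE]
  vals <- matrix(1, nrow = length(pi_grid), ncol = length(pj_grid))
  for (c in seq_along(pj_grid)) {
    ok <- n_ij[, c] > 0
    vals[ok, c] <- pmin(1, pi_grid[ok] * (n_j_u[rj[c]] / n_ij[ok, c]))
  }
  dimnames(vals) <- list(format(pi_grid, scientific = TRUE, digits = 4),
                         format(pj_grid, scientific = TRUE, digits = 4))
  structure(list(pi_grid = pi_grid, pj_grid = pj_grid, values = vals,
                 monotonized = FALSE),
            class = "cfdr_table")
}

#' Monotonize a cFDR look-up table
#'
#' Within each conditioning column, replaces every cell by the minimum over
#' itself and all cells at larger principal p-values (a suffix-minimum scan
#' from least to most significant p_i), so that a more significant p_i never
#' carries a larger cFDR. This is the same regularisation step that turns
#' `n * p / rank` into Benjamini-Hochberg adjusted p-values.
#'
#' @param table a `cfdr_table`.
#' @return the table with monotone columns and `monotonized = TRUE`.
#' @export
monotonize <- function(table) {
  stopifnot(inherits(table, "cfdr_table"))
  ord <- order(table$pi_grid)  # increasing p_i
  vals <- table$values
  for (c in seq_len(ncol(vals))) {
    v <- vals[ord, c]
    vals[ord, c] <- rev(cummin(rev(v)))
  }
  table$values <- vals
  table$monotonized <- TRUE
  table
}

#' Monotonize per-SNP statistics along ranked p-values
#'
#' Suffix-minimum of `values` in order of increasing `p`, i.e. each SNP's
#' statistic becomes the smallest statistic among SNPs with p-values at least
#' as large; identical to the Benjamini-Hochberg step-up regularisation.
#' Returned in the original SNP order.
#'
#' @param values statistic vector (e.g. raw per-SNP cFDR).
#' @param p the p-values that rank the SNPs.
#' @return monotonized vector, same order as the input.
#' @export
monotonize_values <- function(values, p) {
  stopifnot(length(values) == length(p))
  ord <- order(p)
  out <- values
  out[ord] <- rev(cummin(rev(values[ord])))
  out
}

#' Per-SNP cFDR in both conditioning directions and the conjunctional cFDR
#'
#' For every SNP of the merged panel, evaluates the empirical cFDR of trait i
#' given trait j at the SNP's own p-value pair, the reverse direction with
#' the roles swapped, and the conjunctional cFDR
#' `ccFDR = max(cFDR_i|j, cFDR_j|i)` — the posterior probability the SNP is
#' null for at least one of the two traits. Joint counts are exact (an
#' O(n log n) Fenwick-tree dominance count at the observed points), not grid
#' interpolations.
#'
#' @param merged a `merged_stats` table.
#' @param monotonize_snps if TRUE, each directional cFDR is additionally
#'   regularised by [monotonize_values()] along its own ranked p-value within
#'   conditioning-trait strata of the default ladder; default FALSE (raw
#'   estimator values, reproducible unambiguously).
#' @return `data.table` of class `cfdr_result`: `snp_id`, `chrom`, `pos`,
#'   `p_i`, `p_j`, `cfdr_i_given_j`, `cfdr_j_given_i`, `ccfdr`.
#' @export
assign_cfdr <- function(merged, monotonize_snps = FALSE) {
  stopifnot(nrow(merged) > 0)
  n <- nrow(merged)
  n_ij <- joint_dominance_count(merged$p_i, merged$p_j)
  n_j <- count_leq(merged$p_j, merged$p_j)
  n_i <- count_leq(merged$p_i, merged$p_i)
  cfdr_ij <- pmin(1, merged$p_i * (n_j / n_ij))
  cfdr_ji <- pmin(1, merged$p_j * (n_i / n_ij))
  if (monotonize_snps) {
    strat <- stratum_spec()$thresholds
    bin_j <- cut(merged$p_j, breaks = c(0, rev(strat)), labels = FALSE)
    bin_i <- cut(merged$p_i, breaks = c(0, rev(strat)), labels = FALSE)
    for (b in unique(bin_j)) {
      k <- bin_j == b
      cfdr_ij[k] <- monotonize_values(cfdr_ij[k], merged$p_i[k])
    }
    for (b in unique(bin_i)) {
      k <- bin_i == b
      cfdr_ji[k] <- monotonize_values(cfdr_ji[k], merged$p_j[k])
    }
  }
  out <- data.table::data.table(
    snp_id = merged$snp_id, chrom = merged$chrom, pos = merged$pos,
    p_i = merged$p_i, p_j = merged$p_j,
    cfdr_i_given_j = cfdr_ij, cfdr_j_given_i = cfdr_ji,
    ccfdr = pmax(cfdr_ij, cfdr_ji))
  data.table::setattr(out, "class", unique(c("cfdr_result", class(out))))
  out[]
}

#' Unconditional empirical FDR of one p-value vector
#'
#' The degenerate case of the cFDR estimator with the conditioning threshold
#' at 1: `p * n / rank(p)`, the raw Benjamini-Hochberg-style quantity, capped
#' at 1. With `monotone = TRUE` it is regularised to the usual BH-adjusted
#' p-values.
#'
#' @param p p-value vector in (0, 1].
#' @param monotone apply the step-up suffix-minimum; default FALSE.
#' @return per-SNP empirical FDR values in the input order.
#' @export
unconditional_fdr <- function(p, monotone = FALSE) {
  stopifnot(all(p > 0), all(p <= 1))
  v <- pmin(1, p * (length(p) / count_leq(p, p)))
  if (monotone) v <- monotonize_values(v, p)
  v
}

#' Select significant SNPs by a cFDR statistic
#'
#' @param results a `cfdr_result` table from [assign_cfdr()].
#' @param field which statistic: `"ccfdr"` (default), `"cfdr_i_given_j"` or
#'   `"cfdr_j_given_i"`.
#' @param alpha significance threshold in (0, 1); default 0.05. The
#'   comparison is strict (`< alpha`), so a statistic exactly at the
#'   threshold is excluded.
#' @return character vector of significant snp_ids.
#' @export
significant_set <- function(results,
                            field = c("ccfdr", "cfdr_i_given_j", "cfdr_j_given_i"),
                            alpha = 0.05) {
  field <- match.arg(field)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  results$snp_id[results[[field]] < alpha]
}

#' Write a cFDR look-up table as a TSV matrix
#'
#' Header row and first column carry the conditioning and principal
#' thresholds respectively.
#'
#' @param table a `cfdr_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  dt <- data.table::data.table(p_i = format_sci(table$pi_grid))
  vals <- table$values
  for (c in seq_along(table$pj_grid))
    dt[[paste0("p_j_", format_sci(table$pj_grid[c]))]] <- format_sci(vals[, c])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# Table-2 style scientific notation, 4 significant digits ("1.040E-06")
format_sci <- function(x) formatC(x, format = "E", digits = 3)
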