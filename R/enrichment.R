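#' Conditioning strata for enrichment diagnostics
#'
#' Nested subsets of SNPs defined by significance on the conditioning trait:
#' each threshold keeps the SNPs with `p_j <=` that cutoff. The default
#' ladder 1, 0.1, 0.01, 1e-3, 1e-4 corresponds to -log10(P) > 0 ... > 4, the
#' standard display for pleiotropic-enrichment Q-Q plots; the first stratum
#' (cutoff 1) is always the all-SNP reference.
#'
#' @param thresholds strictly decreasing p_j cutoffs in (0, 1], first
#'   element 1.
#' @return a `stratum_spec` list.
#' @export
stratum_spec <- function(thresholds = c(1, 0.1, 0.01, 1e-3, 1e-4)) {
  if (any(thresholds <= 0) || any(thresholds > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  if (thresholds[1] != 1)
    stop("the first stratum must be the all-SNP stratum (cutoff 1)", call. = FALSE)
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing", call. = FALSE)
  structure(list(thresholds = thresholds), class = "stratum_spec")
}

#' Default nominal p-value grid for enrichment curves
#'
#' 1,000 points equally spaced in -log10(p) over \[0, 10\].
#'
#' @return numeric vector of nominal p-values (decreasing from 1 to 1e-10).
#' @export
default_nominal_grid <- function() 10^(-seq(0, 10, length.out = 1000))

# empirical q(t) = proportion of p <= t, vectorised over a threshold grid
ecdf_at <- function(p, t) {
  sp <- sort(p)
  findInterval(t, sp) / length(sp)
}

# shared stratum bookkeeping: list of logical masks, skipping small strata
stratum_masks <- function(merged, spec, min_stratum) {
  masks <- lapply(spec$thresholds, function(cut) merged$p_j <= cut)
  sizes <- vapply(masks, sum, integer(1))
  keep <- sizes >= min_stratum
  if (!any(keep))
    stop("all strata below the minimum size (", min_stratum, " SNPs)",
         call. = FALSE)
  if (any(!keep))
    warning(sprintf("skipping %d stratum/strata below %d SNPs (cutoffs: %s)",
                    sum(!keep), min_stratum,
                    paste(spec$thresholds[!keep], collapse = ", ")),
            call. = FALSE)
  list(masks = masks[keep], cutoffs = spec$thresholds[keep], sizes = sizes[keep])
}

#' Stratified Q-Q curves of the principal trait conditional on the second
#'
#' For each conditioning stratum (SNPs with `p_j` at or below a cutoff), the
#' empirical quantile `q(t)` is the proportion of stratum SNPs with
#' `p_i <= t`, reported on the -log10 scale against the nominal `-log10(t)`
#' grid. Leftward/upward shift of stricter strata relative to the all-SNP
#' curve is the visual signature of pleiotropic enrichment. Strata smaller
#' than `min_stratum` give unusable quantile estimates and are skipped with a
#' warning.
#'
#' @param merged a `merged_stats` table from [merge_on_snp()].
#' @param spec a [stratum_spec()].
#' @param grid nominal p-value grid in (0, 1]; default [default_nominal_grid()].
#' @param min_stratum minimum SNPs per stratum (default 100).
#' @return tidy `data.table`: `stratum` (p_j cutoff), `nominal_neglog`,
#'   `empirical_neglog` (NA where the empirical quantile is 0),
#'   `n_in_stratum`.
#' @export
stratified_qq <- function(merged, spec = stratum_spec(),
                          grid = default_nominal_grid(), min_stratum = 100) {
  stopifnot(nrow(merged) > 0, all(grid > 0), all(grid <= 1))
  st <- stratum_masks(merged, spec, min_stratum)
  out <- lapply(seq_along(st$cutoffs), function(k) {
    q <- ecdf_at(merged$p_i[st$masks[[k]]], grid)
    data.table::data.table(stratum = st$cutoffs[k],
                           nominal_neglog = -log10(grid),
                           empirical_neglog = ifelse(q > 0, -log10(q), NA_real_),
                           n_in_stratum = st$sizes[k])
  })
  data.table::rbindlist(out)
}

#' Fold-enrichment curves
#'
#' `fold(t; stratum) = q_stratum(t) / q_all(t)`: the proportion of stratum
#' SNPs with `p_i <= t` relative to the same proportion among all SNPs. The
#' all-SNP stratum is identically 1; values above 1 in stricter strata
#' quantify pleiotropic enrichment. Points where `q_all(t) = 0` are reported
#' as NA, never as infinity.
#'
#' @inheritParams stratified_qq
#' @return tidy `data.table`: `stratum`, `nominal_neglog`, `fold`,
#'   `n_in_stratum`.
#' @export
fold_enrichment <- function(merged, spec = stratum_spec(),
                            grid = default_nominal_grid(), min_stratum = 100) {
  stopifnot(nrow(merged) > 0, all(grid > 0), all(grid <= 1))
  st <- stratum_masks(merged, spec, min_stratum)
  q_all <- ecdf_at(merged$p_i, grid)
  out <- lapply(seq_along(st$cutoffs), function(k) {
    q <- ecdf_at(merged$p_i[st$masks[[k]]], grid)
    data.table::data.table(stratum = st$cutoffs[k],
                           nominal_neglog = -log10(grid),
                           fold = ifelse(q_all > 0, q / q_all, NA_real_),
                           n_in_stratum = st$sizes[k])
  })
  data.table::rbindlist(out)
}

#' Stratified conditional true-discovery-rate curves
#'
#' `TDR(t; stratum) = 1 - cFDR(t | stratum cutoff)`, with the cFDR evaluated
#' by the same empirical estimator used per SNP ([empirical_cfdr()]): nominal
#' threshold times the inverse conditional empirical CDF, capped at 1.
#' Increasing TDR in stricter strata is the enrichment gain from
#' conditioning, expressed on the discovery-rate scale.
#'
#' @inheritParams stratified_qq
#' @return tidy `data.table`: `stratum`, `nominal_neglog`, `tdr` in \[0, 1\],
#'   `n_in_stratum`.
#' @export
stratified_tdr <- function(merged, spec = stratum_spec(),
                           grid = default_nominal_grid(), min_stratum = 100) {
  stopifnot(nrow(merged) > 0, all(grid > 0), all(grid <= 1))
  st <- stratum_masks(merged, spec, min_stratum)
  out <- lapply(seq_along(st$cutoffs), function(k) {
    p_sub <- sort(merged$p_i[st$masks[[k]]])
    n_j <- st$sizes[k]
    n_ij <- findInterval(grid, p_sub)
    cfdr <- ifelse(n_ij > 0, pmin(1, grid * (n_j / n_ij)), 1)
    data.table::data.table(stratum = st$cutoffs[k],
                           nominal_neglog = -log10(grid),
                           tdr = pmin(1, pmax(0, 1 - cfdr)),
                           n_in_stratum = n_j)
  })
  data.table::rbindlist(out)
}

#' Plot stratified Q-Q or fold-enrichment curves
#'
#' Convenience ggplot2 layer over the tidy curve tables; the analysis can
#' equally plot the exported TSVs with any front-end.
#'
#' @param curves output of [stratified_qq()] or [fold_enrichment()].
#' @param type `"qq"` or `"fold"`.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(curves, type = c("qq", "fold")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  type <- match.arg(type)
  curves <- data.table::as.data.table(curves)
  curves[, stratum_lab := factor(format(stratum, scientific = TRUE),
                                 levels = format(sort(unique(stratum),
                                                      decreasing = TRUE),
                                                 scientific = TRUE))]
  if (type == "qq") {
    gg <- ggplot2::ggplot(curves[!is.na(empirical_neglog)],
                          ggplot2::aes(x = empirical_neglog, y = nominal_neglog,
                                       colour = stratum_lab)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = expression(-log[10](q)), y = expression(-log[10](p)),
                    colour = "p_j stratum")
  } else {
    gg <- ggplot2::ggplot(curves[!is.na(fold)],
                          ggplot2::aes(x = nominal_neglog, y = fold,
                                       colour = stratum_lab)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(x = expression(-log[10](p)), y = "fold enrichment",
                    colour = "p_j stratum")
  }
  gg + ggplot2::theme_minimal()
}
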