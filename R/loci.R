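#' Read a pairwise LD table
#'
#' Three-column delimited text (`snp_a`, `snp_b`, `r2`) of squared allelic
#' correlations; the table is symmetrised on load.
#'
#' @param path file path.
#' @return `data.table` of class `ld_table` with columns `snp_a`, `snp_b`,
#'   `r2`, containing both orientations of every pair.
#' @export
read_ld_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(dt)))
    stop("LD table must have columns snp_a, snp_b, r2", call. = FALSE)
  as_ld_table(dt)
}

#' Construct an LD table from a data.frame
#'
#' @param dt data.frame with columns `snp_a`, `snp_b`, `r2` in \[0, 1\].
#' @return symmetrised `ld_table` data.table.
#' @export
as_ld_table <- function(dt) {
  dt <- data.table::as.data.table(dt)[, .(snp_a = as.character(snp_a),
                                          snp_b = as.character(snp_b),
                                          r2 = as.numeric(r2))]
  if (any(dt$r2 < 0 | dt$r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  sym <- unique(data.table::rbindlist(list(
    dt, dt[, .(snp_a = snp_b, snp_b = snp_a, r2 = r2)])))
  data.table::setattr(sym, "class", unique(c("ld_table", class(sym))))
  sym[]
}

#' Greedy clumping of significant SNPs into independent loci
#'
#' Repeatedly takes the most significant unassigned SNP passing `alpha` as a
#' locus lead and assigns to it every unassigned significant SNP on the same
#' chromosome within `window_kb` of the lead (and, when an LD table is
#' supplied, with `r2 >= r2_clump` to the lead). Ties on the statistic are
#' broken by (chrom, pos), so the procedure is deterministic. The assignment
#' is a partition: every significant SNP belongs to exactly one locus.
#'
#' @param results a `cfdr_result` table.
#' @param field statistic used for significance and lead ranking; see
#'   [significant_set()].
#' @param alpha significance threshold (strict `<`); default 0.05.
#' @param window_kb clumping half-window around the lead in kb; default 1000
#'   (1 Mb), distance-only clumping being the default because no LD reference
#'   is bundled.
#' @param ld optional `ld_table`; activates the LD condition.
#' @param r2_clump minimum r2 to the lead for LD-aware membership.
#' @return `data.table` of class `locus_set`: `lead_snp`, `chrom`, `pos`,
#'   `statistic`, `n_members`, `member_snps` (list column).
#' @export
clump <- function(results, field = c("ccfdr", "cfdr_i_given_j", "cfdr_j_given_i"),
                  alpha = 0.05, window_kb = 1000, ld = NULL, r2_clump = 0.1) {
  field <- match.arg(field)
  sig <- data.table::as.data.table(results)[results[[field]] < alpha]
  empty <- data.table::data.table(lead_snp = character(), chrom = character(),
                                  pos = integer(), statistic = numeric(),
                                  n_members = integer(), member_snps = list())
  data.table::setattr(empty, "class", unique(c("locus_set", class(empty))))
  if (nrow(sig) == 0L) return(empty)

  data.table::setnames(sig, field, ".stat")
  data.table::setorderv(sig[, .ord := chrom_order(chrom)],
                        c(".stat", ".ord", "pos"))
  window_bp <- window_kb * 1000

  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  for (k in seq_len(nrow(sig))) {
    if (assigned[k]) next
    lead <- sig[k]
    members <- !assigned & sig$chrom == lead$chrom &
      abs(sig$pos - lead$pos) <= window_bp
    if (!is.null(ld)) {
      in_ld <- sig$snp_id %in%
        ld[snp_a == lead$snp_id & r2 >= r2_clump, snp_b]
      members <- members & (in_ld | sig$snp_id == lead$snp_id)
    }
    assigned <- assigned | members
    loci[[length(loci) + 1L]] <- data.table::data.table(
      lead_snp = lead$snp_id, chrom = lead$chrom, pos = lead$pos,
      statistic = lead$.stat, n_members = sum(members),
      member_snps = list(sig$snp_id[members]))
  }
  out <- data.table::rbindlist(loci)
  data.table::setorderv(out[, .ord := chrom_order(chrom)], c(".ord", "pos"))
  out[, .ord := NULL]
  data.table::setattr(out, "class", unique(c("locus_set", class(out))))
  out[]
}

#' Cross-check discovery loci against a replication analysis
#'
#' A locus is replicated if its lead SNP passes `alpha` in the replication
#' results, or if any SNP in high LD with the lead (`r2 > r2_rep`, strict,
#' and on the same chromosome) does. Without an LD table only exact-id
#' matching is performed and the output flags that restriction.
#'
#' @param discovery_loci a `locus_set` from [clump()].
#' @param replication_results a `cfdr_result` table from the replication
#'   analysis.
#' @param field statistic checked in the replication results.
#' @param alpha replication significance threshold (strict `<`).
#' @param ld optional `ld_table` of proxies.
#' @param r2_rep LD threshold for proxy replication; default 0.6 (a proxy
#'   counts only when `r2 > 0.6`).
#' @return `data.table`: `lead_snp`, `chrom`, `pos`, `statistic`,
#'   `replicated` (logical), `via` ("self", "proxy" or NA), `proxy_id`,
#'   `proxy_r2`, `ld_available`.
#' @export
replication_check <- function(discovery_loci, replication_results,
                              field = c("ccfdr", "cfdr_i_given_j", "cfdr_j_given_i"),
                              alpha = 0.05, ld = NULL, r2_rep = 0.6) {
  field <- match.arg(field)
  rep_dt <- data.table::as.data.table(replication_results)
  rep_sig <- rep_dt[rep_dt[[field]] < alpha, .(snp_id, chrom)]
  ld_available <- !is.null(ld)
  if (!ld_available)
    warning("no LD table supplied; replication uses exact-id matching only",
            call. = FALSE)

  rows <- lapply(seq_len(nrow(discovery_loci)), function(k) {
    locus <- discovery_loci[k]
    self_hit <- locus$lead_snp %in% rep_sig$snp_id
    via <- NA_character_; proxy_id <- NA_character_; proxy_r2 <- NA_real_
    replicated <- FALSE
    if (self_hit) {
      replicated <- TRUE; via <- "self"
    } else if (ld_available) {
      proxies <- ld[snp_a == locus$lead_snp & r2 > r2_rep]
      # cross-chromosome proxies are never accepted
      hits <- merge(proxies, rep_sig, by.x = "snp_b", by.y = "snp_id")
      hits <- hits[chrom == locus$chrom]
      if (nrow(hits)) {
        best <- hits[which.max(r2)]
        replicated <- TRUE; via <- "proxy"
        proxy_id <- best$snp_b; proxy_r2 <- best$r2
      }
    }
    data.table::data.table(lead_snp = locus$lead_snp, chrom = locus$chrom,
                           pos = locus$pos, statistic = locus$statistic,
                           replicated = replicated, via = via,
                           proxy_id = proxy_id, proxy_r2 = proxy_r2,
                           ld_available = ld_available)
  })
  if (length(rows) == 0L)
    return(data.table::data.table(lead_snp = character(), chrom = character(),
                                  pos = integer(), statistic = numeric(),
                                  replicated = logical(), via = character(),
                                  proxy_id = character(), proxy_r2 = numeric(),
                                  ld_available = logical()))
  data.table::rbindlist(rows)
}

#' Write a locus table as TSV
#'
#' @param loci a `locus_set` or replication-status table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  out <- data.table::as.data.table(loci)
  if ("member_snps" %in% names(out))
    out[, member_snps := vapply(member_snps, paste, character(1), collapse = ",")]
  if ("statistic" %in% names(out))
    out[, statistic := format_sci(statistic)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
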