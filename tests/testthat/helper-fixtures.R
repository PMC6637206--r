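# shared fixtures, all built in code

# the canonical 5-SNP panel used throughout the cFDR estimator tests
toy_panel <- function() {
  data.table::data.table(
    snp_id = paste0("rs", 1:5),
    chrom = "1",
    pos = c(1e5, 2e5, 3e5, 4e5, 5e5),
    p_i = c(0.001, 0.01, 0.02, 0.5, 0.9),
    p_j = c(0.004, 0.03, 0.5, 0.01, 0.8))
}

# independent brute-force double-loop oracle for the empirical cFDR
brute_cfdr <- function(panel, a, b) {
  n_j <- sum(panel$p_j <= b)
  n_ij <- 0
  for (k in seq_len(nrow(panel)))
    if (panel$p_i[k] <= a && panel$p_j[k] <= b) n_ij <- n_ij + 1
  if (n_ij == 0) return(1)
  min(1, a * n_j / n_ij)
}

# random merged panel for property-style tests
random_panel <- function(n, seed) {
  set.seed(seed)
  data.table::data.table(
    snp_id = sprintf("rs%06d", seq_len(n)),
    chrom = as.character(sample.int(4, n, replace = TRUE)),
    pos = sample.int(1e7, n),
    p_i = runif(n)^sample(c(1, 3), n, replace = TRUE),
    p_j = runif(n)^sample(c(1, 3), n, replace = TRUE))
}

# write a small summary-statistics file and return its path
write_sumstats_file <- function(df, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# minimal cfdr_result-shaped table for clumping / replication tests
toy_results <- function(snp_id, chrom, pos, ccfdr) {
  data.table::data.table(snp_id = snp_id, chrom = as.character(chrom),
                         pos = pos, p_i = ccfdr, p_j = ccfdr,
                         cfdr_i_given_j = ccfdr, cfdr_j_given_i = ccfdr,
                         ccfdr = ccfdr)
}
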