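test_that("stratum spec enforces the decreasing ladder anchored at 1", {
  expect_equal(stratum_spec()$thresholds, c(1, 0.1, 0.01, 1e-3, 1e-4))
  expect_error(stratum_spec(c(0.1, 0.01)), "all-SNP")
  expect_error(stratum_spec(c(1, 0.1, 0.1)), "decreasing")
  expect_error(stratum_spec(c(1, 0)), "\\(0, 1\\]")
})

test_that("stratified Q-Q empirical quantiles match hand counts on a toy", {
  m <- data.table::data.table(
    snp_id = paste0("rs", 1:6), chrom = "1", pos = 1:6,
    p_i = c(0.001, 0.01, 0.05, 0.2, 0.5, 0.9), p_j = 1)
  qq <- stratified_qq(m, stratum_spec(1), grid = c(0.05, 1), min_stratum = 1)
  # q(0.05) = 3/6, q(1) = 1 exactly
  expect_equal(qq$empirical_neglog, -log10(c(0.5, 1)))
  expect_equal(qq$n_in_stratum, c(6L, 6L))
})

test_that("q(1) is exactly 1 in every stratum and curves ignore SNP order", {
  m <- random_panel(2000, seed = 21)
  spec <- stratum_spec(c(1, 0.5, 0.1))
  qq <- stratified_qq(m, spec, min_stratum = 10)
  expect_equal(qq[nominal_neglog == 0]$empirical_neglog, rep(0, 3))
  # non-decreasing along the grid within each stratum
  for (s in unique(qq$stratum)) {
    y <- qq[stratum == s & !is.na(empirical_neglog)]$empirical_neglog
    expect_true(all(diff(y) >= 0))
  }
  shuffled <- m[sample(nrow(m))]
  expect_equal(as.data.frame(stratified_qq(shuffled, spec, min_stratum = 10)),
               as.data.frame(qq))
})

test_that("fold enrichment matches hand counts and is 1 for the all-SNP stratum", {
  # 12 SNPs; stratum p_j <= 0.1 holds 4 of them, 2 below t; 3 of 12 overall
  m <- data.table::data.table(
    snp_id = paste0("rs", 1:12), chrom = "1", pos = 1:12,
    p_i = c(0.01, 0.02, 0.8, 0.9, 0.03, rep(0.7, 7)),
    p_j = c(0.05, 0.08, 0.09, 0.1, rep(0.9, 8)))
  fe <- fold_enrichment(m, stratum_spec(c(1, 0.1)), grid = 0.05,
                        min_stratum = 1)
  expect_equal(fe[stratum == 1]$fold, 1)          # self-ratio
  expect_equal(fe[stratum == 0.1]$fold, (2 / 4) / (3 / 12))  # = 2.0
})

test_that("independent null panel shows no enrichment beyond binomial noise", {
  set.seed(22)
  n <- 5e4
  m <- data.table::data.table(snp_id = sprintf("rs%05d", 1:n), chrom = "1",
                              pos = 1:n, p_i = runif(n), p_j = runif(n))
  grid <- c(0.5, 0.1, 0.01)
  fe <- fold_enrichment(m, stratum_spec(c(1, 0.1, 0.01)), grid = grid)
  for (s in c(0.1, 0.01)) {
    sub <- fe[stratum == s]
    n_s <- sub$n_in_stratum[1]
    for (k in seq_along(grid)) {
      q_all <- mean(m$p_i <= grid[k])
      # count in the stratum must sit inside a central binomial envelope
      count <- sub$fold[k] * q_all * n_s
      lo <- qbinom(5e-5, n_s, q_all); hi <- qbinom(1 - 5e-5, n_s, q_all)
      expect_true(count >= lo && count <= hi)
    }
  }
})

test_that("pleiotropic panels push strict-stratum Q-Q curves above the all-SNP curve", {
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    pair <- suppressMessages(generate_pair(generator_config(
      n_snps = 2e4, pi0 = 0.95, pi1 = 0, pi2 = 0.02, pi12 = 0.03, seed = 100L + s)))
    m <- suppressMessages(merge_on_snp(pair$trait1, pair$trait2))
    qq <- stratified_qq(m, stratum_spec(c(1, 1e-2)), grid = 0.01,
                        min_stratum = 50)
    # enrichment: larger q(t) in the strict stratum, i.e. smaller -log10 q
    # (the leftward shift of the conditional curve)
    y <- qq[order(stratum)]  # strict stratum first
    hits <- hits + (y$empirical_neglog[1] < y$empirical_neglog[2])
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("TDR is definitionally 1 - cFDR and behaves at the extremes", {
  m <- random_panel(5000, seed = 23)
  spec <- stratum_spec(c(1, 0.1))
  grid <- c(0.5, 0.01, 1e-4)
  td <- stratified_tdr(m, spec, grid = grid, min_stratum = 10)
  for (s in spec$thresholds) {
    cfdr <- empirical_cfdr(m, grid, rep(s, length(grid)))
    expect_equal(td[stratum == s]$tdr, pmax(0, 1 - cfdr))
  }
  expect_true(all(td$tdr >= 0 & td$tdr <= 1))

  # pure-null independent panel: cFDR near 1 at t = 0.5, so TDR near 0
  set.seed(24)
  null_m <- data.table::data.table(snp_id = paste0("rs", 1:2e4), chrom = "1",
                                   pos = 1:2e4, p_i = runif(2e4),
                                   p_j = runif(2e4))
  td0 <- stratified_tdr(null_m, stratum_spec(c(1, 0.1)), grid = 0.5)
  expect_lt(max(td0$tdr), 0.05)

  # strong-signal panel: TDR at t = 1e-6 close to 1
  pair <- suppressMessages(generate_pair(generator_config(
    n_snps = 2e4, pi0 = 0.9, pi1 = 0.05, pi2 = 0, pi12 = 0.05,
    sigma1_sq = 36, seed = 25L)))
  ms <- suppressMessages(merge_on_snp(pair$trait1, pair$trait2))
  tds <- stratified_tdr(ms, stratum_spec(1), grid = 1e-6)
  expect_gte(tds$tdr, 0.9)
})

test_that("small strata are skipped with a warning; all-small errors", {
  m <- random_panel(500, seed = 26)
  expect_warning(stratified_qq(m, stratum_spec(c(1, 1e-4)), grid = 0.1),
                 "skipping")
  expect_error(
    suppressWarnings(stratified_qq(m, stratum_spec(c(1, 1e-4)), grid = 0.1,
                                   min_stratum = 1e6)),
    "minimum size")
})
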