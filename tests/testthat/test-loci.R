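test_that("distance clumping separates far SNPs and merges near ones", {
  # two significant SNPs 2 Mb apart, window 1 Mb -> 2 loci
  far <- toy_results(c("rs1", "rs2"), 1, c(1e6, 3e6), c(0.01, 0.02))
  expect_equal(nrow(clump(far, "ccfdr", window_kb = 1000)), 2L)

  # three significant SNPs within 100 kb -> one locus led by the smallest
  near <- toy_results(c("rsA", "rsB", "rsC"), 2, c(5e6, 5.05e6, 5.09e6),
                      c(0.03, 0.001, 0.02))
  loci <- clump(near, "ccfdr", window_kb = 1000)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$lead_snp, "rsB")
  expect_setequal(loci$member_snps[[1]], c("rsA", "rsB", "rsC"))

  # nothing significant -> empty locus set
  expect_equal(nrow(clump(toy_results("rs1", 1, 1, 0.5), "ccfdr")), 0L)
})

test_that("clump assignment partitions the significant set", {
  set.seed(41)
  n <- 300
  r <- toy_results(sprintf("rs%03d", 1:n),
                   chrom = sample(1:3, n, TRUE),
                   pos = sample.int(5e7, n),
                   ccfdr = runif(n)^4)
  loci <- clump(r, "ccfdr", alpha = 0.05, window_kb = 500)
  members <- unlist(loci$member_snps)
  expect_equal(sort(members), sort(significant_set(r, "ccfdr", 0.05)))
  expect_false(anyDuplicated(members) > 0)
  # lead statistic is the locus minimum
  stat <- setNames(r$ccfdr, r$snp_id)
  for (k in seq_len(nrow(loci)))
    expect_true(all(stat[loci$member_snps[[k]]] >= loci$statistic[k]))
})

test_that("locus counts are monotone in alpha and window size", {
  r <- toy_results(paste0("rs", 1:6), 1,
                   c(1e6, 1.4e6, 2.2e6, 6e6, 6.3e6, 9e6),
                   c(0.001, 0.04, 0.02, 0.03, 0.06, 0.002))
  n_small_alpha <- nrow(clump(r, "ccfdr", alpha = 0.01))
  n_big_alpha <- nrow(clump(r, "ccfdr", alpha = 0.05))
  expect_gte(n_big_alpha, n_small_alpha)
  n_wide <- nrow(clump(r, "ccfdr", window_kb = 2000))
  n_narrow <- nrow(clump(r, "ccfdr", window_kb = 100))
  expect_gte(n_narrow, n_wide)
})

test_that("LD-aware clumping only absorbs SNPs linked to the lead", {
  r <- toy_results(c("rs1", "rs2", "rs3"), 1, c(1e6, 1.1e6, 1.2e6),
                   c(0.001, 0.01, 0.02))
  ld <- as_ld_table(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  loci <- clump(r, "ccfdr", window_kb = 1000, ld = ld, r2_clump = 0.5)
  # rs3 is within the window but unlinked, so it seeds its own locus
  expect_equal(nrow(loci), 2L)
  expect_setequal(loci$lead_snp, c("rs1", "rs3"))
})

test_that("replication follows the strict r2 > 0.6 proxy rule", {
  loci <- clump(toy_results("rs_lead", 5, 1e6, 0.001), "ccfdr")
  make_rep <- function(ids, vals, chrom = 5)
    toy_results(ids, chrom, seq_along(ids) * 1e5, vals)

  # lead itself significant -> replicated via self
  st <- suppressWarnings(
    replication_check(loci, make_rep("rs_lead", 0.01), "ccfdr"))
  expect_true(st$replicated)
  expect_equal(st$via, "self")

  # lead absent, proxy at r2 = 0.91 significant -> replicated via proxy
  ld <- as_ld_table(data.frame(snp_a = "rs_lead", snp_b = "rs_proxy",
                               r2 = 0.91))
  st2 <- replication_check(loci, make_rep("rs_proxy", 0.01), "ccfdr", ld = ld)
  expect_true(st2$replicated)
  expect_equal(st2$via, "proxy")
  expect_equal(st2$proxy_r2, 0.91)

  # proxy at r2 = 0.5 significant -> not replicated (0.5 < 0.6)
  ld_lo <- as_ld_table(data.frame(snp_a = "rs_lead", snp_b = "rs_proxy",
                                  r2 = 0.5))
  st3 <- replication_check(loci, make_rep("rs_proxy", 0.01), "ccfdr", ld = ld_lo)
  expect_false(st3$replicated)

  # r2 exactly 0.6 fails the strict rule too
  ld_eq <- as_ld_table(data.frame(snp_a = "rs_lead", snp_b = "rs_proxy",
                                  r2 = 0.6))
  st4 <- replication_check(loci, make_rep("rs_proxy", 0.01), "ccfdr", ld = ld_eq)
  expect_false(st4$replicated)

  # cross-chromosome proxies are never accepted
  ld_x <- as_ld_table(data.frame(snp_a = "rs_lead", snp_b = "rs_far",
                                 r2 = 0.95))
  st5 <- replication_check(loci, make_rep("rs_far", 0.01, chrom = 9), "ccfdr",
                           ld = ld_x)
  expect_false(st5$replicated)

  # without an LD table only exact-id matching happens, flagged
  expect_warning(
    st6 <- replication_check(loci, make_rep("rs_proxy", 0.01), "ccfdr"),
    "exact-id")
  expect_false(st6$replicated)
  expect_false(st6$ld_available)
})

test_that("replication status ignores the ordering of replication results", {
  loci <- clump(toy_results(c("rsA", "rsB"), 1, c(1e6, 8e6), c(0.01, 0.02)),
                "ccfdr")
  rep_res <- toy_results(c("rsB", "rsA", "rsZ"), 1, c(8e6, 1e6, 2e6),
                         c(0.01, 0.5, 0.001))
  a <- suppressWarnings(replication_check(loci, rep_res, "ccfdr"))
  b <- suppressWarnings(replication_check(loci, rep_res[c(3, 1, 2)], "ccfdr"))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(a$replicated, c(FALSE, TRUE))
})

test_that("LD tables validate and symmetrise", {
  ld <- as_ld_table(data.frame(snp_a = "a", snp_b = "b", r2 = 0.7))
  expect_equal(nrow(ld), 2L)
  expect_true(all(c("a", "b") %in% ld$snp_a))
  expect_error(as_ld_table(data.frame(snp_a = "a", snp_b = "b", r2 = 1.2)),
               "r2")
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(snp_a = "a", snp_b = "b", r2 = 0.8), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_ld_table(path)), 2L)
})
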