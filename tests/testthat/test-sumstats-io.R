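test_that("reading keeps valid rows, drops out-of-range p, keeps min-p duplicate", {
  path <- write_sumstats_file(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = c(1, 2, 3),
    pos = c(100, 200, 300), pvalue = c(0.5, 0.01, 1.0)))
  ss <- suppressMessages(read_sumstats(path))
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss), 3L)
  expect_setequal(ss$snp_id, c("rs1", "rs2", "rs3"))

  path2 <- write_sumstats_file(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = 1, pos = c(1, 2, 3),
    pvalue = c(1.5, 0.2, 0.3)))
  ss2 <- suppressMessages(read_sumstats(path2))
  expect_equal(nrow(ss2), 2L)
  expect_equal(attr(ss2, "log")$n_bad_pvalue, 1L)

  # duplicated rsID keeps the smaller p (brute-force min over the toy file)
  dup <- data.frame(snp_id = c("rs9", "rs9", "rs1"), chrom = 1,
                    pos = c(10, 10, 20), pvalue = c(0.2, 0.05, 0.4))
  expected_min <- min(dup$pvalue[dup$snp_id == "rs9"])
  ss3 <- suppressMessages(read_sumstats(write_sumstats_file(dup)))
  expect_equal(nrow(ss3), 2L)
  expect_equal(ss3[ss3$snp_id == "rs9"]$pvalue, expected_min)
})

test_that("dialect maps arbitrary source columns and flags missing ones", {
  path <- write_sumstats_file(data.frame(
    MarkerName = "rs1", CHR = "chr7", BP = 5, P = 0.1), sep = ",")
  d <- sumstats_dialect(snp_id = "MarkerName", chrom = "CHR",
                        pos = "BP", pvalue = "P")
  ss <- read_sumstats(path, d)
  expect_equal(ss$chrom, "7")  # "chr" prefix stripped
  expect_error(read_sumstats(path, sumstats_dialect()), "absent")
})

test_that("z-score / p-value consistency is enforced on load", {
  path <- write_sumstats_file(data.frame(
    snp_id = c("rs1", "rs2"), chrom = 1, pos = c(1, 2),
    pvalue = c(2 * pnorm(-1.96), 0.5), zscore = c(1.96, 3.0)))
  d <- sumstats_dialect(zscore = "zscore")
  ss <- suppressMessages(read_sumstats(path, d))
  expect_equal(ss$snp_id, "rs1")  # rs2's z contradicts its p
  expect_equal(attr(ss, "log")$n_z_inconsistent, 1L)
})

test_that("sub-minimal p-values follow the clamp/reject policy", {
  df <- data.frame(snp_id = c("rs1", "rs2"), chrom = 1, pos = c(1, 2),
                   pvalue = c(0, 0.3))
  clamped <- suppressMessages(read_sumstats(write_sumstats_file(df)))
  expect_equal(min(clamped$pvalue), 1e-300)
  rejected <- suppressMessages(
    read_sumstats(write_sumstats_file(df), zero_policy = "reject"))
  expect_equal(rejected$snp_id, "rs2")
})

test_that("lambda_GC matches its chi-square definition", {
  # a single p of 0.5 sits at the chi-square(1) median
  one <- data.table::data.table(pvalue = 0.5)
  expect_equal(estimate_lambda_gc(one)$lambda_gc, 1.0, tolerance = 1e-3)

  # any vector whose chi-square transforms have median exactly 0.4549
  p_at_median <- pchisq(c(0.1, 0.4549, 2.0), df = 1, lower.tail = FALSE)
  expect_equal(estimate_lambda_gc(data.table::data.table(pvalue = p_at_median))$lambda_gc,
               1.0, tolerance = 1e-12)

  # Monte-Carlo oracle under the null: lambda -> 1
  set.seed(42)
  unif <- data.table::data.table(pvalue = runif(1e5))
  expect_equal(estimate_lambda_gc(unif)$lambda_gc, 1.0, tolerance = 0.02)

  expect_error(estimate_lambda_gc(data.table::data.table(pvalue = numeric())))
})

test_that("genomic control is the identity at lambda 1 and conservative above", {
  ss <- suppressMessages(validate_sumstats(data.frame(
    snp_id = paste0("rs", 1:4), chrom = 1, pos = 1:4,
    pvalue = c(0.05, 0.5, 1e-6, 0.9))))
  expect_equal(apply_genomic_control(ss, 1)$pvalue, ss$pvalue)

  # closed-form chi-square(1) oracle at p = 0.05, lambda = 2
  expected <- pchisq(qchisq(0.05, 1, lower.tail = FALSE) / 2, 1,
                     lower.tail = FALSE)
  corrected <- apply_genomic_control(ss, 2)
  expect_equal(corrected[ss$pvalue == 0.05]$pvalue, expected)
  expect_true(all(corrected$pvalue >= ss$pvalue))
  expect_equal(order(corrected$pvalue), order(ss$pvalue))  # rank-preserving
  # lambda below 1 leaves p-values unchanged
  expect_equal(apply_genomic_control(ss, 0.8)$pvalue, ss$pvalue)
})

test_that("merge keeps the intersection, orders by coordinate, and is symmetric", {
  a <- suppressMessages(validate_sumstats(data.frame(
    snp_id = paste0("rs", 1:5), chrom = c(2, 1, 1, 3, 2),
    pos = c(50, 10, 99, 7, 20), pvalue = seq(0.1, 0.5, 0.1))))
  b5 <- suppressMessages(merge_on_snp(a, a))
  expect_equal(nrow(b5), 5L)
  expect_equal(b5$p_i, b5$p_j)

  b <- suppressMessages(validate_sumstats(data.frame(
    snp_id = paste0("rs", 3:7), chrom = 1, pos = 1:5,
    pvalue = rep(0.2, 5))))
  m <- suppressMessages(merge_on_snp(a, b))
  expect_equal(nrow(m), 3L)
  expect_setequal(m$snp_id, paste0("rs", 3:5))
  m_rev <- suppressMessages(merge_on_snp(b, a))
  expect_setequal(m$snp_id, m_rev$snp_id)

  # shuffled input order yields identical coordinate-sorted output
  shuf <- a[sample(nrow(a))]
  m2 <- suppressMessages(merge_on_snp(shuf, b))
  expect_identical(as.data.frame(m2), as.data.frame(m))
  expect_false(is.unsorted(m$pos[m$chrom == "1"]))

  no_overlap <- suppressMessages(validate_sumstats(data.frame(
    snp_id = "rsX1", chrom = 1, pos = 1, pvalue = 0.5)))
  expect_error(suppressMessages(merge_on_snp(a, no_overlap)), "shared")
})
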