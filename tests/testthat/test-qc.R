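test_that("HWE exact test matches worked cases and conventions", {
  # monomorphic: p = 1 by convention
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  # enumeration oracle on a heterozygote-deficit configuration
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  # allele-label symmetry
  for (cfg in list(c(3, 7, 12), c(20, 5, 1), c(8, 8, 8))) {
    expect_identical(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                     hwe_exact_test(cfg[3], cfg[2], cfg[1]))
  }
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("HWE exact test agrees with the enumeration oracle (spot sweep)", {
  for (n in c(5, 12, 23, 30)) {
    for (a in 0:n) {
      for (h in 0:(n - a)) {
        b <- n - a - h
        expect_equal(hwe_exact_test(a, h, b), hwe_oracle(a, h, b),
                     tolerance = 1e-12,
                     label = sprintf("(%d,%d,%d)", a, h, b))
      }
    }
  }
})

test_that("SNP QC applies the MAF boundary, call rate, and HWE rules", {
  # col1: MAF exactly 0.05 -> removed; col2: MAF 0.10 -> kept
  d <- cbind(c(rep(0, 9), 1),
             c(rep(0, 8), 1, 1))
  g <- toy_genotypes(d)
  res <- snp_qc(g, hwe_p_min = 0)   # isolate the MAF rule
  expect_equal(res$genotypes$snp_meta$snp_id, "rs2")
  expect_equal(res$report$removed[["maf"]], 1L)

  # call rate 94/100 -> removed at threshold 0.95
  d2 <- cbind(c(rep(NA, 6), sample(c(0, 1, 2), 94, replace = TRUE)),
              sample(c(0, 1), 100, replace = TRUE))
  g2 <- toy_genotypes(d2)
  res2 <- snp_qc(g2, hwe_p_min = 0)
  expect_false("rs1" %in% res2$genotypes$snp_meta$snp_id)
  expect_equal(res2$report$removed[["snp_call_rate"]], 1L)

  # all-heterozygous SNP at n = 200 wildly violates HWE
  d3 <- cbind(rep(1, 200), c(rep(0, 130), rep(1, 60), rep(2, 10)))
  expect_lt(hwe_oracle(0, 200, 0), 1e-6)   # oracle confirms the regime
  res3 <- snp_qc(toy_genotypes(d3))
  expect_equal(res3$genotypes$snp_meta$snp_id, "rs2")
  expect_equal(res3$report$removed[["hwe"]], 1L)

  expect_error(snp_qc(toy_genotypes(cbind(c(rep(0, 19), 1)))),
               "all SNPs removed")
})

test_that("sample QC keeps call rates strictly above the threshold", {
  d <- matrix(0, 3, 100)
  d[1, 1:10] <- NA                     # rate exactly 0.90 -> removed
  d[2, 1:9] <- NA                      # rate 0.91 -> kept
  d[, 60] <- 1                         # avoid all-constant edge
  g <- genotype_matrix(d, data.frame(snp_id = paste0("v", 1:100),
                                     chrom = "1", pos = 1:100 * 10L,
                                     a1 = "A", a2 = "G"))
  res <- sample_qc(g)
  expect_equal(res$genotypes$sample_ids, c("sample2", "sample3"))
  expect_equal(res$report$n_samples_out,
               res$report$n_samples_in -
                 sum(res$report$removed[c("sample_call_rate",
                                          "excluded_list")]))
  # precomputed exclusion list
  res2 <- sample_qc(g, exclude = "sample3")
  expect_equal(res2$genotypes$sample_ids, "sample2")
})

test_that("mean-dosage imputation fills gaps and preserves column means", {
  d <- cbind(c(0, 1, NA, 1), c(2, 2, 1, 0))
  g <- toy_genotypes(d)
  gi <- impute_missing(g)
  expect_equal(gi$dosages[3, 1], 2 / 3)
  expect_false(anyNA(gi$dosages))
  expect_equal(colMeans(gi$dosages),
               colMeans(d, na.rm = TRUE), ignore_attr = TRUE)
  # identity on complete matrices
  g2 <- toy_genotypes(cbind(c(0, 1, 2), c(1, 1, 0)))
  expect_identical(impute_missing(g2), g2)
})

test_that("the surviving SNP set is order-independent across filters", {
  set.seed(21)
  n <- 120
  d <- matrix(sample(c(0, 1, 2, NA), n * 25, replace = TRUE,
                     prob = c(0.45, 0.3, 0.2, 0.05)), n, 25)
  # add low-MAF and HWE-violating columns
  d <- cbind(d, c(rep(0, n - 2), 1, 1), rep(1, n))
  g <- toy_genotypes(d)
  full <- snp_qc(g)
  kept <- full$genotypes$snp_meta$snp_id
  # each filter alone on the original matrix
  only_cr <- snp_qc(g, maf_max_excluded = -1, hwe_p_min = 0)
  only_maf <- snp_qc(g, call_rate_min = 0, hwe_p_min = 0)
  only_hwe <- snp_qc(g, call_rate_min = 0, maf_max_excluded = -1)
  inter <- Reduce(intersect, list(only_cr$genotypes$snp_meta$snp_id,
                                  only_maf$genotypes$snp_meta$snp_id,
                                  only_hwe$genotypes$snp_meta$snp_id))
  expect_setequal(kept, inter)
  # post-QC invariants
  dk <- full$genotypes$dosages
  maf <- pmin(colMeans(dk, na.rm = TRUE) / 2,
              1 - colMeans(dk, na.rm = TRUE) / 2)
  expect_true(all(maf > 0.05))
  expect_true(all(colMeans(!is.na(dk)) >= 0.95))
})
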