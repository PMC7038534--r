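test_that("window mapping is boundary-inclusive and allows multi-mapping", {
  ann <- data.frame(gene = c("GA", "GB"), chrom = "1",
                    start = c(50000L, 55000L), end = c(60000L, 70000L))
  snps <- data.frame(snp_id = c("in_window", "out_by_1", "in_both",
                                "other_chr"),
                     chrom = c("1", "1", "1", "2"),
                     pos = c(30000L, 29999L, 56000L, 56000L))
  map <- map_snps_to_genes(snps, ann, window_bp = 20000)
  expect_true(all(c("in_window", "in_both") %in% map$snp_id))
  expect_false("out_by_1" %in% map$snp_id)
  expect_equal(sort(map$gene[map$snp_id == "in_both"]), c("GA", "GB"))
  expect_equal(attr(map, "n_unmapped"), 2L)

  map0 <- map_snps_to_genes(snps, ann, window_bp = 0)
  expect_false("in_window" %in% map0$snp_id)
  expect_true("in_both" %in% map0$snp_id)
  expect_error(map_snps_to_genes(snps, ann[0, ]), "empty")
})

test_that("single-SNP and rank-1 genes give degenerate PC sets", {
  e1 <- gene_pca(matrix(c(0, 1, 2, 1), ncol = 1))
  expect_equal(ncol(e1$scores), 1)
  expect_equal(e1$var_prop, 1)
  std <- as.numeric(scale(c(0, 1, 2, 1)))
  expect_equal(drop(e1$scores), std * sign(e1$loadings[1, 1]),
               tolerance = 1e-12)

  x <- cbind(c(0, 1, 2, 1, 0), c(0, 2, 4, 2, 0) / 2)  # perfectly correlated
  e2 <- gene_pca(x)
  expect_equal(e2$var_prop[1], 1, tolerance = 1e-9)

  expect_warning(e3 <- gene_pca(cbind(c(0, 1, 2), c(1, 1, 1))), "constant")
  expect_equal(e3$n_snps, 1)
  w <- capture_warnings(expect_null(gene_pca(matrix(1, 4, 2))))
  expect_match(w, "no variable", all = FALSE)
})

test_that("gene PCA matches an independent eigendecomposition", {
  set.seed(33)
  x <- matrix(sample(0:2, 20 * 5, replace = TRUE), 20, 5)
  e <- gene_pca(x)
  # oracle: dense eigensolver on the correlation matrix
  eig <- eigen(cor(x), symmetric = TRUE)
  expect_equal(e$var_prop, eig$values / 5, tolerance = 1e-8)
  # loadings agree up to the deterministic sign convention
  v <- eig$vectors
  for (j in 1:5) {
    lead <- which.max(abs(v[, j]))
    if (v[lead, j] < 0) v[, j] <- -v[, j]
  }
  expect_equal(unname(e$loadings), v, tolerance = 1e-8)
  # scores are the standardized data projected on the loadings
  expect_equal(unname(e$scores), unname(scale(x) %*% v), tolerance = 1e-8)
  # invariants: zero-mean scores, proportions sum to one
  expect_lt(max(abs(colMeans(e$scores))), 1e-9)
  expect_equal(sum(e$var_prop), 1, tolerance = 1e-9)
  # determinism: same input, bit-identical output
  expect_identical(e, gene_pca(x))
})

test_that("PC selection follows the two criteria", {
  expect_equal(select_pcs(list(var_prop = c(0.5, 0.3, 0.2)), "cumvar"), 1)
  expect_equal(select_pcs(list(var_prop = c(0.2, 0.15, 0.65)), "cumvar"), 2)
  expect_equal(select_pcs(list(var_prop = c(0.2, 0.15, 0.65)), "first_pc"), 1L)
  # boundary: cumulative exactly at the threshold does not stop (strict >)
  expect_equal(select_pcs(list(var_prop = c(0.30, 0.30, 0.40)), "cumvar"), 2)
  # monotone non-increasing in the threshold
  vp <- list(var_prop = c(0.35, 0.25, 0.2, 0.12, 0.08))
  sel <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    select_pcs(vp, "cumvar", th), numeric(1))
  expect_true(all(diff(sel) >= 0))
})

test_that("design assembly duplicates shared genes per pathway block", {
  set.seed(5)
  mk <- function() gene_pca(matrix(sample(0:2, 30, TRUE), 10, 3))
  pcs <- list(G1 = mk(), G2 = mk(), G3 = mk())
  db <- pathway_db(list(P1 = c("G1", "G2"), P2 = c("G2", "G3")))
  des <- build_design(pcs, db, criterion = "first_pc")
  expect_equal(ncol(des$Z), 4)   # G2 contributes to both blocks
  expect_equal(des$index$k, c(1L, 1L, 2L, 2L))
  shared <- which(des$index$gene == "G2")
  expect_equal(des$Z[, shared[1]], des$Z[, shared[2]],
               ignore_attr = TRUE)
  # with first_pc, total columns = number of gene slots
  expect_equal(ncol(des$Z), nrow(des$index))

  # pathway with no summarized genes is dropped
  db2 <- pathway_db(list(P1 = c("G1"), P0 = c("GX")))
  expect_message(des2 <- build_design(pcs, db2, criterion = "first_pc"),
                 "dropping")
  expect_equal(des2$pathway_ids, "P1")
  expect_error(suppressMessages(
    build_design(pcs, pathway_db(list(P0 = "GX")))), "empty design")
})
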