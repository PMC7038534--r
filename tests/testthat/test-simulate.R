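test_that("simulated dosages hit their target MAFs and LD ordering", {
  set.seed(1)
  mafs <- c(0.1, 0.25, 0.4)
  d0 <- hiscompca:::simulate_gene_dosages(10000, mafs, rho = 0)
  freq <- colMeans(d0) / 2
  se <- sqrt(mafs * (1 - mafs) / (2 * 10000))
  expect_true(all(abs(freq - mafs) < 3 * se))
  expect_true(all(d0 %in% 0:2))

  set.seed(2)
  d_ld <- hiscompca:::simulate_gene_dosages(4000, c(0.3, 0.3), rho = 0.9)
  set.seed(2)
  d_no <- hiscompca:::simulate_gene_dosages(4000, c(0.3, 0.3), rho = 0)
  expect_gt(cor(d_ld)[1, 2], cor(d_no)[1, 2])
  expect_gt(cor(d_ld)[1, 2], 0.5)
})

test_that("studies are seed-reproducible and carry a consistent truth", {
  cfg <- sim_config(n_samples = 80, n_pathways = 4, genes_per_pathway = 2,
                    n_causal_genes = 2, snps_per_gene = 3)
  s1 <- simulate_study(cfg, seed = 12)
  s2 <- simulate_study(cfg, seed = 12)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotype$y, s2$phenotype$y)

  expect_true(all(s1$causal_genes %in% s1$pathways[[s1$causal_pathway_id]]))
  expect_equal(length(s1$pathways), 4)
  # annotation maps every SNP back to its generating gene via the window rule
  map <- map_snps_to_genes(s1$genotypes$snp_meta, s1$annotation,
                           window_bp = 0)
  expect_equal(map[order(map$snp_id), ],
               s1$snp_genes[order(s1$snp_genes$snp_id), ],
               ignore_attr = TRUE)
})

test_that("phenotype generation follows the additive model", {
  cfg0 <- sim_config(n_samples = 600, n_pathways = 2,
                     genes_per_pathway = 2, n_causal_genes = 2,
                     snps_per_gene = 3, effect_size = 0, noise_sd = 2)
  s0 <- simulate_study(cfg0, seed = 5)
  expect_equal(var(s0$phenotype$y), 4, tolerance = 0.5)
  expect_equal(s0$heritability, 0)

  # single causal SNP, no noise: y is a monotone function of its dosage
  cfg1 <- sim_config(n_samples = 100, n_pathways = 2,
                     genes_per_pathway = 1, n_causal_genes = 1,
                     snps_per_gene = 1, effect_size = 1, noise_sd = 0,
                     ld_rho = 0)
  s1 <- simulate_study(cfg1, seed = 9)
  expect_equal(cor(s1$phenotype$y,
                   s1$genotypes$dosages[, s1$causal_snps],
                   method = "spearman"), 1)

  # variance bookkeeping: effects sized for R^2 = 0.3 realize it closely.
  # independent SNPs (rho = 0): genetic variance = m * b^2, so noise_sd
  # = sqrt(m b^2 (1 - R2) / R2)
  b <- 0.5; m <- 4; R2 <- 0.3
  cfg2 <- sim_config(n_samples = 5000, n_pathways = 1,
                     genes_per_pathway = 1, n_causal_genes = 1,
                     snps_per_gene = m, effect_size = b, ld_rho = 0,
                     noise_sd = sqrt(m * b^2 * (1 - R2) / R2))
  s2 <- simulate_study(cfg2, seed = 31)
  expect_equal(s2$heritability, R2, tolerance = 0.05)
})

test_that("median dichotomization follows the stated conventions", {
  expect_equal(dichotomize_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  y <- rnorm(31)
  expect_equal(sum(dichotomize_median(y)), 15)   # odd n: (n-1)/2 ones
  expect_equal(dichotomize_median(c(1, 2, 2, 2, 5))[2:4], c(0L, 0L, 0L))
  expect_error(dichotomize_median(rep(1, 4)), "constant")
})

test_that("experiments are reproducible and degenerate cases behave", {
  cfg <- sim_config(n_samples = 60, n_pathways = 3, genes_per_pathway = 2,
                    n_causal_genes = 2, snps_per_gene = 2,
                    effect_size = 0.6)
  e1 <- run_power_experiment(cfg, replicates = 1, B = 19, seed = 5)
  expect_true(e1$estimate %in% c(0, 1))
  e2 <- run_power_experiment(cfg, replicates = 3, B = 19, seed = 5)
  e3 <- run_power_experiment(cfg, replicates = 3, B = 19, seed = 5)
  expect_identical(e2$p_values, e3$p_values)
  expect_equal(e2$se, sqrt(e2$estimate * (1 - e2$estimate) / 3))

  # alpha = 1 rejects everything (p values never reach 1 with B = 19)
  e4 <- run_type1_experiment(cfg, replicates = 2, B = 19, alpha = 1,
                             seed = 6)
  expect_equal(e4$estimate, 1)
  expect_false(e4$tracked_pathway == sprintf("PW%03d", cfg$causal_pathway))
  expect_warning(
    run_power_experiment(sim_config(n_samples = 40, n_pathways = 2,
                                    genes_per_pathway = 1,
                                    n_causal_genes = 1, snps_per_gene = 1,
                                    effect_size = 0),
                         replicates = 1, B = 9, seed = 1),
    "zero causal effects")
})

test_that("power increases with effect size and binary trails continuous", {
  base <- function(effect) sim_config(n_samples = 150, n_pathways = 4,
                                      genes_per_pathway = 2,
                                      n_causal_genes = 2, snps_per_gene = 3,
                                      effect_size = effect)
  p0 <- suppressWarnings(
    run_power_experiment(base(0), replicates = 25, B = 49, seed = 11))
  p5 <- run_power_experiment(base(0.5), replicates = 25, B = 49, seed = 11)
  expect_gte(p5$estimate, p0$estimate)
  expect_gt(p5$estimate, 0.5)   # strong effect at this scale
  expect_lt(p0$estimate, 0.35)  # null stays near alpha

  pb <- run_power_experiment(base(0.25), replicates = 25, B = 49,
                             phenotype = "binary", seed = 11)
  pc <- run_power_experiment(base(0.25), replicates = 25, B = 49,
                             phenotype = "continuous", seed = 11)
  expect_gte(pc$estimate + 0.15, pb$estimate)  # one-sided with MC slack
})

test_that("written studies are readable by the format layer", {
  cfg <- sim_config(n_samples = 30, n_pathways = 3, genes_per_pathway = 2,
                    n_causal_genes = 2, snps_per_gene = 2)
  study <- simulate_study(cfg, seed = 2)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  g <- read_plink(file.path(dir, "study.bed"))
  expect_identical(g$dosages, study$genotypes$dosages)
  pw <- read_gmt(file.path(dir, "study.gmt"))
  expect_equal(names(pw), names(study$pathways))
  ph <- read_phenotype_table(file.path(dir, "study.pheno.tsv"), "Q1")
  expect_equal(ph$y, study$phenotype$y, tolerance = 1e-12)
  ann <- read_gene_annotation(file.path(dir, "study.genes.tsv"))
  expect_equal(ann$gene, study$annotation$gene)
})
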