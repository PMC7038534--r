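#' Configuration for a pathway-structured simulation
#'
#' Defaults mirror the design of the mini-exome study the package's
#' power/type-I experiments emulate: 697 individuals, 168 pathways, one
#' causal pathway holding 9 causal genes, a continuous trait driven
#' additively by the causal-gene variants (with a median-dichotomized binary
#' version), and common-variant MAFs on (0.05, 0.5]. Scaled-down settings
#' for routine testing are passed explicitly by the caller.
#'
#' @param n_samples number of individuals (default 697).
#' @param n_pathways number of pathways (default 168).
#' @param genes_per_pathway genes in each non-causal pathway (default 9, so
#'   every null pathway is size-matched to the causal one).
#' @param n_causal_genes causal genes, all members of the causal pathway
#'   (default 9). The causal pathway contains exactly
#'   `max(n_causal_genes, genes_per_pathway)` genes, the first
#'   `n_causal_genes` of them causal.
#' @param snps_per_gene SNPs per gene (default 4).
#' @param maf_range range of per-SNP minor allele frequencies, drawn
#'   uniformly (default `c(0.05, 0.5)`, lower bound exclusive).
#' @param ld_rho exchangeable within-gene LD on the latent (copula) scale,
#'   in \[0, 1) (default 0.3); genes are independent.
#' @param effect_size additive effect per standardized causal-SNP dosage on
#'   the continuous trait (default 0.5).
#' @param noise_sd residual standard deviation of the continuous trait
#'   (default 1).
#' @param causal_pathway index of the causal pathway (default 1).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 697, n_pathways = 168,
                       genes_per_pathway = 9, n_causal_genes = 9,
                       snps_per_gene = 4, maf_range = c(0.05, 0.5),
                       ld_rho = 0.3, effect_size = 0.5, noise_sd = 1,
                       causal_pathway = 1) {
  stopifnot(n_samples >= 2, n_pathways >= 1, genes_per_pathway >= 1,
            n_causal_genes >= 0, snps_per_gene >= 1,
            length(maf_range) == 2, maf_range[1] >= 0, maf_range[2] <= 0.5,
            ld_rho >= 0, ld_rho < 1, noise_sd >= 0,
            causal_pathway >= 1, causal_pathway <= n_pathways)
  structure(list(n_samples = n_samples, n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 n_causal_genes = n_causal_genes,
                 snps_per_gene = snps_per_gene, maf_range = maf_range,
                 ld_rho = ld_rho, effect_size = effect_size,
                 noise_sd = noise_sd, causal_pathway = causal_pathway),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: n = ", x$n_samples, ", ", x$n_pathways, " pathways, ",
      x$n_causal_genes, " causal genes in pathway ", x$causal_pathway,
      ", effect ", x$effect_size, ", noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Simulate genotype dosages alone
#'
#' Convenience wrapper around [simulate_study()] returning only the
#' [genotype_matrix] (per-gene Gaussian-copula LD, Hardy-Weinberg
#' marginals, deterministic under the seed).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return a [genotype_matrix].
#' @export
simulate_genotypes <- function(config = sim_config(), seed = 1) {
  simulate_study(config, seed = seed)$genotypes
}

# draw an n x m dosage block for one gene: two haplotype layers from a
# Gaussian copula with exchangeable correlation rho, thresholded at each
# SNP's MAF, so marginals are Binomial(2, maf) (Hardy-Weinberg)
simulate_gene_dosages <- function(n, mafs, rho) {
  m <- length(mafs)
  thr <- stats::qnorm(mafs)
  d <- matrix(0, n, m)
  for (h in 1:2) {
    f <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * m), n, m)
    lat <- sqrt(rho) * f + sqrt(1 - rho) * e
    d <- d + (lat < rep(thr, each = n))
  }
  d
}

#' Simulate a pathway-structured genotype/phenotype study
#'
#' Generates, under one seed: per-gene SNP dosages (Gaussian-copula LD
#' within genes, independent genes, Hardy-Weinberg marginals at uniform
#' MAFs), a pathway database placing the causal genes in the causal pathway,
#' gene annotation and SNP positions consistent with a 20 kb window mapping,
#' and a continuous phenotype driven additively by the standardized
#' causal-SNP dosages. The SNP-to-gene-to-pathway truth is carried directly,
#' so downstream analysis can skip positional mapping.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (required for reproducibility).
#' @return list with `genotypes` ([genotype_matrix]), `phenotype`
#'   ([phenotype_data], gaussian), `pathways` ([pathway_db]), `annotation`
#'   (gene table), `snp_genes` (truth map: `snp_id`, `gene`),
#'   `causal_pathway_id`, `causal_genes`, `causal_snps`, `config`, `seed`,
#'   and `heritability` (realized variance fraction explained by the genetic
#'   term).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples

  # pathway membership: disjoint gene sets, causal pathway first in truth
  sizes <- rep(config$genes_per_pathway, config$n_pathways)
  sizes[config$causal_pathway] <-
    max(config$n_causal_genes, config$genes_per_pathway)
  total_genes <- sum(sizes)
  gene_names <- sprintf("G%04d", seq_len(total_genes))
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  sets <- lapply(seq_len(config$n_pathways),
                 function(k) gene_names[starts[k]:stops[k]])
  names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
  pathways <- pathway_db(sets)
  causal_pathway_id <- names(sets)[config$causal_pathway]
  causal_genes <- if (config$n_causal_genes > 0)
    sets[[config$causal_pathway]][seq_len(config$n_causal_genes)]
  else character()

  # genotypes gene by gene; genes laid out 1 Mb apart on one chromosome
  m <- config$snps_per_gene
  blocks <- vector("list", total_genes)
  meta <- vector("list", total_genes)
  for (t in seq_len(total_genes)) {
    mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    blocks[[t]] <- simulate_gene_dosages(n, mafs, config$ld_rho)
    gstart <- 1e6 * t
    meta[[t]] <- data.frame(
      snp_id = sprintf("%s_snp%02d", gene_names[t], seq_len(m)),
      chrom = "1", pos = as.integer(gstart + (seq_len(m) - 1) * 500),
      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  dos <- do.call(cbind, blocks)
  snp_meta <- do.call(rbind, meta)
  g <- genotype_matrix(dos, snp_meta,
                       sample_ids = sprintf("id%05d", seq_len(n)))
  annotation <- data.frame(
    gene = gene_names, chrom = "1",
    start = as.integer(1e6 * seq_len(total_genes)),
    end = as.integer(1e6 * seq_len(total_genes) + (m - 1) * 500),
    stringsAsFactors = FALSE)
  snp_genes <- data.frame(snp_id = snp_meta$snp_id,
                          gene = rep(gene_names, each = m),
                          stringsAsFactors = FALSE)

  ph <- simulate_phenotype(g, config, snp_genes, causal_genes)

  list(genotypes = g, phenotype = ph$phenotype, pathways = pathways,
       annotation = annotation, snp_genes = snp_genes,
       causal_pathway_id = causal_pathway_id, causal_genes = causal_genes,
       causal_snps = ph$causal_snps, heritability = ph$heritability,
       config = config, seed = seed)
}

#' Simulate the continuous phenotype from causal-gene dosages
#'
#' \eqn{y_j = \sum_{s \in causal} b \cdot \tilde d_{js} + \epsilon_j},
#' with standardized dosages \eqn{\tilde d}, per-SNP effect `b =
#' config$effect_size`, and \eqn{\epsilon \sim N(0, noise\_sd^2)}. Uses the
#' current RNG state (call inside a seeded context, as [simulate_study()]
#' does).
#'
#' @param g a [genotype_matrix].
#' @param config a [sim_config()].
#' @param snp_genes truth map (`snp_id`, `gene`).
#' @param causal_genes character vector of causal gene names.
#' @return list with `phenotype` (gaussian [phenotype_data]), `causal_snps`,
#'   and realized `heritability` (genetic variance fraction).
#' @export
simulate_phenotype <- function(g, config, snp_genes, causal_genes) {
  n <- nrow(g$dosages)
  causal_snps <- snp_genes$snp_id[snp_genes$gene %in% causal_genes]
  gterm <- numeric(n)
  if (length(causal_snps) && config$effect_size != 0) {
    d <- g$dosages[, causal_snps, drop = FALSE]
    sds <- apply(d, 2, stats::sd)
    keep <- sds > 0
    if (any(keep)) {
      dstd <- scale(d[, keep, drop = FALSE])
      gterm <- drop(dstd %*% rep(config$effect_size, sum(keep)))
    }
  }
  eps <- stats::rnorm(n, 0, config$noise_sd)
  y <- gterm + eps
  h2 <- if (stats::var(y) > 0) stats::var(gterm) / stats::var(y) else 0
  list(phenotype = phenotype_data(y, "gaussian",
                                  sample_ids = g$sample_ids),
       causal_snps = causal_snps, heritability = h2)
}

#' Median dichotomization of a continuous trait
#'
#' Returns 1 where `y` is strictly above its median and 0 otherwise (ties at
#' the median go to 0), so prevalence is within one sample of one half.
#'
#' @param y continuous numeric vector.
#' @return integer 0/1 vector.
#' @examples
#' dichotomize_median(c(1, 2, 3, 4))   # 0 0 1 1
#' @export
dichotomize_median <- function(y) {
  if (length(unique(y)) < 2) stop("constant phenotype", call. = FALSE)
  as.integer(y > stats::median(y))
}

#' Build the analysis design directly from a simulated study
#'
#' Runs the per-gene PCA summarization over the simulator's truth map and
#' assembles the hierarchical design (positional SNP-to-gene mapping is
#' skipped because the truth is known).
#'
#' @param study a [simulate_study()] result.
#' @param criterion,cumvar_threshold PC-selection rule (see [select_pcs()]).
#' @param covariates optional covariate matrix.
#' @return a `hiscom_design`.
#' @export
design_from_study <- function(study, criterion = c("first_pc", "cumvar"),
                              cumvar_threshold = 0.30, covariates = NULL) {
  criterion <- match.arg(criterion)
  pcs <- summarize_genes(study$genotypes, study$snp_genes)
  build_design(pcs, study$pathways, covariates = covariates,
               criterion = criterion, cumvar_threshold = cumvar_threshold,
               sample_ids = study$genotypes$sample_ids)
}

#' Write a simulated study in the pipeline's native file formats
#'
#' Emits the PLINK trio, a GMT pathway file, the gene annotation TSV and a
#' phenotype TSV, so the simulator doubles as a fixture generator for the
#' readers.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default `"study"`).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, prefix)
  write_plink(study$genotypes, stem)
  gmt <- vapply(names(study$pathways), function(pid)
    paste(c(pid, attr(study$pathways, "descriptions")[pid],
            study$pathways[[pid]]), collapse = "\t"), "")
  writeLines(gmt, paste0(stem, ".gmt"))
  utils::write.table(study$annotation, paste0(stem, ".genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(IID = study$phenotype$sample_ids, Q1 = study$phenotype$y)
  utils::write.table(ph, paste0(stem, ".pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# shared engine for the power / type-I experiments: genotypes (and the
# design) are simulated once; each replicate redraws the phenotype, runs the
# permutation test, and records whether the tracked pathway's p < alpha
run_experiment <- function(config, replicates, alpha, track_pathway,
                           phenotype = c("continuous", "binary"), B = 99,
                           lambda_g = 1, lambda_p = 1,
                           criterion = "first_pc", cumvar_threshold = 0.30,
                           seed = 1, tol = 1e-5, max_iter = 500L) {
  phenotype <- match.arg(phenotype)
  stopifnot(replicates >= 1)
  study <- simulate_study(config, seed = seed)
  design <- design_from_study(study, criterion = criterion,
                              cumvar_threshold = cumvar_threshold)
  track_idx <- match(track_pathway, design$pathway_ids)
  if (is.na(track_idx))
    stop("tracked pathway not present in the design: ", track_pathway,
         call. = FALSE)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  p_values <- numeric(replicates)
  failed <- logical(replicates)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    ph <- simulate_phenotype(study$genotypes, config, study$snp_genes,
                             study$causal_genes)
    y <- ph$phenotype$y
    fam <- "gaussian"
    if (phenotype == "binary") {
      y <- dichotomize_median(y)
      fam <- "binomial"
    }
    res <- tryCatch(
      hiscom_permute(design, y, fam, lambda_g = lambda_g,
                     lambda_p = lambda_p, B = B, seed = rep_seeds[r],
                     tol = tol, max_iter = max_iter, gene_level = FALSE),
      error = function(e) NULL)
    if (is.null(res)) {
      failed[r] <- TRUE
      p_values[r] <- NA_real_
      next
    }
    p_values[r] <- res$pathways$p_value[track_idx]
  }
  if (sum(failed) > 0.05 * replicates)
    stop("more than 5% of replicates failed (", sum(failed), "/",
         replicates, ")", call. = FALSE)
  ok <- !failed
  rejections <- sum(p_values[ok] < alpha)
  estimate <- rejections / sum(ok)
  structure(list(replicates = sum(ok), n_failed = sum(failed),
                 rejections = rejections, estimate = estimate,
                 se = sqrt(estimate * (1 - estimate) / sum(ok)),
                 alpha = alpha, p_values = p_values,
                 tracked_pathway = track_pathway, phenotype = phenotype,
                 B = B, config = config, seed = seed),
            class = "hiscom_experiment")
}

#' Empirical power experiment
#'
#' Monte-Carlo estimate of the probability that the causal pathway's
#' permutation p-value falls below `alpha`. Genotypes and the pathway
#' structure are simulated once; each replicate redraws the phenotype from
#' the causal model (optionally median-dichotomized), reruns the full
#' fit-plus-permutation analysis, and records a rejection.
#'
#' @param config a [sim_config()] with nonzero causal effects.
#' @param replicates number of Monte-Carlo replicates (default 200).
#' @param alpha rejection threshold on the permutation p-value (default
#'   0.05, strict `<`).
#' @param phenotype `"continuous"` (gaussian analysis) or `"binary"`
#'   (median-dichotomized, binomial analysis).
#' @param B permutations per replicate (default 99).
#' @param lambda_g,lambda_p ridge penalties used in every fit (default 1).
#' @param criterion,cumvar_threshold PC-selection rule.
#' @param seed master seed; all replicate and permutation seeds derive from
#'   it.
#' @param tol,max_iter passed to [hiscom()] (iteration cap default 500: the
#'   null-permutation refits at the experiment scales need longer ALS runs).
#' @return An object of class `hiscom_experiment`: `estimate`
#'   (rejections/replicates), `se`, `rejections`, `replicates`,
#'   `p_values`, `tracked_pathway`, `config`.
#' @export
run_power_experiment <- function(config, replicates = 200, alpha = 0.05,
                                 phenotype = c("continuous", "binary"),
                                 B = 99, lambda_g = 1, lambda_p = 1,
                                 criterion = "first_pc",
                                 cumvar_threshold = 0.30, seed = 1,
                                 tol = 1e-5, max_iter = 500L) {
  if (config$effect_size == 0 || config$n_causal_genes == 0)
    warning("power experiment requested with zero causal effects",
            call. = FALSE)
  causal_id <- sprintf("PW%03d", config$causal_pathway)
  run_experiment(config, replicates, alpha, causal_id,
                 phenotype = match.arg(phenotype), B = B,
                 lambda_g = lambda_g, lambda_p = lambda_p,
                 criterion = criterion, cumvar_threshold = cumvar_threshold,
                 seed = seed, tol = tol, max_iter = max_iter)
}

#' Empirical type-I-error experiment
#'
#' Identical machinery to [run_power_experiment()], but the tracked pathway
#' is a null pathway containing no causal gene whose gene count matches the
#' causal pathway's (size-matched), while any causal effects stay active
#' elsewhere. With `config$effect_size = 0` this is the fully-null
#' calibration variant.
#'
#' @inheritParams run_power_experiment
#' @param null_pathway index of the tracked null pathway; by default the
#'   first non-causal pathway whose gene count equals the causal pathway's.
#' @return An object of class `hiscom_experiment`.
#' @export
run_type1_experiment <- function(config, replicates = 200, alpha = 0.05,
                                 phenotype = c("continuous", "binary"),
                                 B = 99, lambda_g = 1, lambda_p = 1,
                                 criterion = "first_pc",
                                 cumvar_threshold = 0.30, seed = 1,
                                 tol = 1e-5, max_iter = 500L,
                                 null_pathway = NULL) {
  sizes <- rep(config$genes_per_pathway, config$n_pathways)
  sizes[config$causal_pathway] <-
    max(config$n_causal_genes, config$genes_per_pathway)
  if (is.null(null_pathway)) {
    cand <- setdiff(which(sizes == sizes[config$causal_pathway]),
                    config$causal_pathway)
    if (!length(cand))
      stop("no size-matched null pathway exists; supply null_pathway",
           call. = FALSE)
    null_pathway <- cand[1]
  }
  if (null_pathway == config$causal_pathway)
    stop("null_pathway must differ from the causal pathway", call. = FALSE)
  run_experiment(config, replicates, alpha,
                 sprintf("PW%03d", null_pathway),
                 phenotype = match.arg(phenotype), B = B,
                 lambda_g = lambda_g, lambda_p = lambda_p,
                 criterion = criterion, cumvar_threshold = cumvar_threshold,
                 seed = seed, tol = tol, max_iter = max_iter)
}

#' @export
print.hiscom_experiment <- function(x, ...) {
  cat("hiscom_experiment: ", x$replicates, " replicates, B = ", x$B,
      ", alpha = ", x$alpha, ", ", x$phenotype, " phenotype\n", sep = "")
  cat("tracked pathway ", x$tracked_pathway, ": rejection rate ",
      format(x$estimate, digits = 4), " (MC se ",
      format(x$se, digits = 3), ")\n", sep = "")
  invisible(x)
}
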