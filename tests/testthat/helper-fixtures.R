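# Shared fixture builders and independent oracles.

# hand-built hierarchical design from raw score columns
toy_design <- function(Z, k_index, pathway_ids = NULL, covariates = NULL,
                       genes = NULL) {
  Z <- as.matrix(Z)
  K <- max(k_index)
  if (is.null(pathway_ids)) pathway_ids <- paste0("PW", seq_len(K))
  if (is.null(genes)) genes <- paste0("G", seq_along(k_index))
  index <- data.frame(k = as.integer(k_index),
                      pathway_id = pathway_ids[k_index],
                      gene = genes,
                      pc = 1L, stringsAsFactors = FALSE)
  colnames(Z) <- paste(index$pathway_id, index$gene, "PC1", sep = "|")
  n <- nrow(Z)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  structure(list(Z = Z, index = index, pathway_ids = pathway_ids,
                 covariates = as.matrix(covariates),
                 sample_ids = paste0("s", seq_len(n))),
            class = "hiscom_design")
}

# random multi-pathway design: one PC column per gene, standardized normals
random_design <- function(n, K, genes_per_pathway = 4, seed = 1,
                          covariates = 0) {
  set.seed(seed)
  P <- K * genes_per_pathway
  Z <- scale(matrix(rnorm(n * P), n, P))
  X <- if (covariates > 0) matrix(rnorm(n * covariates), n, covariates)
       else NULL
  toy_design(Z, rep(seq_len(K), each = genes_per_pathway), covariates = X)
}

# small genotype matrix with explicit dosages
toy_genotypes <- function(dosages, chrom = "1", pos = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosages,
                  data.frame(snp_id = paste0("rs", seq_len(m)),
                             chrom = chrom, pos = pos,
                             a1 = "A", a2 = "G", stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# HWE exact p-value by direct log-factorial enumeration over all
# heterozygote counts compatible with the observed allele totals
hwe_oracle <- function(a, h, b) {
  n <- a + h + b
  n_rare <- 2 * min(a, b) + h
  if (n_rare == 0) return(1)
  het_max <- min(n_rare, 2 * n - n_rare)
  hets <- seq(n_rare %% 2, het_max, by = 2)
  logp <- vapply(hets, function(hh) {
    rare_hom <- (n_rare - hh) / 2
    common_hom <- n - hh - rare_hom
    lfactorial(n) - lfactorial(rare_hom) - lfactorial(hh) -
      lfactorial(common_hom) + hh * log(2)
  }, numeric(1))
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  obs <- match(h, hets)
  min(1, sum(p_all[p_all <= p_all[obs] * (1 + 1e-9)]))
}

# Benjamini-Hochberg by the brute-force running-minimum definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(p[ord][js] * m / js)
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# minimal PLINK-shaped file trio around a raw BED byte body
write_plink_fixture <- function(prefix, bed_bytes, n_samples, snp_ids,
                                pos = NULL) {
  m <- length(snp_ids)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  writeBin(bed_bytes, paste0(prefix, ".bed"))
  writeLines(paste("1", snp_ids, 0, pos, "A", "G", sep = "\t"),
             paste0(prefix, ".bim"))
  ids <- paste0("s", seq_len(n_samples))
  writeLines(paste(ids, ids, 0, 0, 0, -9, sep = "\t"),
             paste0(prefix, ".fam"))
  prefix
}
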