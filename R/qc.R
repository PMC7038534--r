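#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact HWE test: conditional on the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Probabilities are
#' computed by the stable Wigginton-style recurrence over heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate).
#' @return Exact p-value in (0, 1]. A monomorphic SNP (one allele absent)
#'   returns 1 by convention.
#' @examples
#' hwe_exact_test(57, 14, 50)   # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)

  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0L) return(1)                       # monomorphic

  # feasible heterozygote counts share the parity of the rare-allele count
  het_max <- min(n_rare, 2L * n - n_rare)
  hets <- seq.int(n_rare %% 2L, het_max, by = 2L)

  # unnormalized probabilities by downward recurrence from het_max:
  # P(h-2)/P(h) = h(h-1) / (4 (rare_hom(h)+1)(common_hom(h)+1))
  probs <- numeric(length(hets))
  probs[length(hets)] <- 1
  for (i in rev(seq_along(hets))[-1]) {
    h <- hets[i + 1L]
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (rare_hom + 1) * (common_hom + 1))
  }
  probs <- probs / sum(probs)

  obs <- match(n_het, hets)
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-9)])
  min(p, 1)
}

#' SNP-level quality control
#'
#' Removes SNPs failing, in this fixed attribution order: genotype call rate
#' below `call_rate_min`, minor allele frequency at or below
#' `maf_max_excluded` (the boundary itself is excluded), or exact HWE p-value
#' below `hwe_p_min`. MAF and HWE use non-missing genotypes only.
#'
#' @param g a [genotype_matrix].
#' @param maf_max_excluded MAF threshold; SNPs with MAF <= this are removed
#'   (default 0.05).
#' @param call_rate_min minimum genotype call rate (default 0.95, removal is
#'   strict `<`).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6, removal strict
#'   `<`).
#' @param hwe_samples optional logical/integer index restricting the samples
#'   used for the HWE test (e.g. controls only); default all samples.
#' @return list with `genotypes` (filtered [genotype_matrix]) and `report`
#'   (a `qc_report`).
#' @export
snp_qc <- function(g, maf_max_excluded = 0.05, call_rate_min = 0.95,
                   hwe_p_min = 1e-6, hwe_samples = NULL) {
  d <- g$dosages
  if (!ncol(d) || !nrow(d)) stop("empty genotype matrix", call. = FALSE)
  n <- nrow(d)

  call_rate <- colMeans(!is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)

  dh <- if (is.null(hwe_samples)) d else d[hwe_samples, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(dh)), function(j) {
    x <- dh[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))

  fail_cr <- call_rate < call_rate_min
  fail_maf <- !fail_cr & maf <= maf_max_excluded
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep))
    stop("all SNPs removed by QC", call. = FALSE)

  report <- qc_report(
    n_snps_in = ncol(d), n_snps_out = sum(keep),
    n_samples_in = n, n_samples_out = n,
    removed = c(snp_call_rate = sum(fail_cr), maf = sum(fail_maf),
                hwe = sum(fail_hwe), sample_call_rate = 0L),
    thresholds = list(maf_max_excluded = maf_max_excluded,
                      call_rate_min = call_rate_min, hwe_p_min = hwe_p_min))
  list(genotypes = subset_genotypes(g, snps = which(keep)), report = report)
}

#' Sample-level quality control
#'
#' Keeps samples whose genotype call rate is strictly greater than
#' `call_rate_min`.
#'
#' @param g a [genotype_matrix].
#' @param call_rate_min minimum call rate; samples at or below it are removed
#'   (default 0.90).
#' @param exclude optional character vector of sample ids to drop first
#'   (e.g. a precomputed sex-inconsistency exclusion list).
#' @return list with `genotypes` and `report` as in [snp_qc()].
#' @export
sample_qc <- function(g, call_rate_min = 0.90, exclude = NULL) {
  d <- g$dosages
  if (!nrow(d)) stop("empty genotype matrix", call. = FALSE)
  pre_keep <- !(g$sample_ids %in% exclude)
  call_rate <- rowMeans(!is.na(d))
  keep <- pre_keep & call_rate > call_rate_min
  if (!any(keep)) stop("all samples removed by QC", call. = FALSE)

  report <- qc_report(
    n_snps_in = ncol(d), n_snps_out = ncol(d),
    n_samples_in = nrow(d), n_samples_out = sum(keep),
    removed = c(snp_call_rate = 0L, maf = 0L, hwe = 0L,
                sample_call_rate = sum(pre_keep & !keep),
                excluded_list = sum(!pre_keep)),
    thresholds = list(sample_call_rate_min = call_rate_min))
  list(genotypes = subset_genotypes(g, samples = which(keep)),
       report = report)
}

qc_report <- function(n_snps_in, n_snps_out, n_samples_in, n_samples_out,
                      removed, thresholds) {
  structure(list(n_snps_in = n_snps_in, n_snps_out = n_snps_out,
                 n_samples_in = n_samples_in, n_samples_out = n_samples_out,
                 removed = removed, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: SNPs ", x$n_snps_in, " -> ", x$n_snps_out,
      "; samples ", x$n_samples_in, " -> ", x$n_samples_out, "\n", sep = "")
  rem <- x$removed[x$removed > 0]
  if (length(rem))
    cat("removed:", paste(names(rem), rem, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Mean-dosage imputation of residual missing genotypes
#'
#' Replaces each missing dosage by the per-SNP mean of the non-missing
#' dosages (a continuous value; downstream PCA accepts continuous dosages).
#'
#' @param g a [genotype_matrix], post-QC.
#' @return A `genotype_matrix`-shaped object with no missing values. Because
#'   imputed dosages are continuous the strict \{0,1,2\} invariant is relaxed
#'   on the result (class `genotype_matrix`, imputed flag set).
#' @export
impute_missing <- function(g) {
  d <- g$dosages
  if (!anyNA(d)) return(g)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("SNP with no observed genotypes; run snp_qc first", call. = FALSE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- g
  out$dosages <- d
  attr(out, "imputed") <- TRUE
  out
}
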