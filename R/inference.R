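#' Permutation test for pathway and gene effects
#'
#' The observed statistic for pathway k is \eqn{|\beta_k|} from the fit on
#' the unpermuted phenotype; the gene-level statistic is
#' \eqn{\max_i |w_{kti}\beta_k|} over the gene's PC columns within its
#' pathway. For each of `B` replicates the phenotype vector is permuted
#' uniformly at random (covariate rows are not permuted), the full model is
#' refitted from the deterministic equal-weight start with identical
#' configuration, and the permuted statistics are recorded. Empirical
#' p-values use the add-one estimator \eqn{p = (1 + \#\{|stat^{(b)}| \ge
#' |stat|\}) / (B + 1)}; Benjamini-Hochberg q-values are attached.
#'
#' Permuted refits that fail to converge are counted and excluded; more than
#' 5\% failures is an error.
#'
#' @inheritParams hiscom
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutations (default 1).
#' @param gene_level also compute the per-gene table (default `TRUE`).
#' @param scheme `"phenotype"` permutes the raw phenotype (the default);
#'   `"freedman_lane"` (gaussian only) permutes residuals from the
#'   covariate-only model and adds back its fitted values, for
#'   covariate-confounded designs.
#' @param permutations optional integer matrix (n x B) of explicit
#'   permutations, overriding the RNG (used for reproducibility checks).
#' @return An object of class `hiscom_perm`: list with `pathways` and
#'   `genes` data frames (id, statistic/coefficient, permutation count,
#'   `p_value`, `q_value`), the observed `fit`, `B`, `B_used`, `n_failed`,
#'   `seed`.
#' @export
hiscom_permute <- function(design, y, family = c("gaussian", "binomial"),
                           lambda_g = 1, lambda_p = 1, B = 1000, seed = 1,
                           tol = 1e-5, max_iter = 500L, gene_level = TRUE,
                           scheme = c("phenotype", "freedman_lane"),
                           permutations = NULL) {
  if (inherits(y, "phenotype_data")) {
    family <- y$family
    y <- y$y
  } else {
    family <- match.arg(family)
  }
  scheme <- match.arg(scheme)
  if (scheme == "freedman_lane" && family != "gaussian")
    stop("freedman_lane permutation is implemented for the gaussian family",
         call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  n <- length(y)

  refit <- function(yy) {
    suppressWarnings(
      hiscom(design, yy, family, lambda_g = lambda_g, lambda_p = lambda_p,
             tol = tol, max_iter = max_iter, init = "equal"))
  }
  fit <- refit(y)
  idx <- fit$design$index
  obs_path <- abs(fit$beta)
  gene_key <- paste(idx$pathway_id, idx$gene, sep = "\r")
  gene_stat <- function(f) {
    contrib <- abs(f$weights * f$beta[idx$k])
    as.numeric(tapply(contrib, gene_key, max)[unique(gene_key)])
  }
  obs_gene <- if (gene_level) gene_stat(fit) else NULL

  if (scheme == "freedman_lane") {
    Xc <- cbind(1, design$covariates)
    qr_ <- qr(Xc)
    base_fit <- drop(Xc %*% qr.coef(qr_, y))
    base_res <- y - base_fit
  }

  if (is.null(permutations)) {
    if (!is.null(seed)) set.seed(seed)
    permutations <- replicate(B, sample.int(n))
  } else {
    permutations <- as.matrix(permutations)
    B <- ncol(permutations)
  }

  cnt_path <- numeric(length(obs_path))
  cnt_gene <- if (gene_level) numeric(length(obs_gene)) else NULL
  n_failed <- 0L
  for (b in seq_len(B)) {
    perm <- permutations[, b]
    yy <- if (scheme == "phenotype") y[perm] else base_fit + base_res[perm]
    fb <- refit(yy)
    if (!fb$converged) {
      n_failed <- n_failed + 1L
      next
    }
    cnt_path <- cnt_path + (abs(fb$beta) >= obs_path)
    if (gene_level) cnt_gene <- cnt_gene + (gene_stat(fb) >= obs_gene)
  }
  if (n_failed > 0.05 * B)
    stop("more than 5% of permuted refits failed to converge (",
         n_failed, "/", B, ")", call. = FALSE)
  B_used <- B - n_failed

  p_path <- (1 + cnt_path) / (B_used + 1)
  pathways <- data.frame(pathway_id = names(fit$beta),
                         coefficient = as.numeric(fit$beta),
                         statistic = as.numeric(obs_path),
                         count_ge = as.integer(cnt_path),
                         p_value = p_path,
                         q_value = bh_fdr(p_path),
                         row.names = NULL, stringsAsFactors = FALSE)
  genes <- NULL
  if (gene_level) {
    keys <- unique(gene_key)
    split_keys <- strsplit(keys, "\r", fixed = TRUE)
    p_gene <- (1 + cnt_gene) / (B_used + 1)
    genes <- data.frame(pathway_id = vapply(split_keys, `[[`, "", 1L),
                        gene = vapply(split_keys, `[[`, "", 2L),
                        statistic = as.numeric(obs_gene),
                        count_ge = as.integer(cnt_gene),
                        p_value = p_gene,
                        q_value = bh_fdr(p_gene),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(pathways = pathways, genes = genes, fit = fit,
                 B = B, B_used = B_used, n_failed = n_failed, seed = seed,
                 scheme = scheme),
            class = "hiscom_perm")
}

#' @export
print.hiscom_perm <- function(x, ...) {
  cat("hiscom_perm: ", nrow(x$pathways), " pathways, B = ", x$B, sep = "")
  if (x$n_failed > 0) cat(" (", x$n_failed, " failed refits excluded)")
  cat("\n")
  top <- x$pathways[order(x$pathways$p_value), ]
  print(utils::head(top[, c("pathway_id", "coefficient", "p_value",
                            "q_value")], 10),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: for p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped back
#' to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select significant pathways
#'
#' @param result a `hiscom_perm` object.
#' @param alpha significance threshold (strict `<`).
#' @param corrected use BH q-values instead of nominal p-values.
#' @return the selected rows of the pathway table, in input order.
#' @export
significant_pathways <- function(result, alpha = 0.05, corrected = FALSE) {
  stopifnot(inherits(result, "hiscom_perm"))
  tab <- result$pathways
  keep <- if (corrected) tab$q_value < alpha else tab$p_value < alpha
  tab[keep, , drop = FALSE]
}
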