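#' Map SNPs to genes by a window rule
#'
#' A SNP is assigned to a gene when it lies on the same chromosome and its
#' position falls inside the gene body extended by `window_bp` on both sides
#' (both boundaries inclusive). A SNP may map to several overlapping genes;
#' unmapped SNPs are counted but silently dropped from the map.
#'
#' @param snp_meta data frame with columns `snp_id`, `chrom`, `pos` (as in a
#'   [genotype_matrix]).
#' @param annotation gene annotation data frame (`gene`, `chrom`, `start`,
#'   `end`; 1-based, end inclusive), e.g. from [read_gene_annotation()].
#' @param window_bp flanking window in base pairs (default 20000).
#' @return data frame with columns `snp_id`, `gene`; attribute `n_unmapped`
#'   holds the number of SNPs mapping to no gene.
#' @export
map_snps_to_genes <- function(snp_meta, annotation, window_bp = 20000) {
  annotation <- validate_gene_annotation(annotation)
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(snp_meta$chrom),
    ranges = IRanges::IRanges(start = snp_meta$pos, width = 1))
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(
      start = pmax(1L, annotation$start - window_bp),
      end = annotation$end + window_bp))
  hits <- GenomicRanges::findOverlaps(snps, genes)
  map <- data.frame(
    snp_id = snp_meta$snp_id[S4Vectors::queryHits(hits)],
    gene = annotation$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  attr(map, "n_unmapped") <-
    nrow(snp_meta) - length(unique(S4Vectors::queryHits(hits)))
  attr(map, "window_bp") <- window_bp
  map
}

#' Per-gene PCA of SNP dosages
#'
#' Standardizes the gene's dosage columns (center, and by default scale to
#' unit variance) and decomposes them by singular value decomposition via
#' [stats::prcomp()]. Constant (zero-variance) columns are dropped first with
#' a warning; a gene whose columns are all constant yields `NULL`. PC signs
#' are fixed deterministically: the loading of largest absolute value in each
#' PC is made positive.
#'
#' @param x dosage submatrix for one gene (samples x SNPs), no missing
#'   values.
#' @param scale. scale columns to unit variance before PCA (default `TRUE`).
#' @return list with `scores` (samples x PCs, columns mean-zero), `loadings`
#'   (SNPs x PCs), `var_prop` (variance proportions, descending, summing to
#'   1), `n_snps`; or `NULL` for an all-constant gene.
#' @export
gene_pca <- function(x, scale. = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("gene dosage matrix contains missing values; impute first",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant SNP column(s) before PCA",
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!ncol(x)) {
    warning("gene has no variable SNPs; dropped", call. = FALSE)
    return(NULL)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # deterministic sign: largest-|loading| entry positive in each PC
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_prop <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_prop = var_prop,
       n_snps = ncol(x))
}

#' Number of PCs to retain for a gene
#'
#' Two criteria: `"first_pc"` always keeps one PC; `"cumvar"` keeps the
#' smallest leading set of PCs whose cumulative variance proportion strictly
#' exceeds `cumvar_threshold`.
#'
#' @param entry a [gene_pca()] result.
#' @param criterion `"first_pc"` or `"cumvar"`.
#' @param cumvar_threshold cumulative variance proportion to exceed (default
#'   0.30).
#' @return integer, the number of PCs selected (always >= 1).
#' @examples
#' e <- list(var_prop = c(0.2, 0.15, 0.65))
#' select_pcs(e, "cumvar")   # 2: 0.35 > 0.30
#' @export
select_pcs <- function(entry, criterion = c("first_pc", "cumvar"),
                       cumvar_threshold = 0.30) {
  criterion <- match.arg(criterion)
  if (criterion == "first_pc") return(1L)
  cum <- cumsum(entry$var_prop)
  which(cum > cumvar_threshold)[1]
}

#' Assemble the hierarchical pathway design
#'
#' Lays out the selected per-gene PC score columns into pathway blocks: for
#' pathway k with genes t = 1..T_k, the design holds the N_kt selected PCs of
#' each gene. A gene belonging to several pathways contributes its columns
#' independently to each pathway block (weights are pathway-specific).
#' Pathways retaining no gene with PCs are dropped with a message.
#'
#' @param pc_sets named list (gene symbol -> [gene_pca()] entry, `NULL`
#'   entries allowed) with an `n_selected` element per entry, or pass
#'   `n_selected` via `criterion`.
#' @param pathways a [pathway_db].
#' @param covariates optional numeric matrix of unpenalized covariates
#'   (samples x c).
#' @param criterion,cumvar_threshold PC-selection rule applied to each entry
#'   (see [select_pcs()]).
#' @param sample_ids optional character vector of row identities.
#' @return An object of class `hiscom_design`: list with `Z` (samples x
#'   total selected PCs), `index` (data frame: `k`, `pathway_id`, `gene`,
#'   `pc` per column), `pathway_ids`, `covariates`, `sample_ids`.
#' @export
build_design <- function(pc_sets, pathways, covariates = NULL,
                         criterion = c("first_pc", "cumvar"),
                         cumvar_threshold = 0.30, sample_ids = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(pathways, "pathway_db"))
  pc_sets <- pc_sets[!vapply(pc_sets, is.null, logical(1))]
  if (!length(pc_sets)) stop("no genes with PCs", call. = FALSE)

  cols <- list()
  idx <- list()
  kept <- character()
  k <- 0L
  for (pid in names(pathways)) {
    genes <- intersect(pathways[[pid]], names(pc_sets))
    if (!length(genes)) {
      message("dropping pathway with no summarized genes: ", pid)
      next
    }
    k <- k + 1L
    kept <- c(kept, pid)
    for (gene in genes) {
      entry <- pc_sets[[gene]]
      m <- select_pcs(entry, criterion, cumvar_threshold)
      m <- min(m, ncol(entry$scores))
      cols[[length(cols) + 1L]] <- entry$scores[, seq_len(m), drop = FALSE]
      idx[[length(idx) + 1L]] <- data.frame(
        k = k, pathway_id = pid, gene = gene, pc = seq_len(m),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) stop("empty design: no pathway retained any gene",
                          call. = FALSE)
  Z <- do.call(cbind, cols)
  index <- do.call(rbind, idx)
  colnames(Z) <- paste(index$pathway_id, index$gene,
                       paste0("PC", index$pc), sep = "|")
  n <- nrow(Z)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n)
    stop("covariate rows must match the number of samples", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(Z)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))

  structure(list(Z = Z, index = index, pathway_ids = kept,
                 covariates = covariates, sample_ids = sample_ids),
            class = "hiscom_design")
}

#' @export
print.hiscom_design <- function(x, ...) {
  cat("hiscom_design: ", nrow(x$Z), " samples, ",
      length(x$pathway_ids), " pathways, ",
      length(unique(paste(x$index$k, x$index$gene))), " gene slots, ",
      ncol(x$Z), " PC columns, ", ncol(x$covariates), " covariate(s)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.hiscom_design <- function(x) dim(x$Z)

# row-subset a design (used by cross-validation)
design_subset <- function(design, rows) {
  out <- design
  out$Z <- design$Z[rows, , drop = FALSE]
  out$covariates <- design$covariates[rows, , drop = FALSE]
  out$sample_ids <- design$sample_ids[rows]
  out
}

#' Per-gene PCA over a genotype matrix
#'
#' Runs [gene_pca()] on every gene of a SNP-to-gene map and returns the
#' named list of per-gene PC sets consumed by [build_design()].
#'
#' @param g a [genotype_matrix] without missing values (post-imputation).
#' @param snp_gene_map data frame (`snp_id`, `gene`), e.g. from
#'   [map_snps_to_genes()].
#' @param scale. standardize dosages before PCA (default `TRUE`).
#' @return named list of [gene_pca()] entries (`NULL` for dropped genes).
#' @export
summarize_genes <- function(g, snp_gene_map, scale. = TRUE) {
  d <- g$dosages
  genes <- unique(snp_gene_map$gene)
  sets <- lapply(genes, function(gn) {
    snps <- snp_gene_map$snp_id[snp_gene_map$gene == gn]
    snps <- intersect(snps, colnames(d))
    if (!length(snps)) return(NULL)
    gene_pca(d[, snps, drop = FALSE], scale. = scale.)
  })
  names(sets) <- genes
  sets
}
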