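#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format (one gene set per line: id,
#' description, then member genes). Pathway order follows the file; genes
#' repeated within a line are deduplicated.
#'
#' @param path path to a `.gmt` file.
#' @return An object of class `pathway_db`: a named list of character vectors
#'   of gene symbols, with a `descriptions` attribute (named character
#'   vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(pathway_db(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT parse error at line ", which(nf < 3)[1],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  names(desc) <- ids
  pathway_db(sets, desc)
}

#' Pathway gene-set collection
#'
#' @param sets named list: pathway id -> character vector of gene symbols.
#' @param descriptions optional named character vector of descriptions.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("pathway ids must be present and unique", call. = FALSE)
    if (any(lengths(sets) == 0))
      stop("gene sets must be non-empty", call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("pathway_db: ", length(x), " pathways, ",
      length(unique(unlist(x))), " distinct genes\n", sep = "")
  invisible(x)
}

#' Read a phenotype/covariate table
#'
#' Reads a TSV with a header and a sample-id column, extracts the phenotype
#' and any covariates, drops samples with a missing phenotype, and validates
#' (optionally recodes) a binomial phenotype to \{0, 1\}.
#'
#' @param path TSV file with header.
#' @param pheno_col name of the phenotype column.
#' @param covar_cols character vector of covariate column names (may be
#'   empty).
#' @param family `"gaussian"` or `"binomial"`.
#' @param id_col name of the sample-id column (default `"IID"`).
#' @param recode optional length-2 vector mapping the raw codes of a binomial
#'   phenotype to 0 and 1, e.g. `c(1, 2)` for PLINK-style control/case.
#' @return An object of class `phenotype_data`: list with `y`, `family`,
#'   `covariates` (numeric matrix, 0 columns allowed), `covariate_names`,
#'   `sample_ids`, and `n_dropped` (missing-phenotype rows removed).
#' @export
read_phenotype_table <- function(path, pheno_col, covar_cols = character(),
                                 family = c("gaussian", "binomial"),
                                 id_col = "IID", recode = NULL) {
  family <- match.arg(family)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, pheno_col, covar_cols))
    if (!col %in% names(tab))
      stop("column not found in ", path, ": ", col, call. = FALSE)

  keep <- !is.na(tab[[pheno_col]])
  n_dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  y <- tab[[pheno_col]]

  if (family == "binomial") {
    if (!is.null(recode)) {
      if (!all(y %in% recode))
        stop("binomial phenotype contains values outside the recode map",
             call. = FALSE)
      y <- as.numeric(y == recode[2])
    }
    if (!all(y %in% c(0, 1)))
      stop("binomial phenotype must be coded {0,1} (or supply `recode`)",
           call. = FALSE)
  }
  y <- as.numeric(y)

  covariates <- matrix(numeric(0), nrow = length(y), ncol = 0)
  if (length(covar_cols)) {
    covariates <- as.matrix(tab[, covar_cols, drop = FALSE])
    storage.mode(covariates) <- "double"
    sds <- apply(covariates, 2, stats::sd)
    if (any(sds == 0))
      warning("constant covariate column(s): ",
              paste(covar_cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  phenotype_data(y, family, covariates, covar_cols,
                 sample_ids = as.character(tab[[id_col]]),
                 n_dropped = n_dropped)
}

#' Phenotype + covariates container
#'
#' @param y numeric phenotype vector (0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param covariates numeric matrix aligned with `y` (0 columns allowed).
#' @param covariate_names character vector.
#' @param sample_ids character vector aligned with `y`.
#' @param n_dropped count of rows dropped for missing phenotype.
#' @return An object of class `phenotype_data`.
#' @export
phenotype_data <- function(y, family = c("gaussian", "binomial"),
                           covariates = NULL, covariate_names = character(),
                           sample_ids = NULL, n_dropped = 0L) {
  family <- match.arg(family)
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial phenotype must be coded {0,1}", call. = FALSE)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = length(y), ncol = 0)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(y))
    stop("covariate rows must align with the phenotype", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(y))
  structure(list(y = y, family = family, covariates = covariates,
                 covariate_names = covariate_names,
                 sample_ids = as.character(sample_ids),
                 n_dropped = as.integer(n_dropped)),
            class = "phenotype_data")
}

#' @export
print.phenotype_data <- function(x, ...) {
  cat("phenotype_data: n = ", length(x$y), ", family = ", x$family,
      ", ", ncol(x$covariates), " covariate(s)", sep = "")
  if (x$n_dropped > 0) cat(" [", x$n_dropped, " dropped: missing phenotype]")
  cat("\n")
  invisible(x)
}

#' Align genotypes and phenotypes on shared sample ids
#'
#' Intersects the two sample-id sets and reorders both objects so that row i
#' refers to the same sample everywhere downstream.
#'
#' @param g a [genotype_matrix].
#' @param ph a [phenotype_data].
#' @return list with elements `genotypes` and `phenotype`, both restricted to
#'   the shared samples in genotype order.
#' @export
align_samples <- function(g, ph) {
  common <- intersect(g$sample_ids, ph$sample_ids)
  if (!length(common)) stop("no shared sample ids", call. = FALSE)
  gi <- match(common, g$sample_ids)
  pi_ <- match(common, ph$sample_ids)
  ph2 <- phenotype_data(ph$y[pi_], ph$family,
                        ph$covariates[pi_, , drop = FALSE],
                        ph$covariate_names, sample_ids = common,
                        n_dropped = ph$n_dropped)
  list(genotypes = subset_genotypes(g, samples = gi), phenotype = ph2)
}

#' Read a gene annotation table
#'
#' Four tab-separated columns with header: gene, chrom, start, end (1-based,
#' end inclusive).
#'
#' @param path TSV path.
#' @return data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(ann)[1:4] <- c("gene", "chrom", "start", "end")
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (!nrow(ann)) stop("empty gene annotation", call. = FALSE)
  if (any(ann$start > ann$end))
    stop("gene annotation has start > end", call. = FALSE)
  if (anyDuplicated(paste(ann$gene, ann$chrom)))
    stop("gene symbols must be unique per chromosome", call. = FALSE)
  ann
}

#' Write permutation-test results as TSV
#'
#' One row per pathway (and, when gene-level results are present, a companion
#' `<path>.genes.tsv` with one row per gene-in-pathway), in input pathway
#' order: id, coefficient/statistic, p-value, BH q-value.
#'
#' @param result a `hiscom_perm` object from [hiscom_permute()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "hiscom_perm"))
  pw <- result$pathways
  if (!nrow(pw)) stop("empty result", call. = FALSE)
  utils::write.table(pw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$genes)) {
    gpath <- sub("\\.tsv$", "", path)
    utils::write.table(result$genes, paste0(gpath, ".genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
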