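#' Genotype dosage matrix
#'
#' Container for a samples-by-SNPs matrix of allele dosages together with the
#' per-SNP metadata needed downstream (chromosome, base-pair position,
#' alleles). Dosages count copies of the A1 allele, so every non-missing entry
#' is 0, 1 or 2; missing genotypes are `NA` (never 0, which is a valid
#' dosage).
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns. Row names
#'   (sample ids) and column names (SNP ids) are taken from the matrix when
#'   present.
#' @param snp_meta data frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   bp), `a1` (counted allele), `a2`; one row per SNP column.
#' @param sample_ids character vector of unique sample identifiers.
#' @param sample_sex optional integer vector (1 = male, 2 = female, NA =
#'   unknown), PLINK FAM coding.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snp_meta`, `sample_ids`, `sample_sex`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'                             dimnames = list(c("s1", "s2"), c("rs1", "rs2"))),
#'                      data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                                 pos = c(100L, 200L), a1 = "A", a2 = "G"))
#' g
#' @export
genotype_matrix <- function(dosages, snp_meta,
                            sample_ids = rownames(dosages),
                            sample_sex = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)

  if (nrow(snp_meta) != ncol(dosages))
    stop("snp_meta must have one row per SNP column", call. = FALSE)
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss))
    stop("snp_meta is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length must equal the number of rows", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique", call. = FALSE)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  if (any(snp_meta$pos < 1))
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  if (!is.null(sample_sex) && length(sample_sex) != length(sample_ids))
    stop("sample_sex length mismatch", call. = FALSE)

  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$snp_id
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 sample_ids = sample_ids, sample_sex = sample_sex),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat("genotype_matrix: ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " SNPs", sep = "")
  if (nmiss > 0)
    cat(" (", nmiss, " missing genotypes)", sep = "")
  cat("\nchromosomes: ", paste(unique(x$snp_meta$chrom), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# subset a genotype_matrix by sample and/or SNP index
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  d <- g$dosages
  ids <- g$sample_ids
  sex <- g$sample_sex
  meta <- g$snp_meta
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
    if (!is.null(sex)) sex <- sex[samples]
  }
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
    rownames(meta) <- NULL
  }
  genotype_matrix(d, meta, ids, sex)
}

# ---------------------------------------------------------------------------
# PLINK binary (BED v1.00, SNP-major) reader / writer.
#
# Encoding, per SNP, packed 4 genotypes per byte starting at the low bits:
#   00 -> homozygous A1 (dosage 2),  01 -> missing,
#   10 -> heterozygous  (dosage 1),  11 -> homozygous A2 (dosage 0).
# The counted allele is BIM A1.
# ---------------------------------------------------------------------------

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# two-bit code -> dosage of A1; index by code + 1
.bed_code_to_dosage <- c(2, NA, 1, 0)

#' Read PLINK binary genotypes
#'
#' Reads a PLINK 1 binary fileset (BED/BIM/FAM, SNP-major BED v1.00) into a
#' [genotype_matrix]. Dosages count copies of the BIM A1 allele; the PLINK
#' missing genotype code becomes `NA`.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. `bim_path` and
#'   `fam_path` default to the `.bed` path with the extension swapped.
#' @return A [genotype_matrix].
#' @seealso [write_plink()]
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  names(fam) <- c("fid", "iid", "father", "mother", "sex", "pheno")

  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("not a PLINK v1.00 SNP-major BED file (bad magic bytes): ", bed_path,
         call. = FALSE)
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp)
    stop("BED size inconsistent with BIM/FAM: expected ", m * bytes_per_snp,
         " data bytes, found ", length(body), call. = FALSE)

  # unpack all 2-bit codes at once
  codes <- matrix(as.integer(body), nrow = bytes_per_snp)   # bytes x SNPs
  dos <- matrix(NA_real_, nrow = n, ncol = m)
  for (shift in 0:3) {
    idx <- shift + 1 + 4 * (seq_len(bytes_per_snp) - 1)     # sample slots
    keep <- idx <= n
    if (!any(keep)) next
    code <- codes[keep, , drop = FALSE] %/% 4L^shift %% 4L
    dos[idx[keep], ] <- .bed_code_to_dosage[code + 1L]
  }

  meta <- bim[, c("snp_id", "chrom", "pos", "a1", "a2")]
  genotype_matrix(dos, meta, sample_ids = fam$iid, sample_sex = fam$sex)
}

#' Write PLINK binary genotypes
#'
#' Writes a [genotype_matrix] as a PLINK 1 binary fileset (SNP-major BED
#' v1.00 plus BIM and FAM). Inverse of [read_plink()].
#'
#' @param g a [genotype_matrix].
#' @param prefix output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return The `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  d <- g$dosages
  n <- nrow(d)
  m <- ncol(d)
  bytes_per_snp <- ceiling(n / 4)

  # dosage -> 2-bit code (2->00, NA->01, 1->10, 0->11)
  code <- matrix(1L, nrow = n, ncol = m)        # default: missing
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L

  padded <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
  padded[seq_len(n), ] <- code
  shift <- 4L^(0:3)
  byte_vals <- matrix(0L, nrow = bytes_per_snp, ncol = m)
  for (s in 1:4) {
    rows <- s + 4 * (seq_len(bytes_per_snp) - 1)
    byte_vals <- byte_vals + padded[rows, , drop = FALSE] * shift[s]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(byte_vals), con)

  bim <- data.frame(chrom = g$snp_meta$chrom, snp_id = g$snp_meta$snp_id,
                    cm = 0, pos = g$snp_meta$pos,
                    a1 = g$snp_meta$a1, a2 = g$snp_meta$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  sex <- if (is.null(g$sample_sex)) rep(0L, n) else g$sample_sex
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids,
                    father = 0L, mother = 0L, sex = sex, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
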