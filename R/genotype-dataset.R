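#' Construct a case-control genotype dataset
#'
#' The central container of the package: an `n` samples by `p` SNPs matrix of
#' minor-allele dosages in `{0, 1, 2}` (with `NA` as the missing sentinel),
#' an optional binary phenotype (1 = case, 0 = control), and per-SNP
#' metadata.
#'
#' @param genotypes Integer matrix, samples in rows, SNPs in columns; values
#'   0, 1, 2 or `NA`.
#' @param phenotype Optional integer/numeric vector of 0 (control) / 1
#'   (case), one per sample.
#' @param snp_info Optional tibble/data.frame with one row per SNP; columns
#'   `snp_id`, `chrom`, `pos` are created with defaults when absent; an
#'   optional `gene` column is passed through to reports.
#' @param sample_id Optional character vector of sample identifiers.
#'
#' @return An object of class `geno_data`.
#' @export
genotype_dataset <- function(genotypes, phenotype = NULL, snp_info = NULL,
                             sample_id = NULL) {
  if (!is.matrix(genotypes)) {
    stop("`genotypes` must be a matrix", call. = FALSE)
  }
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    stop("genotype values must be 0, 1, 2 or NA", call. = FALSE)
  }
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (n < 1L || p < 1L) stop("empty genotype matrix", call. = FALSE)

  if (!is.null(phenotype)) {
    phenotype <- as.integer(phenotype)
    if (length(phenotype) != n) {
      stop("`phenotype` length must equal the number of samples",
           call. = FALSE)
    }
    if (anyNA(phenotype) || !all(phenotype %in% 0:1)) {
      stop("`phenotype` must be complete and coded 0 (control) / 1 (case)",
           call. = FALSE)
    }
  }

  if (is.null(snp_info)) snp_info <- tibble::tibble(.rows = p)
  snp_info <- tibble::as_tibble(snp_info)
  if (nrow(snp_info) != p) {
    stop("`snp_info` must have one row per SNP", call. = FALSE)
  }
  if (is.null(snp_info$snp_id)) {
    snp_info$snp_id <- if (!is.null(colnames(genotypes))) {
      colnames(genotypes)
    } else {
      sprintf("snp%d", seq_len(p))
    }
  }
  if (anyDuplicated(snp_info$snp_id)) {
    stop("duplicated SNP ids", call. = FALSE)
  }
  if (is.null(snp_info$chrom)) snp_info$chrom <- "1"
  snp_info$chrom <- as.character(snp_info$chrom)
  if (is.null(snp_info$pos)) snp_info$pos <- seq_len(p) * 1000L
  colnames(genotypes) <- snp_info$snp_id

  if (is.null(sample_id)) {
    sample_id <- if (!is.null(rownames(genotypes))) {
      rownames(genotypes)
    } else {
      sprintf("S%d", seq_len(n))
    }
  }
  rownames(genotypes) <- sample_id

  structure(
    list(genotypes = genotypes, phenotype = phenotype, snp_info = snp_info,
         sample_id = sample_id),
    class = "geno_data"
  )
}

#' @export
print.geno_data <- function(x, ...) {
  cat(sprintf("<geno_data> %d samples x %d SNPs\n",
              n_samples(x), n_snps(x)))
  if (!is.null(x$phenotype)) {
    cat(sprintf("  phenotype: %d cases / %d controls\n",
                sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  } else {
    cat("  phenotype: unset\n")
  }
  nmiss <- sum(is.na(x$genotypes))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$genotypes)))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param x A `geno_data` object.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$genotypes)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$genotypes)

#' SNP identifiers of a dataset
#' @param x A `geno_data` object.
#' @return Character vector of SNP ids in column order.
#' @export
snp_ids <- function(x) x$snp_info$snp_id

#' Per-SNP minor allele frequency
#'
#' Sample frequency of the counted (minor) allele, computed over non-missing
#' genotypes of all samples.
#'
#' @param x A `geno_data` object.
#' @return Numeric vector, one frequency per SNP.
#' @export
snp_maf <- function(x) {
  colMeans(x$genotypes, na.rm = TRUE) / 2
}

#' Subset a dataset to a set of SNPs
#'
#' @param x A `geno_data` object.
#' @param keep Character vector of SNP ids (order of the dataset is
#'   preserved) or logical/integer column index.
#' @return A `geno_data` with the selected SNPs.
#' @export
subset_snps <- function(x, keep) {
  if (is.character(keep)) {
    missing_ids <- setdiff(keep, snp_ids(x))
    if (length(missing_ids) > 0) {
      stop("unknown SNP ids: ", paste(utils::head(missing_ids, 5),
                                      collapse = ", "), call. = FALSE)
    }
    keep <- snp_ids(x) %in% keep
  }
  idx <- seq_len(n_snps(x))[keep]
  if (length(idx) == 0) stop("subset would remove every SNP", call. = FALSE)
  genotype_dataset(x$genotypes[, idx, drop = FALSE],
                   phenotype = x$phenotype,
                   snp_info = x$snp_info[idx, , drop = FALSE],
                   sample_id = x$sample_id)
}

#' Subset a dataset to a set of samples
#'
#' @param x A `geno_data` object.
#' @param keep Logical or integer row index.
#' @return A `geno_data` with the selected samples.
#' @export
subset_samples <- function(x, keep) {
  idx <- seq_len(n_samples(x))[keep]
  if (length(idx) == 0) stop("subset would remove every sample",
                             call. = FALSE)
  genotype_dataset(x$genotypes[idx, , drop = FALSE],
                   phenotype = x$phenotype[idx],
                   snp_info = x$snp_info,
                   sample_id = x$sample_id[idx])
}

# internal: checks required before forest fitting
check_fit_ready <- function(x) {
  if (anyNA(x$genotypes)) {
    stop("dataset contains missing genotypes; run mode_impute() first",
         call. = FALSE)
  }
  if (is.null(x$phenotype)) {
    stop("dataset has no phenotype labels", call. = FALSE)
  }
  if (length(unique(x$phenotype)) < 2) {
    stop("both cases and controls must be present", call. = FALSE)
  }
  invisible(x)
}
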