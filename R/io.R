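#' Read a PLINK text .ped/.map pair
#'
#' Parses whitespace-delimited allelic data into minor-allele dosages. The
#' minor allele of each SNP is determined from the combined sample
#' frequency (ties go to the lexicographically smaller allele); dosage is
#' the count of the minor allele, and the `"0 0"` allele pair becomes the
#' missing sentinel. Phenotypes use the text dialect 1 = control,
#' 2 = case, mapped to 0/1 internally; missing phenotype codes (0, -9) are
#' rejected, since classification requires complete labels.
#'
#' @param ped_path Path to the .ped file (6 leading columns, then two
#'   allele fields per SNP).
#' @param map_path Path to the .map file (chromosome, SNP id, genetic
#'   distance, bp position).
#' @return A `geno_data` (possibly with `NA` sentinels).
#' @export
read_plink <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_fields) != 4)
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: expected 4 fields", map_path, bad[1]),
         call. = FALSE)
  }
  map <- do.call(rbind, map_fields)
  p <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  if (n == 0) stop("empty .ped file", call. = FALSE)
  alle <- matrix("", n, 2L * p)
  sample_id <- character(n)
  pheno <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * p) {
      stop(sprintf("%s line %d: expected %d fields, found %d", ped_path, i,
                   6L + 2L * p, length(f)), call. = FALSE)
    }
    sample_id[i] <- f[2]
    ph <- f[6]
    if (!ph %in% c("1", "2")) {
      stop(sprintf("%s line %d: phenotype code '%s' (need 1=control, 2=case)",
                   ped_path, i, ph), call. = FALSE)
    }
    pheno[i] <- as.integer(ph) - 1L
    alle[i, ] <- f[-(1:6)]
  }

  geno <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    a <- alle[, 2L * j - 1L]
    b <- alle[, 2L * j]
    obs <- c(a[a != "0"], b[b != "0"])
    lev <- sort(unique(obs))
    if (length(lev) > 2) {
      stop(sprintf("SNP %s: more than two alleles (%s)", map[j, 2],
                   paste(lev, collapse = ", ")), call. = FALSE)
    }
    if (length(lev) == 0) {
      geno[, j] <- NA_integer_
      next
    }
    counts <- vapply(lev, function(al) sum(obs == al), numeric(1))
    # minor = less frequent; tie -> lexicographically smaller (lev is sorted)
    minor <- lev[which.min(counts)]
    miss <- a == "0" | b == "0"
    geno[, j] <- (a == minor) + (b == minor)
    geno[miss, j] <- NA_integer_
  }

  info <- tibble::tibble(snp_id = map[, 2], chrom = map[, 1],
                         pos = as.integer(map[, 4]))
  genotype_dataset(geno, phenotype = pheno, snp_info = info,
                   sample_id = sample_id)
}

#' Write a dataset as a PLINK text .ped/.map pair
#'
#' Dosage 2/1/0 is written as `A A` / `A G` / `G G` (`A` the counted minor
#' allele), `NA` as `0 0`; phenotypes as 2 = case, 1 = control.
#'
#' @param x A `geno_data` with phenotypes.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "geno_data"))
  if (is.null(x$phenotype)) {
    stop("dataset has no phenotype labels to write", call. = FALSE)
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")

  utils::write.table(
    data.frame(chrom = x$snp_info$chrom, snp_id = x$snp_info$snp_id,
               cm = 0, pos = x$snp_info$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  pair <- c("G G", "A G", "A A")   # dosage 0, 1, 2
  g <- x$genotypes
  n <- nrow(g)
  rows <- character(n)
  for (i in seq_len(n)) {
    a <- pair[g[i, ] + 1L]
    a[is.na(g[i, ])] <- "0 0"
    rows[i] <- paste(x$sample_id[i], x$sample_id[i], 0, 0, 0,
                     x$phenotype[i] + 1L, paste(a, collapse = " "))
  }
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a PLINK .raw additive-dosage file
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`; dosage columns hold
#' counts of the suffixed (counted) allele, `NA` marks missing.
#'
#' @param path Path to the .raw file.
#' @param map_path Optional .map file supplying chromosome/position
#'   metadata for the SNPs.
#' @return A `geno_data`.
#' @export
read_raw <- function(path, map_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(colnames(tab)[1:6], need)) {
    stop("not a .raw file: header must start with ",
         paste(need, collapse = " "), call. = FALSE)
  }
  ph <- tab$PHENOTYPE
  if (!all(ph %in% c("1", "2"))) {
    stop("phenotype codes must be 1=control, 2=case", call. = FALSE)
  }
  snp_cols <- colnames(tab)[-(1:6)]
  geno <- as.matrix(tab[, -(1:6), drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "integer")
  snp_id <- sub("_[ACGT]$", "", snp_cols)
  info <- tibble::tibble(snp_id = snp_id)
  if (!is.null(map_path)) {
    map <- do.call(rbind, strsplit(trimws(readLines(map_path)), "[ \t]+"))
    m <- match(snp_id, map[, 2])
    info$chrom <- map[m, 1]
    info$pos <- as.integer(map[m, 4])
  }
  genotype_dataset(geno, phenotype = as.integer(ph) - 1L, snp_info = info,
                   sample_id = tab$IID)
}

#' Write a dataset as a PLINK .raw additive-dosage file
#'
#' @param x A `geno_data` with phenotypes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(x, path) {
  stopifnot(inherits(x, "geno_data"))
  if (is.null(x$phenotype)) {
    stop("dataset has no phenotype labels to write", call. = FALSE)
  }
  head_cols <- data.frame(
    FID = x$sample_id, IID = x$sample_id, PAT = 0, MAT = 0, SEX = 0,
    PHENOTYPE = x$phenotype + 1L)
  g <- as.data.frame(x$genotypes)
  colnames(g) <- paste0(snp_ids(x), "_A")
  utils::write.table(cbind(head_cols, g), path, sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Remove SNPs with excessive missingness
#'
#' SNPs whose missing fraction exceeds `threshold` (default 10%) are
#' dropped.
#'
#' @param x A `geno_data`.
#' @param threshold Maximum tolerated missing fraction, in \[0, 1\].
#' @return The filtered dataset.
#' @export
filter_missingness <- function(x, threshold = 0.10) {
  stopifnot(inherits(x, "geno_data"))
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  frac <- colMeans(is.na(x$genotypes))
  if (all(frac <= threshold)) return(x)
  subset_snps(x, frac <= threshold)
}

#' Impute missing genotypes by per-SNP mode
#'
#' Each missing entry is replaced by its SNP's most frequent observed
#' dosage, ties going to the lower dosage. Deterministic. A column-mode
#' rule is adequate here because downstream screening only needs complete
#' dosages, not haplotype-aware reconstruction.
#'
#' @param x A `geno_data`; every SNP must have at least one observed
#'   value (filter first).
#' @return The dataset with no missing values.
#' @export
mode_impute <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  g <- x$genotypes
  miss_cols <- which(colSums(is.na(g)) > 0)
  for (j in miss_cols) {
    col <- g[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0) {
      stop(sprintf("SNP %s is fully missing; run filter_missingness()",
                   snp_ids(x)[j]), call. = FALSE)
    }
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode_val <- which.max(counts) - 1L   # which.max: first max = lower dosage
    col[is.na(col)] <- mode_val
    g[, j] <- col
  }
  out <- x
  out$genotypes <- g
  out
}

#' Write a run manifest
#'
#' Records the configuration file hash (MD5), the seeds in play, the
#' package version and a timestamp, so any stage can be replayed in
#' isolation.
#'
#' @param path Output JSON path.
#' @param config_path Optional configuration file whose MD5 is recorded.
#' @param seeds Named list/vector of seeds used.
#' @param extra Optional named list of further fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path = NULL, seeds = list(),
                           extra = list()) {
  manifest <- c(
    list(
      package = "snpforest",
      version = as.character(utils::packageVersion("snpforest")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config_md5 = if (is.null(config_path)) NA_character_ else
        unname(tools::md5sum(config_path)),
      seeds = as.list(seeds)
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
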