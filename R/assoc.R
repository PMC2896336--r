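#' Allelic chi-square association tests
#'
#' Per SNP, alleles are counted as two per sample (dosage summed within
#' cases and within controls) and a Pearson chi-square statistic (df = 1,
#' no continuity correction) is computed on the 2x2 allele-by-class table,
#' with the p-value from the upper tail of chi-square(1). Monomorphic SNPs
#' get chi-square 0, p = 1 and are flagged.
#'
#' @param x A `geno_data` with phenotypes (missing genotypes are dropped
#'   per SNP from the allele counts).
#' @return A `snp_assoc` tibble: `snp_id`, `chrom`, `pos`, `maf`,
#'   `minor_case`, `minor_control` (minor-allele counts by class),
#'   `chisq`, `p`, `monomorphic`.
#' @export
allelic_chisq <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  if (is.null(x$phenotype) || length(unique(x$phenotype)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  g <- x$genotypes
  case <- x$phenotype == 1L
  obs_case <- colSums(!is.na(g[case, , drop = FALSE]))
  obs_ctrl <- colSums(!is.na(g[!case, , drop = FALSE]))
  a1 <- colSums(g[case, , drop = FALSE], na.rm = TRUE)    # minor, cases
  a0 <- colSums(g[!case, , drop = FALSE], na.rm = TRUE)   # minor, controls
  b1 <- 2 * obs_case - a1                                 # major, cases
  b0 <- 2 * obs_ctrl - a0

  n <- a1 + a0 + b1 + b0
  chisq <- n * (a1 * b0 - a0 * b1)^2 /
    ((a1 + b1) * (a0 + b0) * (a1 + a0) * (b1 + b0))
  mono <- (a1 + a0 == 0) | (b1 + b0 == 0)
  chisq[mono] <- 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p[mono] <- 1

  out <- tibble::tibble(
    snp_id = snp_ids(x), chrom = x$snp_info$chrom, pos = x$snp_info$pos,
    maf = unname((a1 + a0) / n), minor_case = unname(a1),
    minor_control = unname(a0), chisq = unname(as.numeric(chisq)),
    p = unname(p), monomorphic = unname(mono)
  )
  class(out) <- c("snp_assoc", class(out))
  out
}

#' Genomic inflation factor
#'
#' `lambda` = median observed chi-square divided by the chi-square(1)
#' median (0.4549); values near 1 indicate negligible population
#' stratification. Reported to two decimals, the convention for this
#' statistic.
#'
#' @param chisq Numeric vector of chi-square statistics (or a `snp_assoc`
#'   tibble).
#' @return `lambda`, rounded to 2 decimals.
#' @export
genomic_inflation <- function(chisq) {
  if (inherits(chisq, "snp_assoc")) chisq <- chisq$chisq
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0) {
    stop("need at least one finite chi-square value", call. = FALSE)
  }
  round(stats::median(chisq) / stats::qchisq(0.5, df = 1), 2)
}

#' Analytic power of the allelic test
#'
#' Normal-approximation power of the two-proportion allelic test: the case
#' minor-allele frequency is `p1 = or * maf / (1 + maf * (or - 1))`,
#' allele sample sizes are `2 * n_cases` and `2 * n_controls`, the null is
#' rejected at `z[alpha/2]` using the pooled-null standard error, and
#' power is evaluated under the alternative standard error. Vectorized
#' over `maf` and `or_per_allele`.
#'
#' @param n_cases,n_controls Class sample sizes.
#' @param maf Control minor allele frequency, strictly inside (0, 1).
#' @param or_per_allele Per-allele odds ratio (> 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in \[0, 1\] (equal to `alpha` when `or_per_allele = 1`).
#' @export
allelic_power <- function(n_cases, n_controls, maf, or_per_allele,
                          alpha = 1.5e-7) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (any(or_per_allele <= 0)) {
    stop("`or_per_allele` must be positive", call. = FALSE)
  }
  if (any(maf <= 0 | maf >= 1)) {
    stop("`maf` must lie strictly inside (0, 1)", call. = FALSE)
  }
  p0 <- maf
  p1 <- expected_case_maf(p0, or_per_allele)
  m1 <- 2 * n_cases
  m0 <- 2 * n_controls
  pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m0))
  se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  z <- stats::qnorm(1 - alpha / 2)
  d <- p1 - p0
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}

#' Duplication report against a reference association list
#'
#' Classifies each reference SNP as `direct` (the reference id itself is
#' in the ranked top list), `tagged` (a member of its tag set is; the
#' best-ranked tagging SNP is reported), or `absent`.
#'
#' @param rf_top_list Character vector of top-ranked SNP ids, best first.
#' @param reference_snps Character vector of reference SNP ids.
#' @param tagmap A `tag_map` from [find_tag_snps()] built at the
#'   configured tagging threshold.
#' @return Tibble with `reference_snp`, `status`, `matched_snp`, `rank`.
#' @export
duplication_report <- function(rf_top_list, reference_snps, tagmap) {
  rows <- lapply(reference_snps, function(ref) {
    if (ref %in% rf_top_list) {
      return(tibble::tibble(reference_snp = ref, status = "direct",
                            matched_snp = ref,
                            rank = match(ref, rf_top_list)))
    }
    tags <- setdiff(tagmap$tag_snp[tagmap$ref_snp == ref], ref)
    hit <- intersect(rf_top_list, tags)
    if (length(hit) > 0) {
      ranks <- match(hit, rf_top_list)
      best <- which.min(ranks)
      return(tibble::tibble(reference_snp = ref, status = "tagged",
                            matched_snp = hit[best], rank = ranks[best]))
    }
    tibble::tibble(reference_snp = ref, status = "absent",
                   matched_snp = NA_character_, rank = NA_integer_)
  })
  dplyr::bind_rows(rows)
}

#' Ranked results table
#'
#' Joins the variable-importance ranking with the marginal association
#' results and reports the top `k` SNPs with columns in the conventional
#' order: chromosome, SNP id, gene annotation, MAF, RF rank, chi-square,
#' p-value.
#'
#' @param vi A `snp_vi` tibble.
#' @param assoc A `snp_assoc` tibble over (a superset of) the same SNPs.
#' @param snp_info Optional tibble with `snp_id` and a `gene` column,
#'   passed through verbatim.
#' @param k Number of top-ranked SNPs to report (truncated with a warning
#'   when fewer are available).
#' @return Tibble with columns `chrom`, `snp`, `gene`, `maf`, `rf_rank`,
#'   `chisq`, `p`.
#' @export
results_table <- function(vi, assoc, snp_info = NULL, k = 25) {
  if (k > nrow(vi)) {
    warning(sprintf("only %d SNPs available; truncating k = %d", nrow(vi),
                    k), call. = FALSE)
    k <- nrow(vi)
  }
  top <- vi[order(vi$rank), ][seq_len(k), ]
  out <- dplyr::left_join(
    top,
    assoc[, c("snp_id", "chrom", "maf", "chisq", "p")],
    by = "snp_id")
  gene <- rep(NA_character_, nrow(out))
  if (!is.null(snp_info) && !is.null(snp_info$gene)) {
    gene <- snp_info$gene[match(out$snp_id, snp_info$snp_id)]
  }
  tibble::tibble(chrom = out$chrom, snp = out$snp_id, gene = gene,
                 maf = out$maf, rf_rank = out$rank, chisq = out$chisq,
                 p = out$p)
}

#' Write a results table as tab-separated text
#'
#' @param tab A tibble from [results_table()] (or any data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
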