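#' Pairwise linkage disequilibrium r2 between two dosage vectors
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors (composite LD,
#' not based on phased haplotypes). Symmetric, and invariant under the
#' allele relabeling `g -> 2 - g` of either argument.
#'
#' @param g1,g2 Equal-length dosage vectors (length >= 2).
#' @return r2 in \[0, 1\]; `NA` (with a warning) when either vector is
#'   constant, where the correlation is undefined.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 2) {
    stop("`g1` and `g2` must have equal length >= 2", call. = FALSE)
  }
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    warning("constant dosage vector: r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(g1, g2)^2
}

# internal: multiple correlation R2 of column `j` regressed (with
# intercept) on the other columns of `mat`; rank deficiency handled by a
# minimum-norm (pseudoinverse) least-squares solve
multiple_r2 <- function(mat, j) {
  y <- mat[, j]
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0) return(0)  # constant target: nothing to explain
  X <- mat[, -j, drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  if (!any(pos)) return(0)
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% yc) / sv$d[pos])
  rss <- sum((yc - Xc %*% coef)^2)
  max(0, min(1, 1 - rss / tss))
}

#' Prune SNPs by linkage disequilibrium in sliding windows
#'
#' Slides a window of `window_size` SNPs along each chromosome (ordered by
#' position), advancing by `window_step`. Within each window, for method
#' `"window_r2"` the SNP whose multiple correlation R2 on the other
#' retained window SNPs is highest is removed (ties to the higher index)
#' repeatedly until no retained SNP exceeds `threshold`; for
#' `"pairwise_r2"` the later SNP of any retained pair with pairwise
#' r2 > `threshold` is removed greedily. Removals persist across windows.
#'
#' @param x A `geno_data` (complete genotypes).
#' @param threshold LD threshold in (0, 1\].
#' @param method `"window_r2"` (multiple correlation) or
#'   `"pairwise_r2"`.
#' @param window_size Window length in SNPs (>= 2).
#' @param window_step Window advance in SNPs (<= `window_size`).
#' @return Character vector of retained SNP ids in dataset order, with the
#'   removed ids in attribute `"pruned"` and the call parameters in
#'   attribute `"params"`.
#' @export
ld_prune <- function(x, threshold, method = c("window_r2", "pairwise_r2"),
                     window_size = 50, window_step = 5) {
  stopifnot(inherits(x, "geno_data"))
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  if (window_size < 2) stop("`window_size` must be >= 2", call. = FALSE)
  if (window_step < 1 || window_step > window_size) {
    stop("`window_step` must be in [1, window_size]", call. = FALSE)
  }
  geno <- x$genotypes
  if (anyNA(geno)) {
    stop("LD pruning requires complete genotypes; run mode_impute()",
         call. = FALSE)
  }
  info <- x$snp_info
  keep <- rep(TRUE, n_snps(x))

  for (ch in unique(info$chrom)) {
    cols <- which(info$chrom == ch)
    cols <- cols[order(info$pos[cols])]
    nc <- length(cols)
    if (nc < 2) next
    for (ws in seq(1, nc, by = window_step)) {
      we <- min(ws + window_size - 1, nc)
      if (we - ws < 1) break
      win <- cols[ws:we]
      if (method == "pairwise_r2") {
        for (a in seq_along(win)) {
          i <- win[a]
          if (!keep[i]) next
          for (b in seq_along(win)) {
            if (b <= a) next
            j <- win[b]
            if (!keep[j]) next
            if (stats::var(geno[, i]) == 0 || stats::var(geno[, j]) == 0) next
            if (stats::cor(geno[, i], geno[, j])^2 > threshold) {
              keep[j] <- FALSE
            }
          }
        }
      } else {
        repeat {
          act <- win[keep[win]]
          if (length(act) < 2) break
          r2 <- vapply(seq_along(act), function(k) {
            multiple_r2(geno[, act, drop = FALSE], k)
          }, numeric(1))
          over <- which(r2 > threshold)
          if (length(over) == 0) break
          worst <- over[r2[over] == max(r2[over])]
          keep[act[worst[length(worst)]]] <- FALSE  # ties: higher index
        }
      }
      if (we == nc) break
    }
  }
  retained <- snp_ids(x)[keep]
  attr(retained, "pruned") <- snp_ids(x)[!keep]
  attr(retained, "params") <- list(method = method, threshold = threshold,
                                   window_size = window_size,
                                   window_step = window_step)
  retained
}

#' Write LD prune lists
#'
#' Emits `<prefix>.prune.in` (retained) and `<prefix>.prune.out` (removed)
#' files, one SNP id per line, mirroring the standard convention.
#'
#' @param retained The vector returned by [ld_prune()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_prune_lists <- function(retained, prefix) {
  p_in <- paste0(prefix, ".prune.in")
  p_out <- paste0(prefix, ".prune.out")
  writeLines(retained, p_in)
  pruned <- attr(retained, "pruned")
  writeLines(if (is.null(pruned)) character(0) else pruned, p_out)
  invisible(c(p_in, p_out))
}

#' Identify tag SNPs for a set of reference SNPs
#'
#' For each reference SNP, the tag set is every SNP on the same chromosome
#' within `max_distance` base pairs whose pairwise r2 with the reference
#' is at least `r2_threshold`. Every SNP tags itself. Reference ids absent
#' from the dataset are skipped with a warning.
#'
#' @param x A `geno_data` with complete genotypes.
#' @param reference_snps Character vector of reference SNP ids.
#' @param r2_threshold Tagging threshold (default 0.5).
#' @param max_distance Distance bound in base pairs (default 250 kb).
#' @return A `tag_map` tibble with columns `ref_snp`, `tag_snp`, `r2`.
#' @export
find_tag_snps <- function(x, reference_snps, r2_threshold = 0.5,
                          max_distance = 250000) {
  stopifnot(inherits(x, "geno_data"))
  ids <- snp_ids(x)
  absent <- setdiff(reference_snps, ids)
  if (length(absent) > 0) {
    warning("reference SNP(s) absent from dataset, skipped: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  present <- intersect(reference_snps, ids)
  rows <- list()
  for (ref in present) {
    ri <- match(ref, ids)
    cand <- which(x$snp_info$chrom == x$snp_info$chrom[ri] &
                    abs(x$snp_info$pos - x$snp_info$pos[ri]) <= max_distance)
    gr <- x$genotypes[, ri]
    r2 <- vapply(cand, function(ci) {
      if (ci == ri) return(1)
      if (stats::var(gr) == 0 || stats::var(x$genotypes[, ci]) == 0) {
        return(NA_real_)
      }
      stats::cor(gr, x$genotypes[, ci])^2
    }, numeric(1))
    sel <- !is.na(r2) & r2 >= r2_threshold
    rows[[ref]] <- tibble::tibble(ref_snp = ref, tag_snp = ids[cand[sel]],
                                  r2 = r2[sel])
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(ref_snp = character(0), tag_snp = character(0),
                   r2 = numeric(0))
  class(out) <- c("tag_map", class(out))
  out
}
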