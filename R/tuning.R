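#' Candidate mtry grid for a panel of p SNPs
#'
#' The coarse search grid used for genome-wide panels:
#' `{1, floor(sqrt(p)), floor(0.1 p), floor(0.5 p), p}`, each clamped to at
#' least 1, deduplicated and sorted ascending. `sqrt(p)` is the
#' conventional default for classification forests; on sparse genome-wide
#' panels the optimum is typically near `0.1 p`.
#'
#' @param p Number of SNPs (>= 1).
#' @return Integer vector of candidate values.
#' @export
mtry_grid <- function(p) {
  if (length(p) != 1 || is.na(p) || p < 1) {
    stop("`p` must be a single value >= 1", call. = FALSE)
  }
  p <- as.integer(p)
  g <- pmax(1L, as.integer(floor(c(1, sqrt(p), 0.1 * p, 0.5 * p, p))))
  sort(unique(g))
}

#' Detect convergence of an OOB error trajectory
#'
#' The trajectory has converged at the first tree index `t` such that the
#' range (max minus min) of the trailing `window` values ending at `t` is
#' at most `tol`. Leading entries can be `NA` (before every sample has an
#' out-of-bag vote); windows containing `NA` are skipped.
#'
#' @param trajectory Numeric vector of OOB error after 1, 2, ... trees.
#' @param window Number of trailing trees examined (>= 2).
#' @param tol Maximum allowed range within the window (> 0); absolute
#'   error-rate units.
#' @return List with `converged` (logical) and `converged_at` (tree index,
#'   or `NA` when not converged).
#' @export
has_converged <- function(trajectory, window = 100, tol = 0.005) {
  if (window < 2) stop("`window` must be >= 2", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  nt <- length(trajectory)
  if (nt < window) {
    return(list(converged = FALSE, converged_at = NA_integer_))
  }
  for (t in window:nt) {
    w <- trajectory[(t - window + 1):t]
    if (anyNA(w)) next
    if (max(w) - min(w) <= tol) {
      return(list(converged = TRUE, converged_at = t))
    }
  }
  list(converged = FALSE, converged_at = NA_integer_)
}

#' Fraction of SNPs with non-positive variable importance
#'
#' A sparse solution is indicated when the permutation importance is zero
#' or negative: the SNP was either never selected into a tree, or
#' permuting it did not hurt out-of-bag accuracy.
#'
#' @param vi A `snp_vi` tibble (from [permutation_importance()]).
#' @return Fraction in \[0, 1\].
#' @export
sparsity_fraction <- function(vi) {
  if (nrow(vi) == 0) stop("empty importance table", call. = FALSE)
  mean(vi$score <= 0)
}

#' Tune mtry by out-of-bag error minimization
#'
#' Fits one forest per candidate `mtry` with a shared base seed and
#' records the final out-of-bag error, the full trajectory, the
#' convergence point, and the sparsity fraction of the permutation
#' importances. The candidate with the lowest final OOB error is selected;
#' ties go to the smallest `mtry`.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param candidates Candidate `mtry` values (default [mtry_grid()]).
#' @param ntree Trees per candidate forest.
#' @param seed Shared base seed.
#' @param window,tol Convergence rule passed to [has_converged()].
#' @param class_weights Optional `(control, case)` weights.
#' @return An `snp_tuning` object; see [tidy.snp_tuning()].
#' @export
tune_mtry <- function(x, candidates = mtry_grid(n_snps(x)), ntree = 1000,
                      seed = 1, window = 100, tol = 0.005,
                      class_weights = NULL) {
  stopifnot(inherits(x, "geno_data"))
  if (length(candidates) == 0) {
    stop("`candidates` must be non-empty", call. = FALSE)
  }
  candidates <- sort(unique(as.integer(candidates)))
  rows <- vector("list", length(candidates))
  trajectories <- list()
  for (i in seq_along(candidates)) {
    m <- candidates[i]
    fit <- grow_forest(x, mtry = m, ntree = ntree,
                       class_weights = class_weights, seed = seed)
    vi <- permutation_importance(fit, x, seed = seed + 1)
    conv <- has_converged(fit$oob_trajectory, window = window, tol = tol)
    rows[[i]] <- tibble::tibble(
      mtry = m,
      oob_error = oob_error(fit),
      oob_error_raw = oob_error(fit, type = "raw"),
      converged = conv$converged,
      converged_at = conv$converged_at,
      sparsity_fraction = sparsity_fraction(vi)
    )
    trajectories[[as.character(m)]] <- fit$oob_trajectory
  }
  results <- dplyr::bind_rows(rows)
  selected <- results$mtry[which.min(results$oob_error)]
  structure(
    list(results = results, trajectories = trajectories,
         selected_mtry = selected, ntree = ntree, seed = seed),
    class = "snp_tuning"
  )
}

#' @export
print.snp_tuning <- function(x, ...) {
  cat(sprintf("<snp_tuning> %d candidates, ntree = %d; selected mtry = %d\n",
              nrow(x$results), x$ntree, x$selected_mtry))
  print(x$results)
  invisible(x)
}

#' Per-candidate tuning results
#'
#' @param x An `snp_tuning` object.
#' @param ... Unused.
#' @return Tibble with one row per candidate `mtry`: final OOB error
#'   (balanced and raw), convergence point, sparsity fraction.
#' @method tidy snp_tuning
#' @export
tidy.snp_tuning <- function(x, ...) x$results

#' One-row tuning summary
#'
#' @param x An `snp_tuning` object.
#' @param ... Unused.
#' @return Tibble with the selected `mtry` and its final OOB error.
#' @method glance snp_tuning
#' @export
glance.snp_tuning <- function(x, ...) {
  sel <- x$results[x$results$mtry == x$selected_mtry, ]
  tibble::tibble(selected_mtry = x$selected_mtry, ntree = x$ntree,
                 oob_error = sel$oob_error,
                 converged_at = sel$converged_at)
}

#' Write a tuning report as a tab-separated table
#'
#' One row per candidate (`mtry`, final OOB error, convergence point,
#' sparsity fraction); optionally one trajectory file per candidate for
#' plotting.
#'
#' @param tuning An `snp_tuning` object.
#' @param path Output TSV path.
#' @param trajectory_dir Optional directory for per-candidate trajectory
#'   files (`trajectory_mtry<m>.tsv`).
#' @return `path`, invisibly.
#' @export
write_tuning_report <- function(tuning, path, trajectory_dir = NULL) {
  stopifnot(inherits(tuning, "snp_tuning"))
  utils::write.table(tuning$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trajectory_dir)) {
    dir.create(trajectory_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(tuning$trajectories)) {
      tr <- tuning$trajectories[[m]]
      utils::write.table(
        data.frame(tree = seq_along(tr), oob_error = tr),
        file.path(trajectory_dir, sprintf("trajectory_mtry%s.tsv", m)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
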