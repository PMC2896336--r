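#' Iterative sparsity pruning
#'
#' Repeatedly fits a forest, computes permutation importance, drops SNPs
#' with non-positive importance, and refits on the retained set. Iteration
#' stops when the new out-of-bag error exceeds the previous one
#' (`"increased"`), when the absolute change is at most `stop_tol`
#' (`"stabilized"`), or after `max_iter` iterations. The iteration with
#' the lowest OOB error is flagged as the final configuration. Retained
#' sets are strictly nested across iterations.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param mtry,ntree,class_weights Forest parameters (see
#'   [grow_forest()]).
#' @param seed Master seed; iteration `i` fits with seed `seed + i - 1`
#'   and permutes with `seed + i`.
#' @param stop_tol Absolute OOB-error change treated as "stabilized".
#' @param max_iter Maximum number of fit/prune iterations (>= 1).
#' @param drop_rule `"nonpositive"` (default: drop score <= 0) or
#'   `"quantile"` (drop the bottom `drop_quantile` fraction by score).
#' @param drop_quantile Fraction dropped per iteration under the quantile
#'   rule.
#' @param fit_fun Optional stand-in fitter for testing:
#'   `function(data, iter)` returning `list(oob_error =, vi =)` with `vi`
#'   a `snp_vi` tibble over the SNPs of `data`.
#' @return A `prune_trace` object; see [tidy.prune_trace()].
#' @export
sparsity_prune <- function(x, mtry = NULL, ntree = 1000, seed = 1,
                           stop_tol = 0.005, max_iter = 10,
                           drop_rule = c("nonpositive", "quantile"),
                           drop_quantile = 0.2, class_weights = NULL,
                           fit_fun = NULL) {
  stopifnot(inherits(x, "geno_data"))
  drop_rule <- match.arg(drop_rule)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (is.null(fit_fun)) {
    fit_fun <- function(data, iter) {
      # refits run on ever-smaller panels: cap mtry at the current p
      mtry_i <- if (is.null(mtry)) NULL else min(mtry, n_snps(data))
      fit <- grow_forest(data, mtry = mtry_i, ntree = ntree,
                         class_weights = class_weights,
                         seed = seed + iter - 1)
      list(oob_error = oob_error(fit),
           vi = permutation_importance(fit, data, seed = seed + iter))
    }
  }

  current <- x
  iters <- list()
  retained <- list()
  vis <- list()
  stop_reason <- "max_iterations"
  prev_err <- NA_real_

  for (iter in seq_len(max_iter)) {
    res <- fit_fun(current, iter)
    vi <- res$vi
    iters[[iter]] <- tibble::tibble(
      iteration = iter, n_snps = n_snps(current),
      oob_error = res$oob_error,
      sparsity_fraction = sparsity_fraction(vi)
    )
    retained[[iter]] <- snp_ids(current)
    vis[[iter]] <- vi

    if (iter >= 2) {
      if (res$oob_error > prev_err) {
        stop_reason <- "increased"
        break
      }
      if (abs(res$oob_error - prev_err) <= stop_tol) {
        stop_reason <- "stabilized"
        break
      }
    }
    prev_err <- res$oob_error
    if (iter == max_iter) break

    drop_ids <- switch(drop_rule,
      nonpositive = vi$snp_id[vi$score <= 0],
      quantile = vi$snp_id[vi$score <= stats::quantile(vi$score,
                                                       drop_quantile)]
    )
    if (length(drop_ids) == 0) {
      stop_reason <- "stabilized"
      break
    }
    if (length(drop_ids) >= n_snps(current)) {
      warning("pruning would remove every SNP; stopping with the last ",
              "non-empty set", call. = FALSE)
      stop_reason <- "stabilized"
      break
    }
    current <- subset_snps(current, setdiff(snp_ids(current), drop_ids))
  }

  iterations <- dplyr::bind_rows(iters)
  final_iteration <- which.min(iterations$oob_error)
  structure(
    list(iterations = iterations, retained = retained, vi = vis,
         stop_reason = stop_reason, final_iteration = final_iteration),
    class = "prune_trace"
  )
}

#' @export
print.prune_trace <- function(x, ...) {
  cat(sprintf("<prune_trace> %d iteration(s), stop reason: %s, final: %d\n",
              nrow(x$iterations), x$stop_reason, x$final_iteration))
  print(x$iterations)
  invisible(x)
}

#' Per-iteration summary of a sparsity-pruning trace
#'
#' @param x A `prune_trace`.
#' @param ... Unused.
#' @return Tibble with iteration number, retained SNP count, OOB error and
#'   sparsity fraction, plus a `final` flag on the lowest-error iteration.
#' @method tidy prune_trace
#' @export
tidy.prune_trace <- function(x, ...) {
  out <- x$iterations
  out$final <- seq_len(nrow(out)) == x$final_iteration
  out
}

#' Variable importance at the flagged final pruning iteration
#'
#' @param trace A `prune_trace`.
#' @return The `snp_vi` tibble of the lowest-OOB-error iteration.
#' @export
final_importance <- function(trace) {
  stopifnot(inherits(trace, "prune_trace"))
  trace$vi[[trace$final_iteration]]
}

#' Serialize a pruning trace to JSON
#'
#' @param trace A `prune_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prune_trace <- function(trace, path) {
  stopifnot(inherits(trace, "prune_trace"))
  jsonlite::write_json(
    list(iterations = trace$iterations,
         retained = trace$retained,
         stop_reason = trace$stop_reason,
         final_iteration = trace$final_iteration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-iteration retained SNP lists
#'
#' One plain-text file per iteration, one SNP id per line.
#'
#' @param trace A `prune_trace`.
#' @param prefix Path prefix; files are `<prefix>_iter<i>.txt`.
#' @return The paths written, invisibly.
#' @export
write_retained_lists <- function(trace, prefix) {
  stopifnot(inherits(trace, "prune_trace"))
  paths <- character(0)
  for (i in seq_along(trace$retained)) {
    path <- sprintf("%s_iter%d.txt", prefix, i)
    writeLines(trace$retained[[i]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Remove a genomic region from a dataset
#'
#' Drops all SNPs on the given chromosome (optionally restricted to a
#' 1-based, inclusive position interval), preserving the order of the
#' rest. Used to mask a dominant locus so weaker effects can surface.
#' Masking a chromosome absent from the data is the identity; masking is
#' idempotent.
#'
#' @param x A `geno_data`.
#' @param chrom Chromosome label to remove.
#' @param start,end Optional interval bounds (both or neither); absent
#'   means the whole chromosome.
#' @return The dataset without the masked SNPs.
#' @export
mask_region <- function(x, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(x, "geno_data"))
  if (xor(is.null(start), is.null(end))) {
    stop("give both `start` and `end`, or neither", call. = FALSE)
  }
  hit <- x$snp_info$chrom == as.character(chrom)
  if (!is.null(start)) {
    if (start > end) stop("`start` must be <= `end`", call. = FALSE)
    hit <- hit & x$snp_info$pos >= start & x$snp_info$pos <= end
  }
  if (!any(hit)) return(x)
  if (all(hit)) stop("mask would remove every SNP", call. = FALSE)
  subset_snps(x, !hit)
}

#' Seed-change reliability of the screening pipeline
#'
#' Re-runs the full forest (+ optional sparsity-pruning) pipeline once per
#' seed and reports the pairwise overlap (intersection size) of the top-k
#' variable-importance SNP id lists. Stable results give overlaps close to
#' `k`.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param seeds Integer vector of at least two seeds.
#' @param k Size of the top list compared.
#' @param mtry,ntree,class_weights Forest parameters.
#' @param prune Run sparsity pruning before ranking (default `TRUE`).
#' @param ... Further arguments to [rf_screen()].
#' @return Tibble with one row per seed pair (`seed1`, `seed2`,
#'   `overlap`); the per-seed top lists are attached as attribute
#'   `"top_lists"`.
#' @export
reliability_check <- function(x, seeds, k = 25, mtry = NULL, ntree = 1000,
                              class_weights = NULL, prune = TRUE, ...) {
  if (length(seeds) < 2) stop("need at least two seeds", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  tops <- lapply(seeds, function(s) {
    run <- rf_screen(x, mtry = mtry, ntree = ntree, seed = s,
                     class_weights = class_weights, prune = prune, ...)
    top_snps(run$vi, k)
  })
  names(tops) <- as.character(seeds)
  pairs <- utils::combn(seq_along(seeds), 2)
  out <- tibble::tibble(
    seed1 = seeds[pairs[1, ]],
    seed2 = seeds[pairs[2, ]],
    overlap = apply(pairs, 2, function(ij) {
      length(intersect(tops[[ij[1]]], tops[[ij[2]]]))
    })
  )
  attr(out, "top_lists") <- tops
  out
}

#' Scree-plot elbow cutoff for variable-importance scores
#'
#' Formalizes the visual "elbow" rule for deciding how many top-ranked
#' SNPs to report: over the top-`window` scores (sorted descending), the
#' cutoff is the index `k` maximizing the forward second difference
#' `s[k] - 2 s[k+1] + s[k+2]`, provided that maximum exceeds `clearness`
#' times the median absolute second difference (a "clear" elbow);
#' otherwise `default_k` is returned. The rule is invariant to rescaling
#' the scores by a positive constant.
#'
#' @param scores Numeric vector of importance scores, sorted descending
#'   (at least 3).
#' @param default_k Fallback cutoff when no clear elbow exists.
#' @param window Number of top scores examined.
#' @param clearness Multiple of the median absolute second difference the
#'   maximum must exceed.
#' @return Integer cutoff `k`.
#' @export
elbow_cutoff <- function(scores, default_k = 25, window = 100,
                         clearness = 2) {
  if (length(scores) < 3) stop("need at least 3 scores", call. = FALSE)
  if (is.unsorted(-scores)) {
    stop("`scores` must be sorted in descending order", call. = FALSE)
  }
  s <- utils::head(scores, min(window, length(scores)))
  m <- length(s)
  d2 <- s[1:(m - 2)] - 2 * s[2:(m - 1)] + s[3:m]
  k <- which.max(d2)
  if (d2[k] > clearness * stats::median(abs(d2))) {
    as.integer(k)
  } else {
    as.integer(default_k)
  }
}

#' Run the forest screening pipeline on one dataset
#'
#' The unit re-run by reliability checks: grow a forest, optionally apply
#' iterative sparsity pruning, and return the permutation-importance
#' ranking of the final configuration.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param mtry,ntree,class_weights Forest parameters.
#' @param seed Master seed of the run.
#' @param prune Apply sparsity pruning (default `TRUE`).
#' @param stop_tol,max_iter Pruning stop rule (see [sparsity_prune()]).
#' @return An `rf_screen` list: `vi` (final `snp_vi`), `trace` (the
#'   `prune_trace`, or `NULL` when `prune = FALSE`), and `retained`
#'   (SNP ids of the final configuration).
#' @export
rf_screen <- function(x, mtry = NULL, ntree = 1000, seed = 1,
                      class_weights = NULL, prune = TRUE,
                      stop_tol = 0.005, max_iter = 10) {
  stopifnot(inherits(x, "geno_data"))
  if (prune) {
    trace <- sparsity_prune(x, mtry = mtry, ntree = ntree, seed = seed,
                            stop_tol = stop_tol, max_iter = max_iter,
                            class_weights = class_weights)
    vi <- final_importance(trace)
    out <- list(vi = vi, trace = trace,
                retained = trace$retained[[trace$final_iteration]])
  } else {
    fit <- grow_forest(x, mtry = mtry, ntree = ntree,
                       class_weights = class_weights, seed = seed)
    vi <- permutation_importance(fit, x, seed = seed + 1)
    out <- list(vi = vi, trace = NULL, retained = snp_ids(x))
  }
  class(out) <- "rf_screen"
  out
}
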