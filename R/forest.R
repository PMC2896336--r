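#' @useDynLib snpforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal: balanced class weights (inverse class frequency, normalized to
# mean 1), or validate user-supplied (control, case) weights
resolve_class_weights <- function(phenotype, class_weights) {
  if (is.null(class_weights)) {
    n <- length(phenotype)
    n0 <- sum(phenotype == 0L)
    n1 <- sum(phenotype == 1L)
    class_weights <- c(control = n / (2 * n0), case = n / (2 * n1))
  }
  if (length(class_weights) != 2 || any(!is.finite(class_weights)) ||
      any(class_weights <= 0)) {
    stop("`class_weights` must be two strictly positive values ",
         "(control, case)", call. = FALSE)
  }
  unname(class_weights)
}

#' Grow a random forest on genotype dosages
#'
#' Bagged, unpruned classification trees: each tree is grown on a
#' with-replacement bootstrap of size `n`; at every node a fresh uniform
#' random subset of `mtry` SNPs is searched over all three binary
#' partitions of the genotype categories `{0, 1, 2}` for the split that
#' maximizes the class-weighted Gini impurity decrease, so the trees are
#' agnostic to additive, dominant or recessive effects. Growth continues
#' until nodes are pure or no candidate varies. The out-of-bag (OOB) error
#' trajectory is recorded after each tree.
#'
#' Class weighting defaults to balanced (inverse class frequency) and
#' enters the Gini criterion, terminal votes, and OOB error aggregation.
#'
#' @param x A complete (no missing genotypes) `geno_data` with phenotypes.
#' @param mtry Number of candidate SNPs per node; defaults to
#'   `max(1, floor(0.1 * p))`, the setting that minimizes OOB error on
#'   large sparse SNP panels.
#' @param ntree Number of trees (>= 1).
#' @param class_weights Optional numeric length-2 `(control, case)`
#'   weights; `NULL` for balanced.
#' @param seed Integer master seed; per-tree random streams are derived
#'   from it by tree index, so results do not depend on evaluation order.
#' @param importance If `TRUE`, compute permutation variable importance
#'   after fitting (seed `seed + 1`) and store it on the model.
#' @return An object of class `snp_forest`.
#' @export
grow_forest <- function(x, mtry = NULL, ntree = 1000, class_weights = NULL,
                        seed = 1, importance = FALSE) {
  stopifnot(inherits(x, "geno_data"))
  check_fit_ready(x)
  p <- n_snps(x)
  if (is.null(mtry)) mtry <- max(1L, floor(0.1 * p))
  mtry <- as.integer(mtry)
  ntree <- as.integer(ntree)
  if (ntree < 1L) stop("`ntree` must be >= 1", call. = FALSE)
  if (mtry < 1L || mtry > p) {
    stop("`mtry` must lie in [1, p]", call. = FALSE)
  }
  w <- resolve_class_weights(x$phenotype, class_weights)

  fit <- cpp_grow_forest(x$genotypes, x$phenotype, ntree, mtry,
                         w[1], w[2], as.double(seed))
  model <- structure(
    list(trees = fit$trees,
         bootstrap = fit$bootstrap,
         oob = fit$oob,
         oob_trajectory = fit$oob_trajectory,
         oob_trajectory_raw = fit$oob_trajectory_raw,
         oob_votes = fit$oob_votes,
         mtry = mtry, ntree = ntree, class_weights = w, seed = seed,
         n = n_samples(x), p = p,
         snp_id = snp_ids(x), phenotype = x$phenotype),
    class = "snp_forest"
  )
  if (importance) {
    model$importance <- permutation_importance(model, x, seed = seed + 1)
  }
  model
}

#' @export
print.snp_forest <- function(x, ...) {
  cat(sprintf("<snp_forest> %d trees, mtry = %d, %d samples x %d SNPs\n",
              x$ntree, x$mtry, x$n, x$p))
  cat(sprintf("  OOB error: %.4f (balanced), %.4f (raw)\n",
              oob_error(x), oob_error(x, type = "raw")))
  invisible(x)
}

#' Out-of-bag error rate of a forest
#'
#' Each sample is classified by a class-weighted vote over the trees in
#' which it is out-of-bag. `"balanced"` (default) averages the per-class
#' misclassification rates with the class weights, so the balanced default
#' weighting gives the mean of the sensitivity and specificity
#' complements; `"raw"` is the plain misclassification fraction. Samples
#' never out-of-bag are excluded with a warning.
#'
#' @param model A `snp_forest`.
#' @param x Optional `geno_data`; phenotypes stored on the model are used
#'   when omitted.
#' @param type `"balanced"` or `"raw"`.
#' @return Error rate in \[0, 1\].
#' @export
oob_error <- function(model, x = NULL, type = c("balanced", "raw")) {
  stopifnot(inherits(model, "snp_forest"))
  type <- match.arg(type)
  y <- if (is.null(x)) model$phenotype else x$phenotype
  votes <- model$oob_votes
  w <- model$class_weights
  has_vote <- rowSums(votes) > 0
  if (!all(has_vote)) {
    warning(sprintf("%d sample(s) never out-of-bag; excluded from OOB error",
                    sum(!has_vote)), call. = FALSE)
  }
  pred <- as.integer(w[2] * votes[, 2] > w[1] * votes[, 1])
  y <- y[has_vote]
  pred <- pred[has_vote]
  if (type == "raw") return(mean(pred != y))
  e0 <- mean(pred[y == 0L] != 0L)
  e1 <- mean(pred[y == 1L] != 1L)
  (w[1] * e0 + w[2] * e1) / sum(w)
}

#' Permutation variable importance
#'
#' For each tree and each SNP appearing in that tree, the SNP's values are
#' permuted among the tree's out-of-bag samples and the OOB
#' (class-weighted) accuracy recomputed; the SNP's score is the mean over
#' all trees of the accuracy decrease, with trees not containing the SNP
#' contributing 0. Scores are unscaled (no standard-error division): the
#' screening protocol ranks raw importances. A SNP never selected into any
#' tree scores exactly 0.
#'
#' @param model A `snp_forest`.
#' @param x The `geno_data` the model was fitted on.
#' @param seed Integer seed for the permutations.
#' @return A `snp_vi` tibble with columns `snp_id`, `score`, and `rank`
#'   (1 = most important; ties broken by SNP order).
#' @export
permutation_importance <- function(model, x, seed = 1) {
  stopifnot(inherits(model, "snp_forest"), inherits(x, "geno_data"))
  if (n_snps(x) != model$p) {
    stop("dataset does not match the fitted model", call. = FALSE)
  }
  w <- model$class_weights
  score <- cpp_permutation_importance(model$trees, model$oob, x$genotypes,
                                      x$phenotype, w[1], w[2],
                                      as.double(seed))
  vi_table(snp_ids(x), score)
}

# internal: build a ranked VI tibble
vi_table <- function(snp_id, score) {
  ord <- order(-score)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- tibble::tibble(snp_id = snp_id, score = as.numeric(score),
                        rank = rank)
  class(out) <- c("snp_vi", class(out))
  out
}

#' Top-k SNP ids of a variable-importance table
#'
#' @param vi A `snp_vi` tibble.
#' @param k Number of SNPs.
#' @return Character vector of the `k` best-ranked SNP ids.
#' @export
top_snps <- function(vi, k = 25) {
  vi$snp_id[order(vi$rank)][seq_len(min(k, nrow(vi)))]
}

#' Predict class labels from a fitted forest
#'
#' Class-weighted majority vote across all trees; ties go to the control
#' class. Vote fractions over trees sum to 1 per sample.
#'
#' @param object A `snp_forest`.
#' @param newdata A `geno_data` or dosage matrix with `p` columns matching
#'   the model.
#' @param ... Unused.
#' @return Tibble with `sample_id`, predicted `class` (0/1), and
#'   `vote_control` / `vote_case` fractions.
#' @export
predict.snp_forest <- function(object, newdata, ...) {
  geno <- if (inherits(newdata, "geno_data")) newdata$genotypes else newdata
  storage.mode(geno) <- "integer"
  if (ncol(geno) != object$p) {
    stop(sprintf("newdata has %d SNP columns; model expects %d",
                 ncol(geno), object$p), call. = FALSE)
  }
  if (anyNA(geno)) stop("missing genotypes in newdata", call. = FALSE)
  votes <- cpp_predict_votes(object$trees, geno)
  w <- object$class_weights
  frac <- votes / object$ntree
  tibble::tibble(
    sample_id = if (!is.null(rownames(geno))) rownames(geno) else
      sprintf("S%d", seq_len(nrow(geno))),
    class = as.integer(w[2] * votes[, 2] > w[1] * votes[, 1]),
    vote_control = frac[, 1],
    vote_case = frac[, 2]
  )
}

#' Optimal binary split at a node
#'
#' Exhaustive search over the candidate SNPs and the three binary
#' partitions of `{0, 1, 2}` (`{0}|{1,2}`, `{0,1}|{2}`, `{0,2}|{1}`) for
#' the maximal class-weighted Gini impurity decrease. Partitions with an
#' empty side at the node are skipped; ties are broken by lower SNP index,
#' then partition order. Returns `NULL` when the node is pure or no
#' candidate admits a valid split.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param rows Sample indices forming the node (repeats allowed, as in a
#'   bootstrap).
#' @param candidates SNP column indices to search.
#' @param class_weights Optional `(control, case)` weights; `NULL` for
#'   balanced (computed on the full dataset).
#' @return `NULL`, or a list with `snp` (column index), `snp_id`,
#'   `partition` (1-3, the left-branch sets above) and `decrease`.
#' @export
best_split <- function(x, rows, candidates, class_weights = NULL) {
  stopifnot(inherits(x, "geno_data"))
  check_fit_ready(x)
  if (length(rows) == 0 || length(candidates) == 0) {
    stop("`rows` and `candidates` must be non-empty", call. = FALSE)
  }
  w <- resolve_class_weights(x$phenotype, class_weights)
  res <- cpp_best_split(x$genotypes, x$phenotype, as.integer(rows),
                        as.integer(candidates), w[1], w[2])
  if (is.null(res)) return(NULL)
  res$snp_id <- snp_ids(x)[res$snp]
  res
}

#' Grow a single unpruned tree
#'
#' One tree of the forest, on an explicit bootstrap sample. With
#' `mtry = p` the candidate subset is the full SNP panel at every node and
#' the tree equals an exhaustive CART search with the package's tie rules.
#'
#' @param x A complete `geno_data` with phenotypes.
#' @param bootstrap Sample indices (with multiplicity) to grow on.
#' @param mtry Candidates per node.
#' @param class_weights Optional `(control, case)` weights.
#' @param seed Integer seed for the per-node candidate draws.
#' @return A `snp_tree`: list with `nodes` (split SNP, partition, children;
#'   `NA` marks terminals) and `votes` (weighted class counts per node).
#' @export
grow_tree <- function(x, bootstrap, mtry, class_weights = NULL, seed = 1) {
  stopifnot(inherits(x, "geno_data"))
  check_fit_ready(x)
  if (length(bootstrap) == 0) {
    stop("`bootstrap` must be non-empty", call. = FALSE)
  }
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > n_snps(x)) {
    stop("`mtry` must lie in [1, p]", call. = FALSE)
  }
  w <- resolve_class_weights(x$phenotype, class_weights)
  tr <- cpp_grow_tree(x$genotypes, x$phenotype, as.integer(bootstrap),
                      mtry, w[1], w[2], as.double(seed))
  tr$snp_id <- snp_ids(x)
  class(tr) <- "snp_tree"
  tr
}

#' Serialize a forest to JSON lines
#'
#' One JSON object per line per tree, with the node table (split SNP id,
#' partition code, children) and terminal weighted votes, so any tree can
#' be inspected or replayed without a binary format.
#'
#' @param model A `snp_forest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  stopifnot(inherits(model, "snp_forest"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(ntree = model$ntree, mtry = model$mtry,
         class_weights = model$class_weights, seed = model$seed,
         n = model$n, p = model$p, snp_id = model$snp_id),
    auto_unbox = TRUE)
  writeLines(header, con)
  for (t in seq_len(model$ntree)) {
    tr <- model$trees[[t]]
    writeLines(jsonlite::toJSON(
      list(tree = t, nodes = tr$nodes, votes = tr$votes),
      auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted forest into its variable-importance table
#'
#' @param x A `snp_forest` fitted with `importance = TRUE`.
#' @param ... Unused.
#' @return The stored `snp_vi` tibble (`snp_id`, `score`, `rank`).
#' @method tidy snp_forest
#' @export
tidy.snp_forest <- function(x, ...) {
  if (is.null(x$importance)) {
    stop("fit with importance = TRUE or call permutation_importance()",
         call. = FALSE)
  }
  x$importance
}

#' One-row model summary of a fitted forest
#'
#' @param x A `snp_forest`.
#' @param ... Unused.
#' @return Tibble with dimensions, parameters and final OOB error rates.
#' @method glance snp_forest
#' @export
glance.snp_forest <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, ntree = x$ntree, mtry = x$mtry,
    oob_error = oob_error(x),
    oob_error_raw = oob_error(x, type = "raw")
  )
}
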