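test_that("best_split matches an exhaustive enumeration oracle", {
  set.seed(7)
  for (rep in 1:20) {
    geno <- matrix(sample(0:2, 8 * 4, replace = TRUE), 8, 4)
    y <- sample(c(0L, 1L), 8, replace = TRUE)
    if (length(unique(y)) < 2) next
    x <- make_dataset(geno, y)
    got <- best_split(x, rows = 1:8, candidates = 1:4,
                      class_weights = c(1, 1))
    want <- oracle_best_split(geno, y, 1:8, 1:4)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$snp, want$snp)
      expect_identical(got$partition, want$partition)
      expect_equal(got$decrease, want$decrease, tolerance = 1e-12)
    }
  }
})

test_that("best_split is absent on pure or constant nodes", {
  geno <- matrix(sample(0:2, 20, replace = TRUE), 10, 2)
  pure <- make_dataset(geno, c(rep(0L, 5), rep(1L, 5)))
  expect_null(best_split(pure, rows = 1:5, candidates = 1:2))  # one class
  const <- make_dataset(matrix(1L, 10, 2), rep(c(0L, 1L), 5))
  expect_null(best_split(const, rows = 1:10, candidates = 1:2))
})

test_that("a perfectly separating SNP is split first and yields a stump", {
  x <- perfect_sep_data(n = 40, p = 5)
  tr <- grow_tree(x, bootstrap = 1:40, mtry = 5, seed = 3)
  expect_identical(unname(tr$nodes[1, "split_snp"]), 1L)
  kids <- tr$nodes[1, c("left", "right")]
  expect_true(all(is.na(tr$nodes[kids, "split_snp"])))
})

test_that("single-sample bootstraps give a terminal root", {
  x <- perfect_sep_data(n = 10, p = 3)
  tr <- grow_tree(x, bootstrap = 4, mtry = 3, seed = 1)
  expect_identical(nrow(tr$nodes), 1L)
  expect_true(is.na(tr$nodes[1, "split_snp"]))
})

test_that("tree growth is deterministic given the seed", {
  set.seed(5)
  geno <- matrix(sample(0:2, 20 * 5, replace = TRUE), 20, 5)
  x <- make_dataset(geno, rep(c(0L, 1L), 10))
  boot <- sample(1:20, 20, replace = TRUE)
  t1 <- grow_tree(x, boot, mtry = 2, seed = 42)
  t2 <- grow_tree(x, boot, mtry = 2, seed = 42)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$votes, t2$votes)
})

test_that("single trees with mtry = p equal exhaustive-search CART", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    p <- sample(2:4, 1)
    geno <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    x <- make_dataset(geno, y)
    tr <- grow_tree(x, bootstrap = seq_len(n), mtry = p,
                    class_weights = c(1, 1), seed = rep)
    oracle <- oracle_cart(geno, y, seq_len(n))
    expect_true(isTRUE(trees_identical(tr, oracle)))
  }
})

test_that("forest construction rejects invalid parameters", {
  x <- perfect_sep_data()
  expect_error(grow_forest(x, ntree = 0), "ntree")
  expect_error(grow_forest(x, mtry = n_snps(x) + 1), "mtry")
  expect_error(grow_forest(x, mtry = 0), "mtry")
})

test_that("per-tree OOB fraction matches the bootstrap closed form", {
  n <- 30L
  x <- make_dataset(random_geno(n, 10, seed = 2), rep(c(0L, 1L), 15))
  fit <- grow_forest(x, mtry = 3, ntree = 200, seed = 9)
  frac <- mean(lengths(fit$oob)) / n
  q <- (1 - 1 / n)^n
  se <- sqrt(q * (1 - q) / (n * 200))
  expect_lt(abs(frac - q), 3 * se)
  # bootstrap multiset size is n per tree; OOB = complement of the bag
  expect_identical(ncol(fit$bootstrap), n)
  bag1 <- unique(fit$bootstrap[1, ])
  expect_setequal(fit$oob[[1]], setdiff(1:n, bag1))
})

test_that("strong separation drives OOB error to ~0 and null data to ~0.5", {
  sep <- perfect_sep_data(n = 60, p = 8)
  fit <- grow_forest(sep, mtry = 8, ntree = 100, seed = 1)
  expect_lt(oob_error(fit), 0.05)
  expect_identical(predict(fit, sep)$class, sep$phenotype)

  nul <- null_data(n = 200, p = 50, seed = 3)
  fit0 <- grow_forest(nul, mtry = 7, ntree = 200, seed = 2)
  expect_lt(abs(oob_error(fit0) - 0.5), 0.05)
})

test_that("forests are reproducible and prediction votes normalize", {
  x <- causal_sim(60, 60, 40, 5L, 2.5, seed = 61)
  f1 <- grow_forest(x, mtry = 6, ntree = 50, seed = 4, importance = TRUE)
  f2 <- grow_forest(x, mtry = 6, ntree = 50, seed = 4, importance = TRUE)
  expect_identical(f1$oob_trajectory, f2$oob_trajectory)
  expect_identical(tidy(f1), tidy(f2))

  pr <- predict(f1, x)
  expect_equal(pr$vote_control + pr$vote_case, rep(1, n_samples(x)))
  expect_error(predict(f1, x$genotypes[, 1:10]), "columns")

  g <- glance(f1)
  expect_identical(g$ntree, 50L)
  expect_true(g$oob_error >= 0 && g$oob_error <= 1)
})

test_that("a SNP absent from every tree scores exactly zero importance", {
  set.seed(8)
  geno <- cbind(sample(0:2, 30, replace = TRUE),
                sample(0:2, 30, replace = TRUE),
                2L)  # constant column: never splittable
  x <- make_dataset(geno, rep(c(0L, 1L), 15))
  fit <- grow_forest(x, mtry = 3, ntree = 50, seed = 5)
  vi <- permutation_importance(fit, x, seed = 6)
  expect_identical(vi$score[3], 0)
})

test_that("single-tree importance equals a hand re-pass with the replayed permutation", {
  set.seed(12)
  geno <- matrix(sample(0:2, 12 * 3, replace = TRUE), 12, 3)
  y <- rep(c(0L, 1L), 6)
  x <- make_dataset(geno, y)
  fit <- grow_forest(x, mtry = 2, ntree = 1, class_weights = c(1, 1),
                     seed = 31)
  vi_seed <- 77
  vi <- permutation_importance(fit, x, seed = vi_seed)

  tree <- fit$trees[[1]]
  oob <- fit$oob[[1]]
  used <- sort(unique(tree$nodes[, "split_snp"]))
  used <- used[!is.na(used)]
  base <- mean(vapply(oob, function(i) {
    walk_tree_class(tree, geno, i) == y[i]
  }, logical(1)))
  perms <- snpforest:::cpp_vi_perms(vi_seed, 1, length(oob), length(used))
  expected <- rep(0, 3)
  for (u in seq_along(used)) {
    acc <- mean(vapply(seq_along(oob), function(k) {
      walk_tree_class(tree, geno, oob[k], perm_snp = used[u],
                      perm_row = oob[perms[u, k]]) == y[oob[k]]
    }, logical(1)))
    expected[used[u]] <- base - acc
  }
  expect_equal(vi$score, expected, tolerance = 1e-12)
})

test_that("samples never out-of-bag are excluded with a warning", {
  x <- perfect_sep_data(n = 30, p = 4)
  fit <- grow_forest(x, mtry = 4, ntree = 1, seed = 2)
  expect_warning(oob_error(fit), "never out-of-bag")
})

test_that("sparsity rises with mtry and falls with ntree", {
  # the trend lives in the incomplete-coverage regime: p large relative
  # to the number of distinct SNPs the forest can visit
  sp <- function(mtry, ntree, seed) {
    x <- causal_sim(60, 60, 1000, c(100L, 600L), 2.5, seed = seed)
    fit <- grow_forest(x, mtry = mtry, ntree = ntree, seed = seed + 500)
    sparsity_fraction(permutation_importance(fit, x, seed = seed + 900))
  }
  seeds <- 1:10
  base <- mean(vapply(seeds, function(s) sp(10, 40, s), numeric(1)))
  hi_mtry <- mean(vapply(seeds, function(s) sp(100, 40, s), numeric(1)))
  expect_gt(hi_mtry, base)
  hi_ntree <- mean(vapply(seeds, function(s) sp(10, 400, s), numeric(1)))
  expect_lt(hi_ntree, base)
})

test_that("forests serialize to JSON lines", {
  x <- perfect_sep_data(n = 20, p = 3)
  fit <- grow_forest(x, mtry = 3, ntree = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_forest_json(fit, path)
  lines <- readLines(path)
  expect_identical(length(lines), 6L)  # header + one line per tree
  header <- jsonlite::fromJSON(lines[1])
  expect_identical(header$ntree, 5L)
  tree1 <- jsonlite::fromJSON(lines[2])
  expect_identical(tree1$tree, 1L)
  expect_true(all(c("nodes", "votes") %in% names(tree1)))
})

test_that("OOB error agrees with an independent forest implementation", {
  x <- causal_sim(150, 150, 60, c(10L, 40L), 3, seed = 301)
  fit <- grow_forest(x, mtry = 8, ntree = 300, seed = 2)
  # independent route: the classical CART-forest implementation with the
  # dosages as 3-level factors (same binary-partition split space)
  preds <- as.data.frame(lapply(as.data.frame(x$genotypes), factor))
  rf <- randomForest::randomForest(x = preds, y = factor(x$phenotype),
                                   mtry = 8, ntree = 300)
  err_rf <- mean(rf$err.rate[300, c("0", "1")])
  expect_lt(abs(oob_error(fit) - err_rf), 0.1)
})
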