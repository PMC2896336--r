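test_that("pairwise r2 matches the squared-correlation definition", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  g2 <- c(0, 1, 0, 2, 1, 2)
  expect_equal(ld_r2(g1, g2), stats::cor(g1, g2)^2)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)  # perfect negative correlation
  expect_error(ld_r2(g1, g2[1:3]), "equal length")
  expect_warning(r <- ld_r2(g1, rep(1, 6)), "constant")
  expect_true(is.na(r))
})

test_that("pairwise r2 is symmetric and allele-relabeling invariant", {
  set.seed(14)
  for (rep in 1:20) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(ld_r2(a, b), ld_r2(b, a))
    expect_equal(ld_r2(a, b), ld_r2(2 - a, b))
    expect_equal(ld_r2(a, b), ld_r2(a, 2 - b))
  }
})

test_that("independent SNPs survive pruning; duplicates do not", {
  x <- make_dataset(random_geno(300, 20, seed = 15),
                    rep(c(0L, 1L), 150))
  for (thr in c(0.99, 0.5)) {
    expect_identical(ld_prune(x, thr, method = "window_r2"),
                     snp_ids(x), ignore_attr = TRUE)
    expect_identical(ld_prune(x, thr, method = "pairwise_r2"),
                     snp_ids(x), ignore_attr = TRUE)
  }
  # plant an exact duplicate pair: exactly one of the two is removed
  geno <- random_geno(100, 10, seed = 16)
  geno[, 6] <- geno[, 5]
  dup <- make_dataset(geno, rep(c(0L, 1L), 50))
  kept <- ld_prune(dup, 0.99, method = "window_r2")
  expect_identical(length(kept), 9L)
  expect_true(xor("snp00005" %in% kept, "snp00006" %in% kept))
})

test_that("window pruning with a full-width window equals the exhaustive oracle", {
  set.seed(17)
  geno <- random_geno(120, 30, seed = 17)
  # planted 3-SNP linear dependency (collinear block, up to noise)
  geno[, 12] <- pmin(2L, pmax(0L, geno[, 10] + geno[, 11] - 1L))
  geno[, 20] <- geno[, 19]
  x <- make_dataset(geno, rep(c(0L, 1L), 60))
  for (thr in c(0.9, 0.5)) {
    kept <- ld_prune(x, thr, method = "window_r2", window_size = 30,
                     window_step = 5)
    oracle <- oracle_ld_prune(geno, thr)
    expect_identical(kept, snp_ids(x)[oracle], ignore_attr = TRUE)
  }
})

test_that("after pairwise pruning no retained window pair exceeds the threshold", {
  x <- causal_sim(150, 150, 200, integer(0), numeric(0), seed = 18,
                  maf_range = c(0.1, 0.5), ld_rho = 0.9)
  thr <- 0.5
  kept <- ld_prune(x, thr, method = "pairwise_r2", window_size = 20,
                   window_step = 5)
  sub <- subset_snps(x, kept)
  for (ch in unique(sub$snp_info$chrom)) {
    cols <- which(sub$snp_info$chrom == ch)
    cols <- cols[order(sub$snp_info$pos[cols])]
    for (ws in seq(1, length(cols), by = 5)) {
      win <- cols[ws:min(ws + 19, length(cols))]
      if (length(win) < 2) next
      r2 <- stats::cor(sub$genotypes[, win])^2
      diag(r2) <- 0
      expect_lte(max(r2), thr)
    }
  }
})

test_that("pairwise pruning is monotone in the threshold on an LD-blocked panel", {
  x <- causal_sim(200, 200, 150, integer(0), numeric(0), seed = 19,
                  maf_range = c(0.1, 0.5), ld_rho = 0.8)
  kept_hi <- ld_prune(x, 0.8, method = "pairwise_r2")
  kept_lo <- ld_prune(x, 0.3, method = "pairwise_r2")
  expect_true(all(kept_lo %in% kept_hi))
})

test_that("lower thresholds remove strictly more of an LD-blocked panel", {
  # blocks at latent rho 0.95 plus a near-duplicate strong-locus cluster,
  # so every threshold from 0.99 down to 0.33 has something to remove
  x <- simulate_gwas(sim_config(
    n_cases = 300, n_controls = 300, p = 300, maf_range = c(0.05, 0.5),
    ld_rho = 0.95, missing_rate = 0,
    strong_locus = strong_locus_spec(block_index = 3, n_snps = 10,
                                     or_per_allele = 1.5, maf = 0.3),
    seed = 20))
  removed <- vapply(c(0.99, 0.90, 0.80, 0.50, 0.33), function(thr) {
    length(attr(ld_prune(x, thr, method = "window_r2"), "pruned"))
  }, numeric(1))
  expect_true(all(diff(removed) > 0))
})

test_that("prune lists are written in the prune.in/prune.out convention", {
  geno <- random_geno(80, 6, seed = 21)
  geno[, 2] <- geno[, 1]
  x <- make_dataset(geno, rep(c(0L, 1L), 40))
  kept <- ld_prune(x, 0.99, method = "pairwise_r2")
  dir <- withr::local_tempdir()
  write_prune_lists(kept, file.path(dir, "ld"))
  expect_identical(readLines(file.path(dir, "ld.prune.in")),
                   as.character(kept))
  expect_identical(readLines(file.path(dir, "ld.prune.out")), "snp00002")
})

test_that("tag sets include the SNP itself and respect the r2 threshold", {
  x <- causal_sim(1000, 1000, 30, integer(0), numeric(0), seed = 22,
                  maf_range = c(0.2, 0.4), ld_rho = 0.98)
  tm <- find_tag_snps(x, c("snp00005", "snp00015"), r2_threshold = 0.5)
  expect_s3_class(tm, "tag_map")
  expect_true("snp00005" %in% tm$tag_snp[tm$ref_snp == "snp00005"])
  # a tight-LD block (latent rho 0.98): all block members tag its centre
  block1 <- sprintf("snp%05d", 1:10)
  expect_true(all(block1 %in% tm$tag_snp[tm$ref_snp == "snp00005"]))
  # tagging never crosses chromosomes
  expect_true(all(tm$tag_snp[tm$ref_snp == "snp00005"] %in%
                    snp_ids(x)[x$snp_info$chrom ==
                                 x$snp_info$chrom[5]]))
  expect_warning(res <- find_tag_snps(x, "rs_absent"), "absent")
  expect_identical(nrow(res), 0L)
})

test_that("a marginal tag pair is classified by the threshold comparison", {
  # construct two SNPs with controlled r2 around 0.5
  set.seed(23)
  n <- 2000
  a <- stats::rbinom(n, 2, 0.4)
  make_corr <- function(a, flip_frac) {
    b <- a
    swap <- sample(n, round(flip_frac * n))
    b[swap] <- stats::rbinom(length(swap), 2, 0.4)
    b
  }
  hi <- make_corr(a, 0.25)   # r2 well above 0.5
  lo <- make_corr(a, 0.70)   # r2 well below 0.5
  stopifnot(stats::cor(a, hi)^2 > 0.5, stats::cor(a, lo)^2 < 0.5)
  x <- make_dataset(cbind(a, hi, lo), rep(c(0L, 1L), n / 2))
  tm <- find_tag_snps(x, "snp00001", r2_threshold = 0.5)
  tags <- tm$tag_snp[tm$ref_snp == "snp00001"]
  expect_true("snp00002" %in% tags)
  expect_false("snp00003" %in% tags)
  tm2 <- find_tag_snps(x, "snp00002", r2_threshold = 0.5)
  expect_true("snp00001" %in% tm2$tag_snp)  # mutual tagging
})
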