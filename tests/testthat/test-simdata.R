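test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_cases = 0), ">= 1")
  expect_error(sim_config(p = 0), ">= 1")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(missing_rate = 0.06), "missing_rate")
  expect_error(sim_config(p = 10, causal_effects =
                            list(causal_effect(11, "additive", 1.5))),
               "exceeds p")
  expect_error(causal_effect(1, "additive", -2), "positive")
  expect_error(causal_effect(1, "additive", Inf), "positive")
})

test_that("genotypes are 0/1/2 dosages with MAFs near their targets", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, p = 100,
                    ld_rho = 0, missing_rate = 0, seed = 3)
  x <- simulate_genotypes(cfg, n = 2000)
  expect_true(all(x$genotypes %in% 0:2))
  target <- x$snp_info$target_maf
  se <- sqrt(target * (1 - target) / (2 * 2000))
  dev <- abs(snp_maf(x) - target)
  # under independent HWE sampling nearly all SNPs sit inside the 99%
  # binomial interval of their target
  expect_gte(mean(dev <= stats::qnorm(0.995) * se), 0.95)
  expect_true(all(dev <= 5 * se))
})

test_that("adjacent-SNP r2 matches a Monte-Carlo oracle of the thresholded latent model", {
  cfg <- sim_config(n_cases = 1, n_controls = 1, p = 20, ld_block_size = 10,
                    ld_rho = 0.9, missing_rate = 0, seed = 5)
  x <- simulate_genotypes(cfg, n = 20000)
  # adjacent pairs within blocks only
  pairs <- cbind(1:19, 2:20)[-10, , drop = FALSE]
  obs <- vapply(seq_len(nrow(pairs)), function(k) {
    stats::cor(x$genotypes[, pairs[k, 1]], x$genotypes[, pairs[k, 2]])^2
  }, numeric(1))

  # independent oracle: directly simulate the thresholded bivariate-normal
  # construction for each pair's target MAFs
  set.seed(99)
  m <- 200000
  maf <- x$snp_info$target_maf
  thresh_geno <- function(z, q) {
    (z > stats::qnorm((1 - q)^2)) +
      (z > stats::qnorm((1 - q)^2 + 2 * q * (1 - q)))
  }
  oracle <- vapply(seq_len(nrow(pairs)), function(k) {
    z1 <- stats::rnorm(m)
    z2 <- 0.9 * z1 + sqrt(1 - 0.81) * stats::rnorm(m)
    stats::cor(thresh_geno(z1, maf[pairs[k, 1]]),
               thresh_geno(z2, maf[pairs[k, 2]]))^2
  }, numeric(1))
  expect_lt(abs(mean(obs) - mean(oracle)), 0.02)
})

test_that("phenotype assignment hits quotas and the allelic odds-ratio closed form", {
  # rare-disease regime: empirical case allele frequency follows
  # or*p0 / (1 + p0*(or-1))
  cfg <- sim_config(n_cases = 800, n_controls = 800, p = 5,
                    maf_range = c(0.5, 0.5), ld_rho = 0, missing_rate = 0,
                    seed = 11)
  pool <- simulate_genotypes(cfg, n = 60000)
  x <- assign_phenotypes(pool,
                         effects = list(causal_effect(1, "additive", 1.3)),
                         n_cases = 800, n_controls = 800, seed = 12,
                         intercept = -4)
  expect_identical(sum(x$phenotype == 1L), 800L)
  expect_identical(sum(x$phenotype == 0L), 800L)
  case_maf <- mean(x$genotypes[x$phenotype == 1L, 1]) / 2
  expect_equal(expected_case_maf(0.5, 1.3), 0.5652, tolerance = 1e-4)
  expect_lt(abs(case_maf - expected_case_maf(0.5, 1.3)), 0.03)
})

test_that("case-control allele frequency difference grows with the odds ratio", {
  p0 <- 0.3
  deltas <- expected_case_maf(p0, c(1.2, 1.5, 2.0)) - p0
  expect_true(all(diff(deltas) > 0))
  expect_equal(expected_case_maf(p0, 1), p0)
})

test_that("null simulation produces chi-square(1) marginal statistics", {
  x <- causal_sim(500, 500, 5000, integer(0), numeric(0), seed = 21,
                  maf_range = c(0.1, 0.5), ld_rho = 0)
  stats_tab <- allelic_chisq(x)
  expect_lt(abs(mean(stats_tab$chisq) - 1), 0.1)
  ks <- suppressWarnings(
    stats::ks.test(stats_tab$chisq, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
  expect_true(genomic_inflation(stats_tab) >= 0.9 &&
                genomic_inflation(stats_tab) <= 1.1)
})

test_that("strong locus reaches chi-square magnitudes typical of a major MHC signal", {
  x <- causal_sim(931, 2431, 200, integer(0), numeric(0), seed = 31,
                  maf_range = c(0.05, 0.5), ld_rho = 0.8,
                  strong_locus = strong_locus_spec(block_index = 2,
                                                   n_snps = 10,
                                                   or_per_allele = 3,
                                                   maf = 0.17))
  tab <- allelic_chisq(x)
  top <- max(tab$chisq[tab$chrom == "6"])
  # order of the largest marginal signals seen on real 500K panels (~10^2)
  expect_gt(top, 100)
  expect_lt(top, 1000)
})

test_that("missingness injection is bounded, calibrated and seed-stable", {
  x <- causal_sim(100, 100, 200, integer(0), numeric(0), seed = 41)
  expect_identical(add_missingness(x, 0), x)
  expect_error(add_missingness(x, 0.06), "rate")
  xm <- add_missingness(x, 0.01, seed = 7)
  frac <- mean(is.na(xm$genotypes))
  se <- sqrt(0.01 * 0.99 / length(xm$genotypes))
  expect_lt(abs(frac - 0.01), 3 * se)
  expect_identical(add_missingness(x, 0.01, seed = 7)$genotypes,
                   xm$genotypes)
})

test_that("identical configurations give bit-identical datasets", {
  cfg <- sim_config(n_cases = 60, n_controls = 140, p = 120,
                    causal_effects = list(causal_effect(7, "dominant", 1.8),
                                          causal_effect(30, "recessive", 2,
                                                        epistasis_partner = 31)),
                    seed = 99)
  x1 <- simulate_gwas(cfg)
  x2 <- simulate_gwas(cfg)
  expect_identical(x1$genotypes, x2$genotypes)
  expect_identical(x1$phenotype, x2$phenotype)
  expect_identical(sim_truth(x1), sim_truth(x2))
  expect_identical(sum(x1$phenotype), 60L)
  truth <- sim_truth(x1)
  expect_setequal(which(truth$causal), c(7L, 30L))
})

test_that("truth files round-trip through the tab-separated format", {
  x <- causal_sim(50, 50, 30, c(5L), 2, seed = 51)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(x, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 30L)
  expect_identical(back$snp_id[back$causal], "snp00005")
})
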