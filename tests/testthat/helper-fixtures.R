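# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# dataset from a raw dosage matrix + labels (zero-padded SNP ids)
make_dataset <- function(geno, y = NULL, chrom = NULL, pos = NULL) {
  info <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(ncol(geno))),
    chrom = if (is.null(chrom)) "1" else chrom,
    pos = if (is.null(pos)) seq_len(ncol(geno)) * 1000L else pos)
  genotype_dataset(geno, phenotype = y, snp_info = info)
}

# independent random dosages under HWE at the given MAF(s)
random_geno <- function(n, p, maf = 0.3, seed = 1) {
  set.seed(seed)
  matrix(stats::rbinom(n * p, 2, maf), n, p)
}

# one SNP (column 1) perfectly separating cases from controls, plus noise
perfect_sep_data <- function(n = 40, p = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  geno <- matrix(stats::rbinom(n * p, 2, 0.3), n, p)
  geno[, 1] <- ifelse(y == 1L, 2L, 0L)
  make_dataset(geno, y)
}

# labels independent of genotypes (null data)
null_data <- function(n = 200, p = 50, seed = 1) {
  set.seed(seed)
  geno <- matrix(stats::rbinom(n * p, 2, stats::runif(p, 0.1, 0.5)[rep(
    seq_len(p), each = n)]), n, p)
  y <- rep(c(0L, 1L), length.out = n)
  make_dataset(geno, y)
}

# small simulated dataset with planted additive causal SNPs
causal_sim <- function(n_cases, n_controls, p, causal_idx, or, seed,
                       maf_range = c(0.2, 0.4), ld_rho = 0,
                       strong_locus = NULL) {
  eff <- lapply(seq_along(causal_idx), function(i) {
    causal_effect(causal_idx[i], "additive",
                  if (length(or) == 1) or else or[i])
  })
  simulate_gwas(sim_config(
    n_cases = n_cases, n_controls = n_controls, p = p,
    maf_range = maf_range, ld_rho = ld_rho, missing_rate = 0,
    causal_effects = eff, strong_locus = strong_locus, seed = seed))
}
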