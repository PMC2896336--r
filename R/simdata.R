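#' Configuration for a synthetic case-control GWAS dataset
#'
#' Describes the generative model the package uses as a stand-in for a real
#' case-control SNP panel: per-SNP minor-allele frequencies drawn from a
#' range, blockwise linkage disequilibrium from a latent Gaussian AR(1)
#' process thresholded at Hardy-Weinberg genotype frequencies, a logistic
#' disease model over a small set of causal SNPs
#' (additive/dominant/recessive, optionally epistatic), an optional
#' high-LD "strong locus" cluster, and sub-1% missingness.
#'
#' Defaults mirror a typical 500K-array case-control study: 931 cases and
#' 2,431 controls (about a 1:2.6 class imbalance), MAF spectrum 0.05-0.50,
#' LD blocks of 10 SNPs with latent adjacent correlation 0.8, and 0.5%
#' missing entries.
#'
#' @param n_cases,n_controls Target class sizes (both >= 1).
#' @param p Number of SNPs (>= 1).
#' @param maf_range Length-2 numeric in (0, 0.5]: per-SNP target minor
#'   allele frequencies are drawn uniformly from this range.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho Latent adjacent correlation within a block, in \[0, 1).
#' @param causal_effects List of [causal_effect()] objects.
#' @param strong_locus Optional [strong_locus_spec()].
#' @param missing_rate Fraction of entries set missing, in \[0, 0.05\].
#' @param seed Master integer seed; all sub-streams are derived from it by
#'   fixed offsets.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 931, n_controls = 2431, p = 5000,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.8, causal_effects = list(),
                       strong_locus = NULL, missing_rate = 0.005,
                       seed = 1) {
  if (n_cases < 1 || n_controls < 1 || p < 1) {
    stop("n_cases, n_controls and p must all be >= 1", call. = FALSE)
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) {
    stop("`ld_rho` must be in [0, 1)", call. = FALSE)
  }
  if (ld_block_size < 1) stop("`ld_block_size` must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 0.05) {
    stop("`missing_rate` must be in [0, 0.05]", call. = FALSE)
  }
  for (eff in causal_effects) {
    if (!inherits(eff, "causal_effect")) {
      stop("`causal_effects` must be a list of causal_effect()", call. = FALSE)
    }
    if (eff$snp_index > p) {
      stop("causal SNP index exceeds p", call. = FALSE)
    }
    if (!is.null(eff$epistasis_partner) && eff$epistasis_partner > p) {
      stop("epistasis partner index exceeds p", call. = FALSE)
    }
  }
  if (!is.null(strong_locus)) {
    stopifnot(inherits(strong_locus, "strong_locus_spec"))
    hi <- (strong_locus$block_index - 1L) * ld_block_size + strong_locus$n_snps
    if (hi > p) stop("strong locus extends past p", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         p = as.integer(p), maf_range = as.numeric(maf_range),
         ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
         causal_effects = causal_effects, strong_locus = strong_locus,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Declare a causal SNP effect
#'
#' @param snp_index Column index of the causal SNP.
#' @param model Penetrance encoding: `"additive"` (dosage), `"dominant"`
#'   (dosage >= 1) or `"recessive"` (dosage == 2).
#' @param or_per_allele Odds ratio per encoded unit (> 0, finite).
#' @param epistasis_partner Optional partner SNP index; adds a product
#'   interaction term between the two encoded genotypes.
#' @param epistasis_or Odds ratio of the interaction term (defaults to
#'   `or_per_allele` when a partner is given).
#' @return A `causal_effect` object.
#' @export
causal_effect <- function(snp_index,
                          model = c("additive", "dominant", "recessive"),
                          or_per_allele, epistasis_partner = NULL,
                          epistasis_or = NULL) {
  model <- match.arg(model)
  if (!is.finite(or_per_allele) || or_per_allele <= 0) {
    stop("`or_per_allele` must be finite and positive", call. = FALSE)
  }
  if (!is.null(epistasis_partner) && is.null(epistasis_or)) {
    epistasis_or <- or_per_allele
  }
  structure(
    list(snp_index = as.integer(snp_index), model = model,
         or_per_allele = or_per_allele,
         epistasis_partner = if (is.null(epistasis_partner)) NULL else
           as.integer(epistasis_partner),
         epistasis_or = epistasis_or),
    class = "causal_effect"
  )
}

#' Declare a strong-locus cluster
#'
#' A contiguous block of SNPs that all share one causal latent variable, so
#' the block behaves like a major-histocompatibility-style region: a
#' multi-SNP, high-LD cluster carrying a large marginal effect. The first
#' SNP of the cluster carries the additive disease effect.
#'
#' @param block_index Which LD block the cluster occupies (1-based).
#' @param n_snps Number of SNPs in the cluster.
#' @param or_per_allele Per-allele odds ratio of the cluster's causal SNP.
#' @param maf Target minor allele frequency of the cluster (member
#'   thresholds are jittered a few percent so members tag, rather than
#'   duplicate, one another).
#' @param chromosome_label Chromosome label given to cluster SNPs (default
#'   `"6"`), so masking experiments can remove it by chromosome.
#' @return A `strong_locus_spec` object.
#' @export
strong_locus_spec <- function(block_index = 1, n_snps = 10,
                              or_per_allele = 3, maf = 0.17,
                              chromosome_label = "6") {
  if (n_snps < 1) stop("`n_snps` must be >= 1", call. = FALSE)
  if (!is.finite(or_per_allele) || or_per_allele <= 0) {
    stop("`or_per_allele` must be finite and positive", call. = FALSE)
  }
  structure(
    list(block_index = as.integer(block_index), n_snps = as.integer(n_snps),
         or_per_allele = or_per_allele, maf = maf,
         chromosome_label = as.character(chromosome_label)),
    class = "strong_locus_spec"
  )
}

# internal: 1-based column indices of the strong-locus SNPs
strong_locus_idx <- function(config) {
  sl <- config$strong_locus
  if (is.null(sl)) return(integer(0))
  start <- (sl$block_index - 1L) * config$ld_block_size + 1L
  seq.int(start, start + sl$n_snps - 1L)
}

# internal: seed folded into the 32-bit range set.seed accepts
fold_seed <- function(seed) as.integer(abs(seed) %% 2147483647L)

#' Simulate genotype dosages
#'
#' Draws an `n` by `p` matrix of 0/1/2 minor-allele dosages. Within each
#' block of `ld_block_size` adjacent SNPs a latent standard-normal AR(1)
#' process with coefficient `ld_rho` is thresholded at the Hardy-Weinberg
#' quantiles of each SNP's target MAF, giving tunable adjacent-SNP r2
#' without phased haplotypes. Blocks are assigned to chromosomes 1-22 in
#' round-robin order; strong-locus SNPs share a single latent variable and
#' carry the configured chromosome label.
#'
#' @param config A [sim_config()].
#' @param n Number of samples to draw (defaults to
#'   `n_cases + n_controls`); larger pools are drawn when rejection
#'   sampling of phenotypes needs them.
#' @param stream Integer sub-stream index; different streams give
#'   independent latent draws under the same per-SNP target MAFs.
#' @return A `geno_data` with genotypes only (phenotype unset).
#' @export
simulate_genotypes <- function(config, n = NULL, stream = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n)) n <- config$n_cases + config$n_controls
  p <- config$p
  b <- config$ld_block_size
  n_blocks <- ceiling(p / b)
  sl_idx <- strong_locus_idx(config)

  # target MAFs: fixed by the master seed, independent of n and stream
  set.seed(fold_seed(config$seed + 1L))
  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  if (length(sl_idx) > 0) {
    sl <- config$strong_locus
    maf[sl_idx] <- sl$maf * stats::runif(length(sl_idx), 0.92, 1.08)
    maf[sl_idx] <- pmin(pmax(maf[sl_idx], 0.01), 0.5)
  }

  set.seed(fold_seed(config$seed + 2L + 1000L * stream))
  geno <- matrix(0L, n, p)
  for (blk in seq_len(n_blocks)) {
    cols <- seq.int((blk - 1L) * b + 1L, min(blk * b, p))
    z <- matrix(0, n, length(cols))
    if (length(sl_idx) > 0 && cols[1] == sl_idx[1]) {
      # strong locus: members share the block's causal latent variable
      shared <- stats::rnorm(n)
      n_sl <- length(sl_idx)
      for (j in seq_along(cols)) {
        if (j <= n_sl) {
          z[, j] <- shared
        } else {
          prev <- z[, j - 1]
          z[, j] <- config$ld_rho * prev +
            sqrt(1 - config$ld_rho^2) * stats::rnorm(n)
        }
      }
    } else {
      z[, 1] <- stats::rnorm(n)
      if (length(cols) > 1) {
        for (j in 2:length(cols)) {
          z[, j] <- config$ld_rho * z[, j - 1] +
            sqrt(1 - config$ld_rho^2) * stats::rnorm(n)
        }
      }
    }
    for (j in seq_along(cols)) {
      q <- maf[cols[j]]
      t0 <- stats::qnorm((1 - q)^2)         # below: 0 copies
      t1 <- stats::qnorm((1 - q)^2 + 2 * q * (1 - q))
      geno[, cols[j]] <- (z[, j] > t0) + (z[, j] > t1)
    }
  }

  chrom <- as.character(rep(((seq_len(n_blocks) - 1L) %% 22L) + 1L,
                            each = b)[seq_len(p)])
  if (length(sl_idx) > 0) {
    chrom[sl_idx] <- config$strong_locus$chromosome_label
  }
  pos <- integer(p)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- seq_len(sum(sel)) * 1000L
  }
  info <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(p)),
    chrom = chrom, pos = pos, target_maf = maf
  )
  out <- genotype_dataset(geno, snp_info = info)
  attr(out, "sim_config") <- config
  out
}

# internal: encode a genotype column under a penetrance model
encode_genotype <- function(g, model) {
  switch(model,
    additive = as.numeric(g),
    dominant = as.numeric(g >= 1L),
    recessive = as.numeric(g == 2L)
  )
}

# internal: logistic linear predictor over all causal terms (no intercept)
linear_predictor <- function(geno, effects) {
  eta <- numeric(nrow(geno))
  for (eff in effects) {
    enc <- encode_genotype(geno[, eff$snp_index], eff$model)
    eta <- eta + log(eff$or_per_allele) * enc
    if (!is.null(eff$epistasis_partner)) {
      enc2 <- encode_genotype(geno[, eff$epistasis_partner], eff$model)
      eta <- eta + log(eff$epistasis_or) * enc * enc2
    }
  }
  eta
}

#' Assign case-control phenotypes under a logistic disease model
#'
#' Disease status is drawn per sample from a logistic model whose linear
#' predictor sums encoded causal-SNP terms (additive: dosage; dominant:
#' dosage >= 1; recessive: dosage == 2) times their log odds ratios, plus
#' optional pairwise product interaction terms. The first `n_cases` cases
#' and `n_controls` controls encountered in row order are retained, so the
#' supplied dataset acts as the sampling pool.
#'
#' @param x A `geno_data` (genotypes only; acts as the population pool).
#' @param effects List of [causal_effect()] objects.
#' @param strong_locus Optional [strong_locus_spec()]; its additive effect
#'   is attached to the first SNP of the cluster (requires `x` to have been
#'   generated by [simulate_genotypes()] with the same configuration).
#' @param n_cases,n_controls Target class sizes.
#' @param seed Integer seed for the status draws.
#' @param intercept Optional logistic intercept; by default it is centred
#'   so the population prevalence approximates the target case fraction and
#'   rejection sampling terminates quickly.
#' @return A `geno_data` of `n_cases + n_controls` samples with phenotype
#'   set (cases = 1, controls = 0), in encounter order.
#' @export
assign_phenotypes <- function(x, effects = list(), strong_locus = NULL,
                              n_cases, n_controls, seed = 1,
                              intercept = NULL) {
  stopifnot(inherits(x, "geno_data"))
  effects <- c(effects, strong_locus_as_effects(x, strong_locus))
  if (n_cases + n_controls > n_samples(x)) {
    stop("target counts exceed the available genotype pool", call. = FALSE)
  }
  eta <- linear_predictor(x$genotypes, effects)
  if (is.null(intercept)) {
    target_frac <- n_cases / (n_cases + n_controls)
    intercept <- stats::qlogis(target_frac) - mean(eta)
  }
  set.seed(fold_seed(seed))
  status <- stats::rbinom(n_samples(x), 1L, stats::plogis(intercept + eta))

  keep <- integer(0)
  got_case <- 0L
  got_ctrl <- 0L
  for (i in seq_along(status)) {
    if (status[i] == 1L && got_case < n_cases) {
      keep <- c(keep, i); got_case <- got_case + 1L
    } else if (status[i] == 0L && got_ctrl < n_controls) {
      keep <- c(keep, i); got_ctrl <- got_ctrl + 1L
    }
    if (got_case == n_cases && got_ctrl == n_controls) break
  }
  if (got_case < n_cases || got_ctrl < n_controls) {
    stop(structure(class = c("snpforest_generation_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "pool exhausted: %d/%d cases, %d/%d controls drawn",
                     got_case, n_cases, got_ctrl, n_controls),
                     call = NULL)))
  }
  out <- subset_samples(x, keep)
  out$phenotype <- as.integer(status[keep])
  attr(out, "sim_config") <- attr(x, "sim_config")
  out
}

# internal: translate a strong locus into its causal effect on the dataset
strong_locus_as_effects <- function(x, strong_locus) {
  if (is.null(strong_locus)) return(list())
  config <- attr(x, "sim_config")
  if (is.null(config)) {
    stop("strong_locus requires a dataset from simulate_genotypes()",
         call. = FALSE)
  }
  idx <- (strong_locus$block_index - 1L) * config$ld_block_size + 1L
  list(causal_effect(idx, "additive", strong_locus$or_per_allele))
}

#' Inject missing genotypes
#'
#' Each entry is independently set missing with probability `rate`
#' (at most 5%, mirroring a post-QC panel with sub-percent missingness).
#'
#' @param x A `geno_data`.
#' @param rate Missingness probability in \[0, 0.05\].
#' @param seed Integer seed.
#' @return The dataset with `NA` sentinels inserted.
#' @export
add_missingness <- function(x, rate, seed = 1) {
  stopifnot(inherits(x, "geno_data"))
  if (rate < 0 || rate > 0.05) {
    stop("`rate` must be in [0, 0.05]", call. = FALSE)
  }
  if (rate == 0) return(x)
  set.seed(fold_seed(seed))
  g <- x$genotypes
  miss <- stats::runif(length(g)) < rate
  g[miss] <- NA_integer_
  out <- x
  out$genotypes <- g
  out
}

#' Simulate a complete case-control GWAS dataset
#'
#' End-to-end generator: draws a genotype pool, assigns phenotypes by
#' rejection sampling from the logistic disease model (growing the pool up
#' to 50x the quota if needed), injects missingness, and attaches a truth
#' table of causal SNPs for parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @return A `geno_data` with phenotypes; the truth table is available via
#'   [sim_truth()].
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  quota <- config$n_cases + config$n_controls
  out <- NULL
  for (mult in c(2L, 5L, 15L, 50L)) {
    pool <- simulate_genotypes(config, n = mult * quota, stream = mult)
    out <- tryCatch(
      assign_phenotypes(pool, effects = config$causal_effects,
                        strong_locus = config$strong_locus,
                        n_cases = config$n_cases,
                        n_controls = config$n_controls,
                        seed = config$seed + 3L),
      snpforest_generation_error = function(e) NULL
    )
    if (!is.null(out)) break
  }
  if (is.null(out)) {
    stop("could not fill case/control quotas within 50x the target size; ",
         "check the effect sizes and intercept", call. = FALSE)
  }
  out <- add_missingness(out, config$missing_rate, seed = config$seed + 9L)

  causal_idx <- vapply(config$causal_effects, `[[`, integer(1), "snp_index")
  sl_idx <- strong_locus_idx(config)
  ids <- snp_ids(out)
  truth <- tibble::tibble(
    snp_id = ids,
    causal = seq_along(ids) %in% c(causal_idx, sl_idx),
    model = NA_character_,
    or = NA_real_
  )
  for (eff in config$causal_effects) {
    truth$model[eff$snp_index] <- eff$model
    truth$or[eff$snp_index] <- eff$or_per_allele
  }
  if (length(sl_idx) > 0) {
    truth$model[sl_idx] <- "strong_locus"
    truth$or[sl_idx[1]] <- config$strong_locus$or_per_allele
  }
  attr(out, "truth") <- truth
  out
}

#' Truth table of a simulated dataset
#'
#' @param x A `geno_data` produced by [simulate_gwas()].
#' @return Tibble with columns `snp_id`, `causal`, `model`, `or`.
#' @export
sim_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("no truth table attached", call. = FALSE)
  truth
}

#' Write a truth table to a tab-separated file
#'
#' @param x A `geno_data` from [simulate_gwas()] (or its truth tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  truth <- if (inherits(x, "geno_data")) sim_truth(x) else x
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expected case minor-allele frequency under a per-allele odds ratio
#'
#' Closed form for the allelic model: with control minor-allele frequency
#' `maf` and per-allele odds ratio `or`, the case frequency is
#' `or * maf / (1 + maf * (or - 1))`.
#'
#' @param maf Control minor allele frequency in (0, 1).
#' @param or Per-allele odds ratio (> 0).
#' @return Expected case minor allele frequency.
#' @export
expected_case_maf <- function(maf, or) {
  or * maf / (1 + maf * (or - 1))
}

#' Configuration for a strong-signal benchmark panel
#'
#' Builds a [sim_config()] whose causal effects are planted on common
#' variants: candidate positions are the first SNP of each LD block, kept
#' when their target MAF is at least `min_causal_maf` (an odds ratio of
#' 1.5-2 on a rare variant is not a strong signal at desk-scale sample
#' sizes), and `n_causal` of them are chosen evenly across the genome.
#' Per-allele odds ratios are spaced over `or_range`. Used by the
#' reliability benchmarks.
#'
#' @param n_cases,n_controls,p,seed,ld_block_size,ld_rho,maf_range As in
#'   [sim_config()].
#' @param n_causal Number of causal SNPs.
#' @param or_range Range of per-allele odds ratios, assigned in
#'   increasing order across the causal SNPs.
#' @param min_causal_maf Smallest target MAF a causal SNP may have.
#' @return A `sim_config` with the causal effects filled in.
#' @export
strong_signal_config <- function(n_cases = 500, n_controls = 500, p = 2000,
                                 n_causal = 10, or_range = c(1.5, 2.0),
                                 min_causal_maf = 0.25, seed = 1,
                                 ld_block_size = 10, ld_rho = 0.8,
                                 maf_range = c(0.05, 0.5)) {
  base <- sim_config(n_cases = n_cases, n_controls = n_controls, p = p,
                     maf_range = maf_range, ld_block_size = ld_block_size,
                     ld_rho = ld_rho, missing_rate = 0, seed = seed)
  # expose the seed-determined target MAFs without simulating a full pool
  probe <- simulate_genotypes(base, n = 2)
  maf <- probe$snp_info$target_maf
  cand <- seq(1L, p, by = ld_block_size)          # block-leading SNPs
  cand <- cand[maf[cand] >= min_causal_maf]
  if (length(cand) < n_causal) {
    stop("not enough common block-leading SNPs for the causal set",
         call. = FALSE)
  }
  causal <- cand[round(seq(1, length(cand), length.out = n_causal))]
  ors <- seq(or_range[1], or_range[2], length.out = n_causal)
  effects <- lapply(seq_len(n_causal), function(i) {
    causal_effect(causal[i], "additive", ors[i])
  })
  sim_config(n_cases = n_cases, n_controls = n_controls, p = p,
             maf_range = maf_range, ld_block_size = ld_block_size,
             ld_rho = ld_rho, missing_rate = 0, causal_effects = effects,
             seed = seed)
}
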