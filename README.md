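# snpforest

Random-Forests screening of case-control genome-wide SNP panels.

Marginal association tests screen one SNP at a time, assume an additive
model, and are easily dominated by a single strong locus. `snpforest`
implements the complementary machine-learning protocol for case-control
GWA data: a genotype-specialized Random Forest — bagged, unpruned
classification trees over 0/1/2 minor-allele dosages whose per-node
binary split over the genotype categories is agnostic to additive,
dominant or recessive effects — together with the surrounding workflow
needed to use it at genome scale:

* **forest engine** (compiled core): bootstrap bagging, fresh random
  `mtry`-subsets per node, class-weighted Gini splits over the three
  binary partitions of {0,1,2}, out-of-bag (OOB) error trajectories,
  and unscaled permutation variable importance (VI),
  `VI_j = mean over trees of [OOB accuracy − OOB accuracy with SNP j
  permuted]`;
* **tuning**: the `{1, √p, 0.1p, 0.5p, p}` mtry grid with OOB-error
  minimization and ntree convergence detection;
* **refinement**: iterative sparsity pruning (drop VI ≤ 0, refit until
  the error stabilizes or increases), strong-locus masking by
  chromosome/interval, seed-change reliability (top-k overlap), and a
  formalized scree-plot elbow cutoff (default top 25);
* **LD tools**: pairwise r² and sliding-window multiple-correlation R²
  pruning, tag-SNP identification (r² ≥ 0.5), prune.in/prune.out lists;
* **association**: allelic χ² (df = 1), genomic inflation λ, analytic
  power of the allelic test, duplication reports against a reference
  hit list, and ranked `Chr / SNP / Gene / MAF / RF rank / χ² / p`
  tables;
* **synthetic data**: a generator with blockwise LD (thresholded latent
  AR(1)), additive/dominant/recessive/epistatic penetrance, an
  MHC-style strong-locus cluster, class imbalance and missingness, plus
  truth files for recovery tests;
* **I/O + CLI**: text PLINK `.ped/.map` and `.raw` dialects,
  missingness filtering, mode imputation, YAML-configured subcommands
  (`inst/cli/snpforest`).

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` scree/trajectory/trace plots, so the pipeline composes
with the usual tidyverse verbs.

## Worked example

```r
library(snpforest)

cfg <- sim_config(
  n_cases = 200, n_controls = 200, p = 300, ld_rho = 0.8,
  missing_rate = 0,
  causal_effects = list(causal_effect(5,   "additive", 2.5),
                        causal_effect(105, "additive", 2.5)),
  seed = 42)
x <- simulate_gwas(cfg)
#> <geno_data> 400 samples x 300 SNPs
#>   phenotype: 200 cases / 200 controls

fit <- grow_forest(x, mtry = 30, ntree = 300, seed = 7, importance = TRUE)
#> <snp_forest> 300 trees, mtry = 30, 400 samples x 300 SNPs
#>   OOB error: 0.4075 (balanced), 0.4075 (raw)

head(dplyr::arrange(tidy(fit), rank), 4)
#>   snp_id      score  rank
#> 1 snp00105 0.00769      1
#> 2 snp00005 0.00402      2
#> 3 snp00104 0.00224      3
#> 4 snp00126 0.00155      4
```

Both planted causal SNPs rank at the top, and `snp00104` — an LD-block
neighbour of `snp00105` — rides along, exactly the tag-SNP behaviour the
VI measure is known for. The marginal view agrees:

```r
head(dplyr::arrange(allelic_chisq(x), -chisq), 2)[, c("snp_id", "chisq", "p")]
#>   snp_id   chisq        p
#> 1 snp00105  25.1  5.35e-7
#> 2 snp00005  16.8  4.24e-5

allelic_power(931, 2431, maf = 0.5, or_per_allele = 1.2)  # study scale
#> 0.0274
allelic_power(931, 2431, maf = 0.5, or_per_allele = 1.3)
#> 0.321
```

The screening pipeline (forest + sparsity pruning + ranking) is one
call, and its seed-change stability one more:

```r
run <- rf_screen(x, mtry = 30, ntree = 300, seed = 1)
tidy(run$trace)                      # per-iteration OOB error, stop reason
reliability_check(x, seeds = c(1, 2), k = 25, mtry = 30, ntree = 300)
```

## Notes

* VI output is a rank ordering of candidates for follow-up, not a
  hypothesis test; no multiple-testing correction is applied.
* The OOB error after sparsity pruning is optimistically biased and is
  used only to compare configurations.
* See `vignettes/snpforest-methods.Rmd` for the model, tuning
  defaults, numerical choices, and known limitations.
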