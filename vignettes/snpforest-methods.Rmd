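---
title: "Random-Forests screening of case-control SNP panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-Forests screening of case-control SNP panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genome-wide association (GWA) screens test hundreds of thousands of SNPs
one at a time with a marginal allelic test. A marginal test is blind to
the genetic model (additive, dominant, recessive) and to interactions
between loci, and a handful of very strong loci — in autoimmune disease,
typically the MHC region on chromosome 6p — can dominate any joint
analysis. Random Forests offer a complementary screen: bagged, unpruned
classification trees whose per-node *binary* split over the three dosage
categories {0, 1, 2} is agnostic to the genetic model, whose out-of-bag
(OOB) error gives an internal estimate of classification quality, and
whose permutation variable importance (VI) ranks SNPs by how much they
contribute to case-control discrimination — jointly, not marginally.

`snpforest` implements that screening protocol end to end: the
genotype-specialized forest engine, the mtry/ntree tuning search, the
iterative sparsity-pruning loop, strong-locus masking,
linkage-disequilibrium (LD) pruning, seed-change reliability checks,
marginal allelic statistics for comparison, and a synthetic case-control
generator so every stage is testable without access to restricted
genotype data.

VI output should be read as a *rank ordering of candidates worth
follow-up*, not as a hypothesis test with a known type-I error rate; no
multiple-testing correction is applied anywhere.

## The forest engine

Each of `ntree` trees is grown on a with-replacement bootstrap of size
$n$; on average $(1-1/n)^n \approx e^{-1} \approx 37\%$ of samples are
left out of each tree's bag and form its OOB set. At every node a fresh
uniform random subset of `mtry` SNPs is drawn, and the split search
enumerates, for each candidate, the three binary partitions of the
dosage categories — $\{0\}|\{1,2\}$, $\{0,1\}|\{2\}$, $\{0,2\}|\{1\}$ —
maximizing the decrease in class-weighted Gini impurity
$1 - \sum_c \pi_c^2$. Growth continues until nodes are pure or no
candidate varies; trees are never pruned. Ties in the split search are
broken lexicographically (lower SNP index, then the partition order
above) so a run is bit-reproducible given its seed.

Class weights default to balanced (inverse class frequency, normalized
to mean 1) — the convention for unbalanced case-control panels, fixed
rather than tuned — and enter in three places: the Gini criterion,
terminal votes, and OOB error aggregation. The reported OOB error is
therefore *balanced* (the class-weight average of the per-class error
rates); the raw misclassification fraction is stored alongside, since
conventions differ between implementations.

Permutation VI: for each tree and each SNP appearing in it, the SNP's
values are permuted among that tree's OOB samples and the tree's
(class-weighted) OOB accuracy is recomputed; a SNP's score is the mean
accuracy drop over **all** trees, with trees not containing the SNP
contributing zero. Averaging over all trees (the original bagging
convention) deliberately reproduces the LD-dilution effect: two SNPs in
perfect LD each appear in about half the trees either would appear in
alone, halving each one's VI. One nuance follows from the deterministic
tie rule: markers in *near*-perfect LD split the importance roughly in
half (bootstrap noise decides which one wins each node), whereas
bit-identical columns tie exactly at every node, so the lexicographic
rule routes all of the shared importance to the lower-indexed copy; and
the halving is sharpest when a single binary split absorbs the signal
(dominant/recessive-shaped effects), since an additive effect leaves
residual signal in the `{1,2}` branch that the other copy can pick up
deeper in the tree. Scores are unscaled — the protocol ranks
raw importances, so dividing by a standard error would only reshuffle
near-zero noise. A SNP never selected into any tree scores exactly 0,
which is what makes "VI $\le$ 0" a usable sparsity signal.

### Random streams

The engine uses its own splitmix64-based generator. Per-tree streams
are derived from the master seed by tree index, so forests are
invariant to evaluation order, identical across platforms, and any
single tree can be regrown in isolation. The VI pass derives its
permutation streams the same way from its own seed, and the test suite
replays them to verify the accuracy bookkeeping by hand.

## Tuning

The mtry search grid is $\{1, \lfloor\sqrt p\rfloor, \lfloor 0.1
p\rfloor, \lfloor 0.5 p\rfloor, p\}$ (clamped to $\ge 1$,
deduplicated). On large sparse panels the conventional $\sqrt p$
default — roughly 550 SNPs per node at 300K markers — searches far too
few variables per node to find the weak signals, and the OOB error is
typically minimized near $0.1p$; the grid brackets that value. The
candidate with the lowest final OOB error wins, ties going to the
smaller (cheaper, lower-variance) value.

Convergence of the OOB trajectory is declared at the first tree index
where the range of the trailing `window` values is at most `tol`.
Defaults `window = 100`, `tol = 0.005` (absolute error-rate units)
reproduce the qualitative 200–400-tree plateau seen on strong-signal
panels; no published numeric rule exists, so the defaults are the
package's own calibration. Stronger predictors converge earlier;
weak-signal configurations (e.g. after masking a major locus) need
several thousand trees, which is why the `ntree` presets scale from
1,000 (strong signal retained) to 5,000/10,000 for masked or heavily
pruned configurations.

## Sparsity pruning, masking, reliability, the elbow

**Sparsity pruning.** Most SNPs are noise; a forest says so by giving
them VI $\le 0$. The loop fits, drops all non-positive-VI SNPs, refits,
and stops when the OOB error increases, changes by at most `stop_tol`
(default 0.005, matching the convergence tolerance), or `max_iter` is
reached; the iteration with the lowest OOB error is flagged final. Note
the final error estimate is optimistically biased (the retained set was
chosen using the same data) — it is used to compare configurations, not
as an honest prediction error. An alternative bottom-quantile drop rule
(20% by default) is available but not the default. When an explicit
`mtry` is supplied it is capped at the shrinking panel size on refits;
with the default (`mtry = NULL`) each refit uses $0.1p$ of its current
panel, which is the protocol's own reading of "mtry = 0.1p" for
sub-sampled configurations.

**Masking.** A dominant locus (the MHC in multiple sclerosis) can mask
weaker effects, because trees that can split on it rarely need anything
else. `mask_region()` removes a chromosome (or a position interval —
needed for an arm such as "6p", since .map files carry no arm labels)
so the remaining signal can surface. The corresponding test checks the
behavioral claim: weak causal SNPs improve in mean VI rank once the
planted strong locus is removed.

**Reliability.** The forest is a Monte-Carlo procedure, so the protocol
re-runs the full pipeline with a different seed and counts the overlap
of the top-k (default 25) VI lists. On a strong-signal panel overlap
close to k indicates the ranking is driven by signal, not by forest
noise.

**Elbow cutoff.** How many top SNPs to report was a visual decision in
the original protocol (a scree plot with an elbow around 25).
`elbow_cutoff()` formalizes it: over the top-100 scores, pick the index
maximizing the forward second difference $s_k - 2s_{k+1} + s_{k+2}$,
provided that maximum exceeds twice the median absolute second
difference (a "clear" elbow); otherwise fall back to the published
default of 25. The rule is scale-invariant.

## LD tools

Pairwise LD is the squared Pearson correlation of dosage vectors
(composite LD — deliberately not haplotype-based). Window pruning
slides a 50-SNP window advancing by 5 (the canonical defaults of the
tool the protocol used; the original study names no values) along each
chromosome: under the multiple-correlation method the SNP with the
highest $R^2$ against the other retained window SNPs is removed
(ties to the higher index) until none exceeds the threshold; under the
pairwise method the later SNP of any offending pair is removed
greedily. Rank-deficient regressions are handled by a pseudoinverse
least-squares solve, so exact duplicates are resolved deterministically.
Tag SNPs are identified at pairwise $r^2 \ge 0.5$ on the same
chromosome within 250 kb (configurable), and the duplication report
classifies each reference SNP as directly recovered, recovered through
a tag, or absent.

## Marginal statistics

The allelic test counts two alleles per sample and applies the Pearson
$\chi^2$ (df = 1, no continuity correction) to the 2×2 allele-by-class
table; the 2n allele counts are treated as independent (the standard
allelic convention). Genomic inflation is the median observed $\chi^2$
over 0.4549 (the $\chi^2_1$ median), reported to two decimals. Analytic
power uses the two-proportion normal approximation with the pooled-null
standard error for the rejection threshold and the alternative standard
error for the power integral; the case allele frequency under a
per-allele odds ratio is $p_1 = \mathrm{OR}\,p_0/(1 + p_0(\mathrm{OR}
- 1))$. Whether the original study's power figures used this allelic
convention or a genotypic trend test is not stated; the allelic
convention is implemented, and at the study's scale (931/2,431, $\alpha
= 1.5\times 10^{-7}$) it reproduces the quoted ~3% (OR 1.2) and ~30%
(OR 1.3) upper ends to within a few percentage points.

## The synthetic generator

`simulate_gwas()` emulates the statistical structure the analysis
assumes, not any particular cohort:

* **Genotypes.** Per-SNP target MAFs are uniform on `maf_range`
  (default 0.05–0.50, the post-QC spectrum of a 500K array). Within
  blocks of `ld_block_size` SNPs (default 10) a latent standard-normal
  AR(1) with coefficient `ld_rho` (default 0.8) is thresholded at the
  Hardy–Weinberg genotype quantiles of each SNP's MAF. This gives a
  tunable, oracle-checkable adjacent-r² profile without phased
  haplotype machinery; the thresholded-latent construction is checked
  in the tests against a direct Monte-Carlo oracle of the same
  bivariate-normal definition. Block size and `ld_rho` are fixture
  choices, not estimates of any real panel's LD decay.
* **Phenotypes.** Disease status follows a logistic model whose linear
  predictor sums encoded causal terms (additive: dosage; dominant:
  dosage ≥ 1; recessive: dosage = 2) times log odds ratios, plus
  optional pairwise product interactions. Sampling is by rejection
  from a genotype pool grown up to 50× the quota; the intercept is
  centred so the population prevalence approximates the target case
  fraction and sampling terminates quickly. The closed form
  $p_1 = \mathrm{OR}\,p_0/(1+p_0(\mathrm{OR}-1))$ for the case allele
  frequency holds exactly only in the rare-disease limit, so the
  calibration test runs at a low-prevalence intercept.
* **Strong locus.** One block whose members all share a single causal
  latent variable (thresholds jittered a few percent so members tag
  rather than duplicate each other), labelled chromosome "6" by
  default, with a large per-allele OR (default 3 at MAF 0.17). At the
  study's sample sizes this reproduces allelic $\chi^2$ on the order
  of $10^2$ — the magnitude of a major MHC signal — and gives the
  masking experiment a realistic multi-SNP cluster to remove.
* **Defaults.** 931 cases / 2,431 controls (the ~1:2.6 imbalance of
  the motivating study), 5,000 SNPs (a desk-scale panel; the full
  325,807 is reachable by setting `p`), 0.5% missingness (sub-1%, as
  in a post-QC panel).

What the generator does **not** emulate: population structure and
admixture, coalescent or haplotype-reference realism, X-chromosome
dosage, genotyping batch effects, and LD decay calibrated to any real
map. Tests passing on this generator therefore demonstrate the
*algorithmic* properties of the pipeline (recovery, stability,
calibration of the null), not performance on any particular cohort.

* **Seeds.** One master seed; every sub-stream (target MAFs, latent
  draws, phenotype draws, missingness) is derived from it by fixed
  offsets, so identical configurations give bit-identical datasets and
  any stage can be regenerated in isolation.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to make the statistical
assertions sharp rather than to mimic the original computation:
oracle-equivalence fixtures at $n \le 12$, $p \le 4$ (exhaustive CART
is exponential); null-calibration panels of 3,000–5,000 SNPs at a few
hundred samples; parameter recovery with 5 common causal SNPs
(OR 2.0, MAF 0.2–0.4, the band where an OR-2 effect is clearly
detectable at $n = 1{,}000$) among ~1,000 SNPs over 20 seeds; and the
seed-change reliability experiment on a 2,000-SNP panel with 10 common
causal SNPs (OR 1.5–2.0) at 500 cases / 500 controls, 500 trees,
mtry = 0.1p, with sparsity pruning. For the reliability fixture the
causal effects are planted on common variants (target MAF ≥ 0.25,
spread across the genome): a "strong-signal" panel is the stated
condition, and an OR of 1.5–2.0 on a rare variant is not a strong
signal at this sample size. At this scale roughly half of the top 25
slots are occupied by causal blocks; the remainder sit in the
near-zero VI tail, which churns between seeds and bounds the
attainable seed-change overlap below the value reported for studies
whose top 25 are all strongly associated markers.

## Numerical choices and degenerate inputs

* Split ties: strict improvement comparisons keep the first (lowest
  SNP index, earliest partition) candidate; identical columns produce
  bit-identical statistics, so duplicates resolve to the lower index.
* Forest votes: per-sample aggregation is `argmax` of class-weighted
  tree-vote counts; exact ties go to the control class.
* Monomorphic SNPs: allelic $\chi^2$ is 0 with p = 1 and a flag;
  pairwise r² against a constant vector is a flagged `NA`.
* Samples never OOB (tiny `ntree`): excluded from the OOB error with a
  warning.
* Pruning that would empty the panel stops with the last non-empty set
  and a warning rather than erroring mid-pipeline.
* Mode imputation ties go to the lower dosage; fully missing SNPs are
  an error (they should have been filtered at the 10% missingness
  threshold first).
* Multiple-$R^2$ regressions use an SVD pseudoinverse, so collinear
  windows (exact duplicates, planted linear dependencies) are handled
  without error and deterministically.

## Known limitations

* The final OOB error after sparsity pruning is optimistically biased;
  it ranks configurations but does not estimate generalization error.
* Permutation VI inherits LD dilution by design; conditional or
  per-appearance VI variants are out of scope.
* The allelic test and power calculation ignore dosage-variance
  corrections and covariates; there is no logistic-regression
  association module.
* Text PLINK dialects only (.ped/.map, .raw); binary .bed and VCF are
  out of scope, as are haplotype phasing and imputation beyond the
  per-SNP mode rule.
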