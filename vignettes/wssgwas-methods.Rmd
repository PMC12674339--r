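---
title: "Weighted single-step GWAS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

In most livestock populations phenotypes and pedigrees are recorded for
thousands of animals, while genotypes exist for only a small subset. The
single-step approach uses all of this at once: breeding values `u` are
modelled for *every* pedigree animal,

```
y = X b + Z u + e,   u ~ N(0, H sigma2_u),   e ~ N(0, I sigma2_e),
```

with a relationship matrix **H** that merges pedigree relationships (**A**)
and genomic relationships (**G**). Its inverse is sparse and direct:

```
H^-1 = A^-1 + [ 0   0                  ]
              [ 0   (G*)^-1 - A22^-1   ]
```

on the genotyped block, where `A22` is the pedigree relationship matrix of
the genotyped animals and `G* = alpha G + (1 - alpha) A22` is the blended
genomic matrix (`g_matrix()`, `blend_g()`, `h_inverse()`).

`G = Z D Z' / (2 sum p q)` is the weighted VanRaden matrix built from
allele-frequency-centered dosages `Z` and SNP weights `D` (initially the
identity). Marker effects are never fitted directly; they are *back-solved*
from the genotyped animals' breeding values:

```
u_hat = lambda D Z' (G*)^-1 a_hat,   lambda = 1 / (2 sum p q),
```

then turned into new weights `d_j = u_hat_j^2 * 2 p_j q_j` (normalised to
sum to the SNP count), and the whole evaluation is repeated — twice by
default — so that large-effect regions gain weight. Association is reported
per non-overlapping window of 30 adjacent SNPs as the percentage of the
additive genetic variance explained by the window's local genetic value
`a_w = Z[, w] u_hat[w]` across genotyped animals:
`pct_w = 100 var(a_w) / sigma2_u`. Windows strictly above 0.5% are the
candidate regions.

## Variance components

`reml_aireml()` maximises the restricted likelihood by average-information
(AI) updates. The model is rotated once into the eigenbasis of
`Z_s H Z_s'` (the relationship matrix of the recorded animals), after which
every likelihood, gradient and AI evaluation is linear in the record count;
the rotation costs one dense inversion of `H^-1` and one symmetric
eigendecomposition. Whenever an AI step would leave the parameter space or
reduce the likelihood, a multiplicative fixed-point step
(`theta <- theta * yPKPy / tr(PK)`, always positive and stationary exactly
at the REML equations) is taken instead; `sigma2_u` is clamped at
`1e-8 var(y)` so near-zero-heritability traits stay estimable. Standard
errors come from the inverse AI matrix; the standard error of `h2` by the
delta method.

One statistical caveat surfaced while testing the null: with a *single*
record per animal and `H = I`, `sigma2_u` and `sigma2_e` are not separately
identifiable (the likelihood is flat along their sum). Null-trait behaviour
is therefore validated on related pedigrees, where the covariance between
relatives identifies the split.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.05 | SNPs with minor allele frequency below this are removed |
| `call_rate_min` | 0.90 | minimum fraction of non-missing calls per SNP |
| `hwe_alpha` | 1e-6 | 1-df chi-square Hardy-Weinberg p-value cutoff |
| `mendel_conflict_max` | 0.01 | opposing-homozygote fraction above which an animal is dropped |
| `ld_r2_max` | 1.0 | LD pruning threshold (1.0 = only perfect duplicates) |
| `alpha_blend` | 0.95 | weight of G in G*; < 1 guarantees invertibility |
| `window_size` | 30 | SNPs per non-overlapping window |
| `region_threshold_pct` | 0.5 | percent of additive variance a candidate window must exceed |
| `n_weight_iterations` | 2 | re-weighting rounds (round 1 = unweighted ssGWAS) |
| `outlier_sd` | 3.0 | phenotype outlier window in SD units |

QC order is fixed: call rate, Mendelian conflicts (animal removal), MAF,
HWE, LD pruning, then imputation — animal removal precedes the
frequency-based filters so that conflicted animals cannot contaminate the
frequencies. Missing genotypes are imputed by the SNP mean dosage `2p`
rounded to 0/1/2; this is a deliberately simple, deterministic stand-in for
haplotype-based imputation and a documented fidelity gap: it removes
missingness but adds no linkage information.

The blended `G*` is used both in `H^-1` and in the back-solve. With allele
frequencies estimated from the genotyped sample the centered `Z` has
column sums of zero, so `G` is always singular along the all-ones vector
and blending (`alpha < 1`) is not a numerical nicety but a requirement; the
exact back-solving identity `Z u_hat = a_hat` holds only when frequencies
come from elsewhere (e.g. a base population) and `G` has full rank.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the world the analysis assumes: a closed
herd of discrete generations (default 8 x 190 animals) bred from a few
active sires per generation; a biallelic SNP panel (default 10 chromosomes
x 300 SNPs at 0.1 cM spacing) gene-dropped through the pedigree with
Haldane recombination; a trait controlled by a handful of large QTL plus a
polygenic tail over all remaining SNPs, scaled so the realized genetic
variance and the QTL's share hit their targets exactly; fixed period
(9 levels, by birth generation) and season (4 levels) effects plus a
continuous covariate; and heritabilities in the 0.04-0.31 range typical of
growth, production and reproduction traits.

Two generator choices deserve justification:

* **Ancestral linkage disequilibrium.** Founders drawn in linkage
  equilibrium produce essentially zero population LD, and we measured the
  consequence: a QTL carrying 20% of the genetic variance back-solves to a
  window share of about 0.6% even when the breeding values are known
  without error — a 30-fold dilution, because with ~150 genotyped animals
  and 3000 SNPs the minimum-norm back-solve spreads signal over every
  spuriously correlated column. Real dense panels do not behave like this:
  closed herds carry strong drift LD. The simulator therefore precedes the
  recorded pedigree with a random-mating ancestral population
  (`ne_ancestral = 40` diploids, `n_burnin_generations = 60`), which yields
  adjacent-SNP r^2 around 0.4-0.5 at the default spacing, in the range
  reported for dense livestock panels. Setting `n_burnin_generations = 0`
  recovers exact equilibrium founders.
* **QTL placement.** QTL are drawn among SNPs with minor allele frequency
  of at least 0.1 in the recent (genotyping-eligible) generations: a "QTL
  explaining 20% of the variance" is only a coherent statement for a locus
  still segregating in the study animals.

What the simulator does *not* emulate: sequence-level error, ascertainment
bias of real reduced-representation panels, selection (matings are random
within the sire/dam structure), repeated records, and maternal or dominance
effects. A green detection test therefore establishes that the estimator
concentrates variance on a segregating large-effect region under drift LD
and random mating — not that it would do so under strong selection or with
imputation artefacts.

Detection itself has an intrinsic ceiling worth stating plainly: with 150
genotyped animals the back-solved SNP effects inherit the error of the
GEBVs (accuracy ~0.7 here), and that error is redistributed over ~100
windows. In repeated simulations the planted QTL's window exceeds the 0.5%
threshold in the large majority of replicates and re-weighting almost
always sharpens it, but it lands in the top 3 windows only in roughly half
— the honest behaviour of the method at this genotyping depth, consistent
with its use as a region-screening rather than fine-mapping tool.

## Numerical choices

* Pedigree algebra uses the exact tabular relationship matrix as the
  reference; the Meuwissen-Luo algorithm is provided as an equivalent fast
  path and tested for exact agreement. `A^-1` is assembled sparsely by
  Henderson's rules with inbreeding (`d_i = 0.5 - 0.25 (F_s + F_d)`).
* `A22` is obtained by restricting the tabular A (fine at a few thousand
  animals); no indirect method is used.
* Matrix inverses of `G*` and `A22` go through Cholesky factorisation with
  an explicit reciprocal-condition guard; a singular `G*` raises an error
  that points at `alpha_blend`.
* REML convergence is declared at a relative parameter change below 1e-8;
  starting values split `var(y)` equally.
* Variance components are frozen during the weighting iterations; only SNP
  effects and breeding values are re-estimated, and the window denominator
  is always the REML additive variance from the unweighted model.
* Window variances use the n-1 sample variance over genotyped animals;
  trailing windows shorter than 30 SNPs are retained and flagged via
  `n_snps`.
* The weight update returns the previous weights unchanged if every
  back-solved effect is zero, and floors weights at a tiny positive value
  so `D` stays invertible.
* Ties/threshold: a window at exactly the region threshold is *excluded*
  (strict inequality), matching the "more than 0.5%" rule.

## Known limitations

* Single-trait models only; no permanent-environment, maternal or dominance
  effects; no unknown-parent groups or metafounders.
* Mean-dosage imputation degrades (rather than exploits) linkage
  information at badly missing SNPs.
* The LD-pruning defaults (window 50, step 5, r2 threshold off) are
  conventional, not tuned; the analysis is usually run with pruning off.
* At ~150 genotyped animals the method screens regions; it does not
  fine-map (see the detection ceiling above).
* One re-weighting round inflates the largest *null* window by a factor of
  3-6 as a matter of mechanism (weights are squared effects), which is why
  the iteration count is kept at two and thresholded selection is applied
  to the final round only.
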