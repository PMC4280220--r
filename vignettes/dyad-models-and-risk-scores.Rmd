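---
title: "Genotype QC, penalized selection, risk scores and mother-child duo models"
author: "dyadGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype QC, penalized selection, risk scores and mother-child duo models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadGWAS)
```

## Scope and data model

dyadGWAS implements a complete case-control genetic analysis for pregnancy
outcomes where both the maternal genome and the fetal (placental) genome are
informative: genotype quality control, per-SNP logistic association with
principal-component adjustment and FDR control, penalized multi-SNP
selection, repeated cross-validated weighted genetic risk scores, and a
multinomial likelihood for mother-child genotype duos with maternal, fetal,
interaction and parent-of-origin (imprinting) effects.

Two containers carry the data. `GenotypeDataset` extends
`SummarizedExperiment`: one `dosage` assay of minor-allele counts (variants
x samples), variant metadata in `rowData`, phenotype and covariates in
`colData`. `DyadDataset` stores, per variant, integer counts of
mother-child dosage pairs over the seven Mendelian-compatible cells
(0,0), (0,1), (1,0), (1,1), (1,2), (2,1), (2,2) — a mother homozygous for
one allele cannot have a child homozygous for the other, so (0,2) and (2,0)
are structurally impossible and are excluded (with a per-variant tally)
when duos are extracted from pedigree records.

## The duo multinomial model

For a biallelic variant with risk-allele frequency $q$ (and $p = 1 - q$),
Hardy-Weinberg equilibrium and random mating give the population duo
distribution over (mother dosage $m$, child dosage $c$), with the
heterozygous-child cells split by parental origin of the child's risk
allele:

| cell | probability | origin |
|------|-------------|--------|
| (0,0) | $p^3$ | — |
| (0,1) | $p^2 q$ | paternal |
| (1,0) | $p^2 q$ | — |
| (1,1) | $p^2 q + p q^2$ | maternal + paternal |
| (1,2) | $p q^2$ | — |
| (2,1) | $p q^2$ | maternal |
| (2,2) | $q^3$ | — |

Disease risk for a pregnancy is $\alpha \,\mu(m, c, \text{origin})$ with

$$\mu = S_m \, R_c \, \mathrm{Im}^{\,[c=1 \wedge \text{maternal}]}
  \, \gamma_{01}^{\,[m=0,c=1]} \, \gamma_{21}^{\,[m=2,c=1]},
  \qquad S_0 = R_0 = 1.$$

$R_1, R_2$ are fetal-genotype relative risks, $S_1, S_2$ maternal ones,
$\mathrm{Im}$ multiplies risk when a heterozygous child's risk allele was
maternally transmitted, and $\gamma_{01}, \gamma_{21}$ capture
maternal-fetal genotype incompatibility (child heterozygous while the
mother carries zero or two copies). Under the rare-disease approximation,
case duos follow the population origin-resolved configurations re-weighted
by $\mu$ and renormalized; control duos follow the population law itself.
`dyadCellProbabilities()` returns both 7-vectors, and the test suite checks
them against an exhaustive enumeration over (mother genotype, maternal
transmitted allele, paternal allele).

Model labels fix the free multipliers: Null (none), F ($R_1,R_2$), M
($S_1,S_2$), M+F (both), I (M+F plus $\gamma_{01},\gamma_{21}$), and
M+F+Im (M+F plus $\mathrm{Im}$) as the nested extension used by the
imprinting likelihood-ratio test. The imprinting multiplier applies only to
heterozygous children with a maternally derived allele: for homozygous
children the parental origin is either forced or the risk is already fully
parametrized by $R_2$, so this is the parametrization in which the
parent-of-origin effect is identifiable from duo data alone.

### Estimation, BIC and the LRT

`fitDyadModel()` maximizes the multinomial likelihood on unconstrained
transforms (logit $q$, log multipliers) with BFGS, a Nelder-Mead polish
when BFGS does not report convergence, and perturbed multi-starts (default
5; scans that chain fits seed each extension at the nested solution and use
2). The free-parameter count is $k = 1 + \#\{\text{free multipliers}\}$ and
$\mathrm{BIC} = -2\ell + k \log n$ with $n$ the total dyads.
`selectBestModel()` fits Null, F, M, M+F and I, lays out the standard
seven-row comparison table and selects the BIC minimizer;
`imprintingScan()` reports the 1-df LRT of M+F+Im against M+F per variant.
The allele frequency is estimated jointly from case and control duos:
under the rare-disease model controls dominate this estimate, and the
mothers' dosage margin provides a moment-style starting value.

## Quality control

`applyQC()` applies the filters in narrative order: samples missing more
than 10% of SNPs; then SNPs missing in more than 10% of samples or with
MAF below 1% (a single combined tally); then SNPs failing the
Hardy-Weinberg exact test among controls. The exact test enumerates all
heterozygote counts compatible with the observed allele counts and sums
the probabilities of configurations no more probable than the observed one;
it is preferred to the chi-square approximation because candidate SNPs sit
near the 1% MAF boundary, where the chi-square is unreliable. The HWE
threshold defaults to `1e-4`, the common genome-wide choice, and is
configurable; MAF is computed on all retained samples for filtering while
outputs report control-sample MAF. A `QCReport` carries the additive
accounting (input, per-step removals, retained).

## Association scan

Each SNP is tested by logistic regression of case status on additive
minor-allele dosage plus intercept, covariates (infant sex) and the top
four principal components of the standardized dosage matrix
(mean-imputed, centered at $2\hat p$, scaled by $\sqrt{2\hat p(1-\hat p)}$).
Samples missing a SNP's genotype are dropped pairwise for that SNP —
standard GWAS practice; genome-wide imputation is out of scope and
penalized fits instead use per-SNP mode imputation, documented as a
deliberate simplification. Wald p-values are treated as the reported
empirical p-values; the Benjamini-Hochberg step-up gives q-values, and the
genomic inflation factor is the median association chi-square over
0.454936. Group comparisons of baseline characteristics use the Welch
(unequal-variance) t-test from summary statistics and the Pearson
chi-square without continuity correction.

## Penalized selection

Genome-wide selection uses the lasso (glmnet) with the penalty chosen by
20-fold cross-validated binomial deviance; the intercept, covariates and
PCs are never penalized. Because the lasso keeps one SNP per correlated
cluster, `ldExpand()` reports every same-chromosome SNP within 500 kb at
$r^2 \ge 0.8$ (squared Pearson correlation of dosages over
pairwise-complete samples) as a proxy of a selected SNP without adding it
to the model.

Candidate-gene selection uses a composite minimax concave penalty: with
$\mathrm{MCP}(t; \lambda, \gamma) = \lambda t - t^2/(2\gamma)$ for
$t \le \gamma\lambda$ (else $\gamma\lambda^2/2$), the penalty is an outer
MCP applied to the sum of inner-MCP-penalized absolute coefficients within
each gene, giving selection at the gene level and at the SNP level inside
selected genes. The outer MCP is scaled to unit slope at zero with
saturation point $\gamma_{\text{out}} = K_g \gamma \lambda^2 / 2$ ($K_g$ =
group size), so the group penalty flattens exactly when every member's
inner penalty has saturated and the null-model entry threshold equals the
plain MCP's $\lambda$ — with singleton groups the selected set coincides
with plain MCP selection. Optimization is by local-linear-approximation
reweighting around the current coefficients with accelerated
proximal-gradient steps (closed-form weighted soft-threshold), declared
converged at a maximum coefficient change below $10^{-6}$; a group-lasso
variant (group soft-thresholding) is available through the same engine.
The penalty grid is 100 log-spaced values from the path maximum down to 1%
of it, and the same cross-validation rule chooses the penalty.

## Weighted genetic risk scores

`crossvalWGRS()` repeats, for a fixed SNP set: a stratified random
partition into 10 folds; per fold, a multivariable logistic fit on the
nine training folds; per SNP, orientation so the training weight
(absolute log-OR) is positive — "number of risk alleles times effect size"
is then well-defined, and differs from signed-weight scoring only by an
additive constant; scoring of the held-out fold. Quartile cut-points come
from the pooled control scores of the replicate (each control used exactly
once per replicate, keeping groups full at this sample size), and a
logistic fit of status on quartile indicators plus sex and PCs yields
quartile odds ratios against the lowest quartile, a 3-df
likelihood-ratio global chi-square, and the AUC (Mann-Whitney, ties one
half). Summaries are the mean replicate log-OR (exponentiated) and mean
AUC with 2.5-97.5 percentile intervals across replicates. The percentile
interval measures partition variability only, so the summary also carries
an inferential quartile-OR interval combining the across-replicate
variance with the mean within-replicate Wald variance; on null data it is
the one expected to cover 1. The study-scale default is 1000 replicates;
desk-scale configurations in the pipeline default to 50.

## The synthetic-data generator

The generator provides the statistical structure the analyses assume, not
a population-genetic simulation. Case-control genotypes: haplotypes from a
stationary first-order Markov chain with per-SNP MAF uniform on a
configured range and adjacent-allele correlation `ldRho` (genotype = sum
of two haplotypes, hence HWE by construction); disease by
$\mathrm{logit}\,P = \mathrm{logit}(\alpha) + \sum_j \log(\mathrm{OR}_j)\,
g_j$; case and control quotas filled by rejection sampling, which yields
exact conditional distributions at the cost of draws; optional
two-subpopulation mixture with symmetric per-SNP allele-frequency
divergence (enough to make PC adjustment testable) and optional
excess-homozygosity at one SNP (inbreeding-style coefficient) to exercise
the HWE filter. Duos: mother under HWE at $q$, transmitted allele uniform
over her two, paternal allele Bernoulli($q$), affected with probability
$\alpha\,\mu$; each variant is generated as an independent duo set.
Default sample sizes mirror the motivating study (280/244 genomes,
222/198 duos); the default baseline risk is 1%, the approximate population
frequency of the outcome. A single seed drives every sub-stream, so equal
configs give bit-identical outputs.

What the generator does not emulate — realistic recombination maps and LD
blocks, imputation error, genotyping batch effects, X-linked inheritance,
shared sampling of many variants on one duo cohort — bounds what passing
tests show: they validate the estimators and selection procedures under
the model's own assumptions, not robustness to violations of them.

Two quirks of the binary-haplotype chain are worth knowing. The attainable
correlation between adjacent SNPs with different allele frequencies is
capped by the binary margins, so high-LD scenarios should use a narrow MAF
range. And because the stored minor allele is fixed while samples are
random, a variant's realized control MAF can drift above 0.5; the PED
reader re-orients to the less-frequent-in-controls allele (ties broken by
overall frequency, then lexicographically), so write-then-read is the
identity exactly on convention-compliant datasets.

## Numerical choices and degenerate inputs

Logistic fits use IRLS (`glm.fit`) with deviance tolerance $10^{-8}$ and
50 iterations; Wald standard errors come from the observed information.
Perfect separation is flagged (infinite-OR sentinel), monomorphic-after-
missing SNPs are flagged rather than fitted, and a rank-deficient joint
refit falls back to a small ridge jitter with a collinearity flag. The duo
likelihood treats zero-probability cells with zero counts as contributing
nothing and returns $-\infty$ for a positive count on a zero-probability
cell. LRT statistics are clipped at zero; a full model fitting worse than
its reduction by more than $10^{-6}$ raises an optimization-failure error,
which the scan surfaces as a flagged row. Quartile assignment ranks
controls into four near-equal groups and classifies cases by midpoint
breaks, so control quartile sizes differ by at most one and assignments
are invariant under strictly increasing transforms of the score.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at sizes chosen to give
stable statistical behaviour on a single core: association nulls at
300/300 samples and 1000-2000 SNPs; lasso power at 500/500 with 5 causal
among 205 SNPs; duo parameter recovery at 5000+5000 dyads; imprinting
type-I calibration over several hundred to a thousand 500-dyad
replicates; BIC selection accuracy over dozens of replicates at 5000+5000
(interaction truth) and at the study's 222+198 (null truth); WGRS at
10 folds with 25-50 replicates. The study-scale settings (1000 WGRS
replicates, genome-wide SNP counts) are configuration values, not code
paths, so scaling up is a config change.

## Known limitations

The duo models assume HWE, random mating and a rare disease; control duos
use unconditioned population probabilities, so common outcomes would need
the exact conditioning. Fathers are not modeled (no trio support), the X
chromosome is excluded, and haplotype-level (diplotype) interaction
analysis is out of scope. The published BIC values for the worked example
are not reconstructible from the printed log-likelihoods under
$-2\ell + k\log(420)$ for any integer $k$, so BIC conventions differ
across implementations; this package's convention (k counts q plus free
multipliers, n = total dyads) is documented and self-consistent, and
likelihood-ratio statistics — which are convention-free — are the quantities
checked against the published table.
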