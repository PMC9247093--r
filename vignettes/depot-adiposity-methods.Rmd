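---
title: "Methods: dissecting the genetics of MRI-derived fat depots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting the genetics of MRI-derived fat depots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotgene)
```

## The problem

Body MRI yields volumes of three fat depots — visceral (VAT), abdominal
subcutaneous (ASAT) and gluteofemoral (GFAT) adipose tissue, all in litres.
Raw depot volumes are dominated by overall adiposity: their Pearson
correlation with BMI in an imaged biobank cohort sits around 0.77–0.88, so a
genome scan of a raw volume largely rediscovers the genetics of BMI. The
quantities of biological interest are *local adiposity* traits: each depot
residualized on age, age², BMI and height within sex (the "adj" traits), and
the three pairwise depot ratios taken on raw volumes. `depotgene` implements
the full downstream machinery for these traits — derivation, common-variant
scanning and clumping, sex-dimorphism testing, multi-trait clustering of
loci, rare-variant burden testing and polygenic-score evaluation — together
with seeded generators that emulate the statistical structure of such a
cohort, so the entire pipeline is exercised end to end without any
access-restricted data.

## Trait derivation

`derive_local_adiposity()` fits, separately within each sex, an ordinary
least-squares regression of each depot volume on `{1, age, age², BMI,
height}` and stores the residual as the adj trait; within-sex residual means
are zero by construction and residuals are orthogonal to every design
column. Rows missing a covariate are dropped from that fit rather than
imputed. Ratios are raw quotients with no residualization. All nine traits
are also returned after rank-based inverse normal transformation (INT),

$$\tilde x_i = \Phi^{-1}\!\left(\frac{r_i - c}{n - 2c + 1}\right), \qquad c = 0.5,$$

with average ranks for ties — the transform biobank GWAS pipelines
conventionally apply before association testing. The offset $c$ is
configurable; 0.5 is the default because it makes the transformed values
symmetric quantiles of the uniform ranks.

Adjusting for heritable covariates (BMI, height) risks collider bias.
`collider_concordance()` implements the standard diagnostic: a lead SNP of
an adj trait is *concordant* when its effect magnitude on the raw depot
volume strictly exceeds its magnitude on BMI. Ties are classified
discordant — "stronger" is read as a strict inequality.

## Common-variant scanning

`variant_qc_common()` applies the two published filter sets: array variants
require MAF ≥ 1%, Hardy–Weinberg exact p > 1e-15 and call rate ≥ 99%;
imputed variants are dropped when MAF < 0.005 or INFO < 0.3. The HWE test is
the Levene–Haldane exact test on hard-called genotypes, implemented by
summed enumeration of heterozygote counts; the exact tail matters because a
chi-square approximation is meaningless at a 1e-15 threshold.

`association_scan()` is covariate-adjusted least squares: trait and dosages
are residualized on the covariates (QR decomposition, intercept always
included) and the per-variant coefficient, standard error and two-sided t
p-value follow from the residual-on-residual regression — numerically
identical to the full multiple regression by the Frisch–Waugh–Lovell
theorem. The published analyses used a linear mixed model to absorb
relatedness and population structure; with unrelated synthetic individuals
the two estimators coincide, so plain least squares is the deliberate engine
here and mixed-model internals are out of scope. Missing dosages are
mean-imputed per variant; zero-variance dosages are skipped with a log
message; an $R^2$ of essentially 1 flags the fit `degenerate` rather than
reporting a spuriously tiny p-value.

`ld_clump()` reproduces the greedy PLINK rule (p1 = 5e-8, p2 = 5e-6,
r² = 0.1, window 1000 kb): repeatedly take the lowest-p unassigned variant
below p1 as a lead and assign to it every unassigned variant below p2 within
the window and in LD above r². Ties in p are broken by (CHR, BP) so output
is deterministic. Pairs absent from the LD table are treated as r² = 0 with
a warning — the empirical reference panel behind a published LD table cannot
be shipped, so absence is interpreted as independence. Novelty
(`flag_novel_loci()`) is maximum catalog r² strictly below 0.1; a value of
exactly 0.1 is "known", and a lead missing from the LD lookup is
`indeterminate`, never novel. `genomic_inflation()` is the median
association chi-square over 0.4549 (the null median), and
`bonferroni_threshold()` performs the sequential-division arithmetic with a
two-significant-figure display form. `replication_concordance()` compares
effect signs against an external study with the exact two-sided binomial
test $p = \min(1,\, 2P(X \ge \max(k, n-k)))$.

## Sex heterogeneity

For each locus the sex-dimorphism statistic is

$$t = \frac{\beta_m - \beta_f}
       {\sqrt{se_m^2 + se_f^2 - 2\,r\,se_m\,se_f}},$$

where $r$ is the genome-wide Spearman correlation between male and female
effect estimates (`effect_rank_correlation()`), computed once per trait over
all shared SNPs — not per locus and not on an LD-pruned subset, matching the
"genome-wide" reading. The subtraction of $2r\,se_m se_f$ accounts for the
positive correlation that shared architecture and overlapping samples induce
between the stratified estimates; ignoring it would make the test
conservative. $t$ is referred to the standard normal (the convention of the
EasyStrata-style implementations; at biobank sample sizes the distinction
from any plausible t reference is negligible), and the dimorphism threshold
is 0.05 divided by the number of tested locus-trait pairs.
`classify_sex_specific_loci()` labels a locus `combined` when genome-wide
significant in the sex-combined scan, `male_only`/`female_only` when
significant in exactly that stratum and in neither the other stratum nor the
combined scan.

## Clustering loci by multi-trait profiles

`build_signed_z_matrix()` prepares the clustering input from lead SNPs and a
panel of per-trait summary statistics: keep leads nominally associated
(p < 0.05) with the primary trait; LD-prune at r² = 0.1 keeping the lower
primary p; form z = β/se; scale each trait column by
$\sqrt{N_{med}/N_{trait}}$; flip each variant's row so its primary-trait z
is positive; drop traits with no |z| above the two-sided Bonferroni quantile
for 0.05/N variants; collapse trait pairs whose signed z columns correlate
above 0.85 in absolute value (Pearson, pre-split), keeping the trait with
the lower minimum p; and split every signed column into non-negative
`_pos`/`_neg` halves. Missing variant-trait entries are an error — the
panel must be complete, because silent zero-filling would masquerade as
evidence of no association. The correlation-collapse step is skipped below
three variants, where a correlation estimate is vacuous.

`fit_bnmf_ard()` factorizes the transposed split matrix $X^T \approx WH$
($W$: 2M split traits × K, $H$: K × variants) by minimizing

$$\tfrac12\lVert X^T - WH\rVert_F^2
  + \sum_k \frac{\tfrac12\lVert W_{\cdot k}\rVert^2
                 + \tfrac12\lVert H_{k\cdot}\rVert^2 + b_0}{\lambda_k}
  + C\sum_k \log \lambda_k,$$

the negative log-posterior under half-normal priors with per-component
relevance weights $\lambda_k$ (automatic relevance determination).
Multiplicative updates alternate with the closed-form
$\lambda_k = (\tfrac12\lVert W_{\cdot k}\rVert^2 +
\tfrac12\lVert H_{k\cdot}\rVert^2 + b_0)/C$, $C = (F+N)/2 + a_0 + 1$;
irrelevant components collapse toward the prior floor $b_0/C$ and their
columns shrink to zero, so the retained count K is inferred. Hyperparameters
follow standard ARD-NMF practice: $a_0 = 10$,
$b_0 = \sqrt{(a_0-1)(a_0-2)\,\overline{X}/K_0}$, maximum rank $K_0 = 20$,
convergence at relative objective change below 1e-7 with a 10,000-iteration
cap. Two numerical details matter:

* after the objective converges, a fixed 200-iteration decay phase lets
  pruned components' residual weight (which decays geometrically but lags
  the objective) reach numerical zero before K is counted at a 1e-8
  relative component-weight tolerance;
* the reported $W, H$ are then *polished* at the selected K by unpenalized
  multiplicative updates. ARD's prior leaves a small (order 1–2%) shrinkage
  bias on retained components; polishing removes it, so a noiseless rank-1
  input is reconstructed to numerical accuracy. Rank selection is unaffected.

The fit runs `n_restarts` (default 100) times from seeded random starts; the
modal K across converged restarts and its frequency are reported, and the
lowest-objective restart among modal-K solutions is the representative
answer. The modal-K fraction is reported, not enforced — callers decide what
stability floor they require. `summarize_clusters()` ranks traits by weight
and variants by loading per cluster and hard-assigns each variant to its
maximum-loading cluster (ties to the lowest index, logged).

## Rare-variant burden testing

`genotype_call_filter()` applies the exome call-level rules (set missing
when DP ≤ 10 or ≥ 200; hom-ref with GQ ≤ 20 or alt ratio > 0.1; het with
alt ratio < 0.2 or PL(ref) < 20; hom-alt with alt ratio < 0.9 or
PL(ref) < 20); it is total and idempotent, and missing quality fields set
the call missing rather than erroring. `rare_variant_qc()` then drops sites
in exclusion regions (BED intervals via GenomicRanges), with exact HWE
p < 1e-15, call rate < 90%, or monomorphic after call filtering.

Gene masks are `pLoF` (high-confidence predicted loss-of-function, weight 1)
and `pLoF + missense` (adding 5/5-damaging missense variants at the
gene-specific weight)

$$w = \min\!\left(1,\ \sqrt{\frac{f_L(1-f_L)}{f_M(1-f_M)}}\right),$$

with $f_L, f_M$ the cumulative allele frequencies of the gene's qualifying
rare (cohort MAF < 0.1%) pLoF and missense variants; a gene with no
high-confidence pLoF variant uses weight 1. The per-sample gene score is the
dosage-weighted sum of qualifying alleles capped at 1 — dosage (het = 1,
hom = 2) rather than a carrier indicator, since the weighted-sum wording
does not resolve the choice and dosage preserves information; a missing call
contributes 0 but the sample is retained, because excluding such samples
would bias carrier counts. Rarity is judged within the analysis cohort after
call-level QC. `burden_association()` regresses the INT phenotype on the
score plus covariates (sex added in combined runs), sex-combined and
stratified, excludes genes under 10 carriers *per stratum* before any
multiplicity accounting, and emits exome-wide (0.05/genes) and study-wide
(further divided by the number of analyses) thresholds. Sample-level QC
(relatedness, sex concordance, heterozygosity outliers) is consumed as an
inclusion list upstream, not recomputed.

## Polygenic-score evaluation

`apply_score()` forms the allele-aligned weighted dosage sum (swapped
effect/other alleles flip the dosage to $2-d$; unresolvable pairs are
skipped and counted; missing dosages take the variant mean).
`score_table()` residualizes against genetic PCs — the residual is exactly
orthogonal to each PC — and percentile-ranks with ties broken by a seeded
shuffle, making ranks uniform, reproducible, and invariant to affine
transforms of the raw score. `tail_enrichment()` cross-tabulates strict
membership beyond empirical (type-7) quantile tails and reports the odds
ratio with a Woolf log-normal 95% CI, applying the Haldane 0.5 correction to
zero cells; the published ORs name no interval method, so the standard
closed form was chosen. Whether the published tail ORs were
covariate-adjusted is not stated; the raw 2×2 is implemented, and
covariate-adjusted tail-indicator regressions (linear for biomarkers,
logistic for diseases) are available separately via
`extreme_score_outcome_association()`.

## What the generators emulate — and what they do not

`simulate_cohort()` draws sex (51% female), age (truncated normal, mean
64.5), sex-specific height, and a latent shared-adiposity factor $A \sim
N(0,1)$ that generates BMI ($27.4 + 4A$) and feeds each depot:

$$\text{depot} = \mu_{sex} + \sigma_{sex}\left(\lambda A +
  \sqrt{1-\lambda^2}\,\varepsilon + g\right),$$

with planted standardized genetic effects $g$ and independent noise
$\varepsilon$. Defaults are the study's sex-specific means (VAT 5.0/2.6,
ASAT 5.9/7.9, GFAT 9.3/11.3 litres for males/females); within-sex SDs
(VAT 2.5/1.4, ASAT 2.2/2.8, GFAT 2.2/2.6 litres) and loadings (0.97, 0.90,
0.90) are tuning constants fixed once so the *sex-combined* depot–BMI
Pearson correlation lands inside the reported 0.77–0.88 band — the
between-sex mean differences attenuate the combined correlation below the
within-sex loading, which the chosen SDs compensate. Volumes are floored at
0.05 L for positivity, with the generating mean analytically shifted
(solving $E[\max(N(\mu^*,s), c)] = \mu$) so cell means still equal the
specification in expectation. Genotypes are independent Binomial(2, MAF)
draws.

The other generators: `simulate_summary_stats()` inverts the z-score
construction ($z = A_{true}B_{true} + \varepsilon$, emitted as β/se with
$se = 1/\sqrt{N}$; every cluster loads on the primary trait so a
primary-selected panel retains all variants);
`simulate_sex_stratified_stats()` draws paired estimates with
bivariate-normal noise at a chosen correlation;
`simulate_clump_panel()` builds block LD (exchangeable r² within block, zero
across — the published empirical panel cannot be shipped);
`simulate_gene_burden_data()` places rare alleles on random chromosomes at
target cumulative frequencies, with bounded redraws guaranteeing ≥ 10
carriers for genes flagged testable. Every generator is driven by a single
recorded seed and regenerates byte-identically.

None of this emulates linkage disequilibrium between causal and tag
variants, population structure, relatedness, imputation error beyond an
INFO pass-through, genotype-phenotype confounding, or non-Gaussian
phenotype tails. Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated under its stated assumptions — not
that mixed-model corrections, LD-aware fine-mapping, or real-data QC
pathologies are handled.

## Problem sizes and calibration checks

The test-suite and acceptance-script sizes were chosen so each check is
statistically decisive at desk scale:

* null genomic inflation uses 80,000 SNPs × 400 individuals — the sampling
  SD of $\lambda_{GC}$ is $\approx 2.33/\sqrt{m}$, so 80k SNPs gives
  SD ≈ 0.008 against a ±0.02 acceptance band;
* the sex-heterogeneity null uses 20,000 SNPs at estimate correlation 0.3;
* bNMF recovery plants K = 3 in 100 variants × 20 traits at noise SD 1 with
  100 restarts;
* burden calibration uses 500 null genes at n = 10,000 with one planted
  gene (effect 0.98, ~24 expected carriers) matching the scale of a strong
  published rare-variant fat-distribution signal;
* the polygenic-score check builds a score explaining 7% of trait variance
  at n = 8,000 and reports the *median* top-5%/top-5% tail OR over five
  replicates: a single replicate's log-OR has SD ≈ 0.15 (the concordant
  tail holds only ~60 people), so the median tests the same regime while
  suppressing Monte-Carlo noise. The population OR in this regime is ≈ 3.7,
  bracketed by the published 3.81.

## Known limitations

* The LD-clumping and novelty logic treat unrecorded LD pairs as
  independent; with a sparse user-supplied LD table this can over-split
  loci and over-call novelty (absence from the table entirely yields
  `indeterminate`, but a present-yet-incomplete table does not warn per
  pair).
* Strand-ambiguous allele resolution is deliberately not attempted;
  mismatches error out rather than guess.
* The bNMF posterior's prior-strength constant is exposed as a hyperparameter
  (`a0`) because the published procedure does not pin it down; cluster
  *membership* is robust across a0 in simulations, but borderline component
  retention near the pruning threshold need not be.
* The burden engine assumes an additive dosage score; recessive or
  compound-heterozygote models are out of scope.
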