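---
title: "Methods: rare-variant gene-set burden analysis with endoburden"
author: "endoburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant gene-set burden analysis with endoburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoburden)
```

## The problem

Common-variant studies explain only part of the genetic architecture of
late-onset Alzheimer's disease. Rare coding variants carry large per-allele
effects but are individually untestable, so the standard remedy is to
aggregate them: over a biologically defined gene set (here, the endocytic
system — endosome, lysosome and trans-Golgi network compartments) for a
single per-individual *burden* test, and per gene through variance-component
kernel tests. `endoburden` implements that entire workflow — QC, rare-variant
selection, burden and kernel association models for binary, ordinal and
time-to-event phenotypes, cross-cohort meta-analysis, and downstream
expression analyses — together with a synthetic-cohort generator so that
every stage is testable against known ground truth without access-controlled
genotype data.

## Quality control

The canonical filter chain, applied by `run_qc()` in this order:

1. **Site filter**: only `FILTER == PASS`, biallelic SNVs. Split
   multi-allelic records are rejected, not silently kept.
2. **Genotype-quality mask**: entries with GQ < 21 are set missing. GQ = 21
   is kept (the rule is "below 21").
3. **Sample missingness**: samples with > 5% missing genotypes are removed;
   exactly 5% is retained.
4. **Variant missingness**: variants with > 2% missing are removed; exactly
   2% is retained. Because the GQ mask precedes this step, masked entries
   count as missing here — the chain order is recorded in the QC report, and
   re-running the chain on retained data is a no-op.
5. **Hardy–Weinberg**: the exact two-sided test (`hwe_exact_test()`,
   conditional on allele counts, summing outcomes no more probable than the
   observed heterozygote count) is computed on **control samples only**, and
   rare variants with p < 0.001 are removed. The boundary p = 0.001 is
   retained (strict inequality; the inclusive side was left open in the
   design we follow, and we chose the permissive reading once). Non-rare
   variants are never touched by this filter.

Relatedness is estimated by method-of-moments IBD from identity-by-state
counts on common variants (MAF ≥ 5%), with finite-sample-corrected
expectations (falling factorials of observed allele counts — without this
correction π̂ of unrelated pairs is biased upward by several percent at
realistic panel sizes). Pairs with π̂ above 0.185 (second degree) form a
graph; `prune_related()` keeps one sample per connected component — lowest
missing rate first, then sample-id order, so pruning is deterministic.
Principal components come from the singular value decomposition of the
centered, frequency-standardized common-genotype matrix with mean imputation
of missing entries; variants can be thinned to one per window, which stands
in for LD pruning because the synthetic data carry no linkage
disequilibrium. The X chromosome never enters any analysis.

## Rare deleterious variants

Rarity follows a dual-source rule at thresholds 0.1% and 1%: if a variant is
present in either external reference panel (1KG EUR, gnomAD NFE), it is rare
iff **every present** external frequency is strictly below the threshold;
only when absent from both does the internal (cohort) minor-allele frequency
decide. Three boundary conventions, each fixed once: frequencies exactly at
the threshold are *not* rare ("below"); when the two external sources
disagree across the threshold the variant is *not* rare (conservative
conjunction); an external frequency recorded as zero counts as *present*.
Deleterious means protein-truncating or splice-disrupting (stop-gain,
stop-loss, frameshift, splice-donor, splice-acceptor) or damaging missense;
an optional tightening additionally requires scaled CADD > 15. Indels are
excluded throughout. Gene sets are read from GMT, deduplicated per term, and
unioned with deduplication.

## Burden scores and association models

For individual $i$ over selected variants $j$ with dosages $d_{ij}$ and
weights $w_j$ (1, or the gene's pLI),

$$ \mathrm{raw}_i \;=\; \frac{\sum_{j \in O_i} w_j d_{ij}}
                             {2 \sum_{j \in O_i} w_j}, $$

where $O_i$ is the set of variants *observed* for $i$ — the denominator
shrinks with missingness so scores stay comparable across samples. The raw
score is residualized by OLS on the genome-wide rare-variant count and the
top ten PCs; residuals are exactly uncorrelated with each covariate. By
default the residual is scaled to unit variance: the raw fraction has a
spread of order $10^{-3}$, which both ill-conditions downstream ordinal fits
and makes "per unit" effects unreadable; on the unit scale every reported
odds or hazard ratio is per SD of residual burden. Zero mean and zero
covariate correlation are unaffected by the scaling.

Association uses three nested models — M0 (sequencing center + 10 PCs), M1
(+ age, sex), M2 (+ APOE ε2 and ε4 allele counts); the PCs appear both in
the residualization and in M0–M2, deliberately redundant but faithful to the
staged design. Binary status uses maximum-likelihood logistic regression
with Wald p (likelihood-ratio fallback, flagged, under separation); samples
labelled MCI are excluded. Braak stages 0–VI use the proportional-odds model
(`MASS::polr`), with the analytic K = 2 degeneration to plain logistic
handled explicitly. Age-at-onset/death uses Cox partial likelihood with
Efron tie handling; age is never a covariate there because it is the time
axis, and controls enter censored at their age at last observation. Family
cohorts use a logistic mixed model with random-effect covariance
$\tau \cdot 2K$ (kinship $K$), fitted by penalized quasi-likelihood with the
single variance component profiled by REML inside each IRLS step —
deterministic, fast at cohort scale, and exactly equal to `glm()` when the
kinship matrix is zero. Non-PSD kinship matrices are repaired by eigenvalue
clipping with a warning.

## Kernel tests

For a gene with weighted genotypes $\tilde G = G\,\mathrm{diag}(w)$ and null
residuals $r$, the statistic is the quadratic form
$Q_\rho = r'\tilde G R_\rho \tilde G' r$ with
$R_\rho = (1-\rho) I + \rho \mathbf{1}\mathbf{1}'$, so $\rho = 0$ is the
pure variance-component kernel and $\rho = 1$ the pure weighted burden test.
Weights default to the Beta(1, 25) density at the cohort minor-allele
frequency. The null distribution is the usual mixture of $\chi^2_1$ with the
eigenvalues of $R_\rho^{1/2}\,\tilde G' P_0 \tilde G\,R_\rho^{1/2}$;
p-values use four-moment (Liu-type) matching, with exact
characteristic-function inversion (Imhof) behind `exact = TRUE`. Both
reduce *exactly* to the single-variant and weighted-burden score tests in
the degenerate cases, which the tests verify against `glm`'s Rao statistic.
The "optimal" test minimizes p over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ and evaluates the
minimum-p statistic by one-dimensional integration over the shared burden
component ($\rho = 1$ is replaced by 0.999 inside the integration, where the
decomposition is singular); the result is additionally capped at the
Bonferroni bound (min p × grid size). Genes are only tested with at least
two carriers — below that the moment approximation is meaningless. The
multi-cohort version pools per-cohort score vectors and information matrices
on a shared variant frame (absent variants contribute zero) under a
homogeneous-effect assumption. Family data enter the kernel tests without
kinship adjustment, consistent with the burden analysis showing family
structure moves the estimate only marginally.

Known approximation behavior, bounded by a 100,000-permutation oracle in the
test suite: the Liu tail approximation is accurate where it matters (small
p) but can deviate by ~0.01 in the distribution center; and at n = 60 the
asymptotic null itself differs from the exchangeable permutation null by up
to ~0.5–2% absolute — the small-sample moment corrections that would remove
this are deliberately out of scope.

## Meta-analysis

Per gene set and phenotype, the best model (smallest p; ties toward the
more-adjusted model) from each cohort feeds two combiners.
Inverse-variance: $\hat\beta = \sum w_k \beta_k / \sum w_k$,
$w_k = SE_k^{-2}$, two-sided normal p. Direction-aware Fisher: each
two-sided p becomes one-sided in the consensus direction (that of the
discovery cohort) — $p/2$ if concordant, $1 - p/2$ if discordant — and
$-2\sum \ln p$ is referred to $\chi^2_{2k}$. The combined one-sided p is
reported as-is by default, matching the convention of the published
meta-analysis columns; a flag doubles it. Bonferroni uses the declared
family (four gene sets × two MAF thresholds = 8 tests, threshold 0.00625);
per-gene scans use alpha over the number of genes actually tested, and the
eGene scan uses Benjamini–Hochberg at FDR 0.05.

## Expression analyses

The cis window of a gene is the union of its body and TSS ± 20 kb, 1-based
closed with both endpoints included — a variant exactly at TSS + 20,000 is
in, at TSS + 20,001 out (unless in the body). We read the flank as
*additional to* the gene body; the alternative reading (flank only) is
narrower and was rejected once. eGene testing runs the continuous-trait
kernel test of expression on the aggregated rare variants in the window,
with age, sex, center, APOE counts and 10 PCs in the null model; its p is
location-scale invariant in the expression units. Case/control contrasts use
Welch's t-test (pooled variance behind a flag); severity uses the Pearson
correlation with Braak stage. Single-cell preprocessing keeps cells with
200–2,500 detected genes inclusive and mitochondrial fraction not *over* 5%,
then log-normalizes: $\ln(1 + 10^4\,c_{gj}/\sum_g c_{gj})$. Per-cell-type
differential expression applies the t-test per cell by default, which
mirrors the procedure this design follows but is anti-conservative under
within-donor correlation; per-sample pseudobulk aggregation is one flag away
and is the statistically safer choice.

## The synthetic cohort generator

`simulate_cohort()` draws, under one seed with bit-identical reruns:

* **Allele-frequency spectrum**: a 0.5 point mass at singleton-scale
  frequency $1/(2n)$ mixed with Beta(0.08, 5) truncated to (0, 0.5] — heavy
  tailed, so both the 0.1% and 1% thresholds bite; the closed-form CDF
  (`maf_spectrum_cdf()`) is what the tests check the realized spectrum
  against. Real singleton counts dominate rare deleterious sets, which this
  mixture emulates; the exact spectrum shape is otherwise unconstrained and
  these parameters were fixed once.
* **Genotypes**: binomial(2, AF) per sample — exact HWE, the assumption the
  QC filter tests; configurable missingness and sub-threshold GQ rates.
* **Phenotypes**: case status from a logistic model with log OR 1.25 per SD
  of true gene-set burden (the published effect scale) plus age, sex,
  center and APOE terms; Braak from a latent-logistic proportional-odds
  model with cutpoints skewed so stages V–VI hold the majority; event times
  exponential under proportional hazards with administrative censoring.
  Effects apply to the **z-scored** true burden — on the raw fraction scale
  "per unit" would be meaningless (see above).
* **Families**: two parents drawn from the AFs, children by Mendelian
  transmission; the block-diagonal kinship matrix carries the expectations
  0.5 (self), 0.25 (parent-offspring and full siblings), 0 (across
  families).
* **Expression**: bulk Gaussian with cis eGene effects proportional to the
  standardized carrier burden in the gene's window plus case shifts;
  single-cell negative-binomial counts with per-cell size factors, six cell
  types, per-type case shifts on marker genes, and Beta-distributed
  mitochondrial fractions spanning the 5% threshold.

Not emulated, hence not demonstrated by passing tests: linkage
disequilibrium (PCA "pruning" is plain thinning here), sequencing-error and
read-level artefacts, non-European allele-frequency structure, assortative
or multi-generation pedigrees, and expression batch effects. The truth
record is written alongside the cohort and is never read by any analysis
function.

## Numerical choices and problem sizes

Null-model GLMs use a tightened convergence epsilon ($10^{-12}$) so score
tests match closed forms to $10^{-6}$ and better. The PQL loop converges on
fixed effects to $10^{-7}$ with τ profiled on [$10^{-8}$, 5]. Imhof
integration uses adaptive quadrature to $10^{-7}$ relative tolerance with a
$10^{-14}$ floor on p. Eigenvalues below $10^{-10}$ of the largest are
treated as zero. The test and acceptance workloads use sizes chosen to make
each property measurable while keeping a full run in minutes on one core:
1,000 null replicates of n = 1,000 for type-I error, 100 replicates for
parameter recovery (n = 5,000 logistic, 800 ordinal, 500 Cox), 100,000
permutations at n = 60 for the kernel oracle, 10–20 replicates of a 40-gene
n = 500 cohort for eGene sensitivity, and a staged three-cohort study of
n = 1,000 per cohort end to end.

## Known limitations

No Firth correction (rare-variant logistic fits can be biased at extreme
imbalance; separation falls back to likelihood-ratio p instead);
homogeneous-effect meta pooling only; no heterogeneity statistics; PQL
variance components are biased downward for very small binary clusters; the
per-cell DE default inherits the anti-conservativeness discussed above; and
the kernel tests rely on asymptotic nulls without small-sample moment
corrections.
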