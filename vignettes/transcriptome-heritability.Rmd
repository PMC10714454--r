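---
title: "Quantitative genetics of blood gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of blood gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txherit)
```

## The problem

Breeding for disease resilience — the ability of an animal to maintain
performance under pathogen pressure — is hampered by the fact that
selection candidates live in high-health nucleus herds and cannot be
exposed to disease. Blood collected from young, visually healthy animals
is an attractive source of indicator traits: if the expression level of a
gene is heritable, and genetically correlated with later resilience, it
can be selected on directly. `txherit` implements the quantitative-genetic
machinery for this programme: per-gene heritability of expression under an
animal model, genetic correlations of expression with resilience
phenotypes from bivariate models, genomic-window summaries, and
enrichment analyses that aggregate weak per-gene signal into pathway-level
statements.

## The animal model for one gene

For gene $g$, the expression level $y$ (log2 scale, see below) of animal
$m$ in batch $i$, pen $k$, litter $l$ is modelled as

$$
y = \mathrm{Batch}_i + \mathrm{Enrich}_j + \beta_1\,\mathrm{Age} +
    \beta_2\,\mathrm{RIN} + (\textstyle\sum_{c=1}^{6}\gamma_c \log_2 w_c) +
    \mathrm{Pen}_k + \mathrm{Litter}_l + u + e,
$$

with $\mathrm{Pen}\sim N(0, I\sigma^2_P)$,
$\mathrm{Litter}\sim N(0, I\sigma^2_L)$, $u\sim N(0, G\sigma^2_A)$ and
$e\sim N(0, I\sigma^2_e)$. The six $w_c$ are the white-blood-cell (WBC)
proportions (lymphocytes, neutrophils, monocytes, basophils, eosinophils,
large unstained cells); the model *with* these covariates is called WI,
the model *without* them WO. Comparing the two separates expression
heritability that acts through cell composition from heritability of
per-cell expression.

Heritability and the litter-effect proportion are reported as

$$
h^2 = \frac{\sigma^2_A}{\sigma^2_A+\sigma^2_P+\sigma^2_L+\sigma^2_e},
\qquad
c^2 = \frac{\sigma^2_L}{\sigma^2_A+\sigma^2_P+\sigma^2_L+\sigma^2_e}.
$$

The denominator includes the pen variance. Definitions of "total
phenotypic variance" differ on whether a purely environmental housing
term belongs in it; we include it by default and expose
`include_pen_in_total = FALSE` in `reml_fit()` for the alternative.

### The genomic relationship matrix

$G$ is built per company with VanRaden's first method:
$Z Z^\top / (2\sum_j p_j(1-p_j))$, where $Z$ holds dosages centered by
twice the within-company allele frequency, and SNPs monomorphic within
the company are dropped from the scaling sum. Company blocks are then
assembled block-diagonally with *exact* zeros between companies. Zeroing
cross-company relationships makes the estimates pooled within-company
variance components — the relevant quantity for closed nucleus
populations, and robust to between-company allele-frequency divergence.
Allele frequencies are computed within company (consistent with the
pooled-within-company target; a global-frequency variant would mix
between-company structure into $Z$). Missing dosages are mean-imputed to
$2p$; quality control (`snp_qc()`) bounds missingness at 10% beforehand,
using strict thresholds (MAF > 0.05, SNP and individual call rate > 0.90)
applied in **every** QC group.

### REML

Variance components are estimated by average-information (AI) REML on the
dense covariance $V=\sigma^2_A G+\sigma^2_P Z_PZ_P^\top+\sigma^2_L
Z_LZ_L^\top+\sigma^2_e I$, maximizing
$-\tfrac12(\log|V|+\log|X^\top V^{-1}X|+y^\top P y)$. Implementation
choices that matter:

* **AI steps with step-halving** on the restricted likelihood, with an
  EM-type multiplicative fallback when no AI step improves. The AI matrix
  doubles as the asymptotic covariance of the estimates (standard errors
  of $h^2$, $c^2$ by the delta method).
* **Active-set boundary handling.** A nonnegative component whose
  estimate falls below $10^{-8}\,\mathrm{Var}(y)$ *and* whose score is
  negative is fixed at exactly zero; it re-enters the free set if its
  score later turns positive. Permanently zeroing components (an earlier
  design) can strand the optimizer below the null-model likelihood.
* **Convergence** when the relative likelihood change per iteration falls
  below $10^{-8}$, with a 200-iteration cap; non-convergence is flagged,
  never silently accepted.
* **Multi-start** (`restarts`): the restricted likelihood of weakly
  identified designs can be multimodal; optional deterministic restarts
  concentrate 80% of the variance in each component in turn and keep the
  best likelihood. Dense algebra (explicit $V$) is used throughout since
  cohorts at this scale are a few thousand animals at most.

Significance of $\sigma^2_A$ (and $\sigma^2_L$) uses the likelihood-ratio
test against the model without the term. Because the null value lies on
the boundary of the parameter space, the LRT null is the 50:50 mixture
$\tfrac12\chi^2_0+\tfrac12\chi^2_1$; `lrt_pvalue()` implements the
mixture, and a Wald z is reported alongside for comparison.

## Bivariate genetic correlations

For gene expression ($y_1$, observed on the transcriptomed subset) and a
phenotype ($y_2$, observed on the full genotyped cohort), the bivariate
model places the genetic covariance structure
$\left[\begin{smallmatrix}\sigma_{A11}&\sigma_{A12}\\ \sigma_{A12}&\sigma_{A22}\end{smallmatrix}\right]\otimes G$
over the stacked records, with trait-specific residuals and a residual
covariance identified only on animals with both records (fixed to zero
when the overlap is under 30 animals — too few records make
$\sigma_{E12}$ practically inestimable and it trades off directly against
$\sigma_{A12}$). The genetic correlation is
$r_g = \sigma_{A12}/\sqrt{\sigma_{A11}\sigma_{A22}}$, clipped to
$[-1,1]$; if either genetic variance is zero $r_g$ is reported missing
with a reason. Significance uses the LRT on $\sigma_{A12}=0$ (plain
$\chi^2_1$: a covariance is an interior parameter), with a delta-method
SE alongside; false-discovery control is Benjamini–Hochberg within trait
and model. When the unconstrained genetic matrix leaves the PSD cone it
is projected to the nearest PSD matrix in Frobenius norm and flagged.

Two code paths produce the same estimates where both apply (this equality
is tested): a general dense path for arbitrary missingness and pen/litter
terms, and an eigen-rotation fast path for complete records with only
additive + residual structure, in which rotating both traits by the
eigenvectors of $G$ turns every REML iteration into $O(n)$ work on
2×2 blocks. The fast path is what makes 100-replicate recovery
experiments at $n=1000$ cheap.

Binary phenotypes (health scores, mortality codings) are analyzed on the
observed 0/1 scale with the same linear mixed models; no threshold-model
fitting is attempted. Non-mortality traits are masked for animals that
did not survive to slaughter (`survivor_filter()`), so that e.g. finisher
growth is defined only on survivors while mortality itself keeps all
records.

## Count normalization

Raw gene counts are filtered (globin genes by id; genes with zero counts
in *more than* 80% of samples — a gene at exactly 80% is retained), then
normalized with TMM (trimmed mean of M-values, via edgeR with the
published defaults: 30% two-sided trim on M, 5% on A, precision
weighting, upper-quartile reference rule), factors rescaled to geometric
mean one. Expression values are $\log_2(\text{normalized count}+1)$,
where normalized counts are raw counts rescaled to a common effective
library size (library size × TMM factor). The scaling target defaults to
the geometric mean of the effective library sizes, which keeps values on
a count-like scale; `target_lib` fixes it explicitly. Note a subtlety:
given a sample's factor and a fixed target, normalized values are exactly
invariant to rescaling that sample's depth, but the automatic target and
TMM's precision weights are themselves (weak) functions of the observed
libraries, so re-estimated factors reproduce values only to ~0.01 log2
units. The convention is recorded in the `provenance` field of the
expression object.

## Windows and enrichment

Gene positions (1-based inclusive, as read from GFF/GTF or TSV) are
converted to 0-based half-open coordinates and each gene is assigned to
the 0.5-Mb window containing its midpoint, windows anchored at coordinate
zero (midpoint assignment is symmetric and strand-free; a start-anchored
variant is a switch). Per gene the larger of the WI and WO heritability
estimates is carried. A window with at least 5 genes of which ≥ 80% are
significantly heritable ($p<0.05$) is a *heritable region*; if all its
genes are significant and mean $h^2>0.2$ it is a *top region*. Windows
with fewer genes carry summaries but no flags.

Over-representation of highly heritable genes ($h^2>0.2$) in user-supplied
gene sets (GMT) uses the one-sided hypergeometric test with BH control.
Pre-ranked GSEA ranks genes by $\mathrm{sign}(\hat r_g)\cdot(-\log_{10}
p)$ — most significant positive correlation first, most significant
negative last; any monotone transform of the signed p-value gives the
same ranks, so only tie structure depends on this choice, and ties break
by $|\hat r_g|$ then gene id. The enrichment score is the signed extremum
of the weighted running sum (hit increments $\propto |s|^w$, $w=1$ by
default; $w=0$ recovers the classical Kolmogorov–Smirnov statistic). The
null redraws set positions uniformly (gene-label permutation — the
appropriate null for a pre-ranked list), NES divides ES by the mean
same-sign null ES, and FDR is the sign-stratified pooled-null ratio. Sets
are filtered to sizes strictly between 10 and 500 within the analyzed
universe. The trait × pathway summary writes
$\pm(-\log_{10}\mathrm{FDR})$, positive when the enrichment direction
(sign of NES times the trait's declared favorable direction) is
favorable, and clusters pathways by complete-linkage hierarchical
agglomeration on Euclidean distances between these profiles.

## The synthetic-data generator

All validation is against `simulate_cohort()`, which emulates the
structure the analyses assume: companies contributing batches of animals
housed in pens, litters nested in batches; SNP genotypes in
Hardy–Weinberg equilibrium with company-specific allele frequencies drawn
from the configured MAF range; WBC proportions from a Dirichlet with
concentration (30, 55, 8, 1, 5, 1) — a plausible young-pig leukogram
shape whose exact values are irrelevant to correctness; and read counts
(when requested) by negative-binomial sampling (dispersion 0.1) around
$2^{\mathrm{expression}}$ with log-normal library sizes, enough to
exercise the TMM front end without claiming distributional realism.

Two design choices matter for what the tests mean:

* **Genetic values are built from the simulated SNPs** ($u = Z_c b$ with
  $b$ i.i.d. normal and $Z_c$ the within-company-centered dosages), not
  drawn from a $N(0, G)$ oracle. The GRM the pipeline then builds from
  the same genotypes is exactly the covariance structure of $u$, so
  recovery experiments test the whole chain — QC, centering, scaling,
  block assembly, REML — rather than the optimizer alone. Within-company
  centering makes breeding values average exactly zero per company.
* **Exact variance bookkeeping.** Each random component (additive, pen,
  litter, residual) is rescaled to its exact target variance fraction;
  the total random variance per gene is 1. Configured $h^2/c^2$ are thus
  *realized* fractions, which removes one layer of Monte-Carlo noise
  from recovery experiments.

Phenotypes share genetics with chosen genes: a trait's breeding value is
$\sum_g w_g \tilde u_g$ plus an independent genotype-derived component,
with $w$ solved from the configured gene×trait correlations against the
realized between-gene genetic correlation matrix (an infeasible target —
implied shared variance above 1 — is an error naming the trait). Binary
traits threshold the standardized liability at the normal quantile of the
configured prevalence. Trait fixed effects reuse the expression model's
batch structure — the study's trait-specific fixed-effect models live in
its companion phenotype analyses, and carrying them would add nothing to
the correctness questions tested here; this is a documented
simplification.

Defaults mirror a large multi-herd challenge cohort (7 companies, 50
batches, ~64 animals per batch, dense genotypes with MAF > 0.05);
experiments in the tests use smaller explicit configurations.

### Study conditions for the recovery experiments

Recovery experiments use $n=400$ animals (8 batches × 50, 2 companies)
with 500 SNPs, 200 genes per setting; bivariate recovery uses $n=1000$
and 50 replicates. The marker count deserves a note: with unrelated
simulated animals the information for separating $\sigma^2_A$ from
$\sigma^2_e$ comes entirely from the dispersion of realized relationships
in $G$, which grows as markers shrink (Marchenko–Pastur: the eigenvalue
spread of $ZZ^\top/m$ widens as $n/m$ grows). Real cohorts get this
dispersion from family structure (litters of sibs), which the generator
deliberately does not model (no pedigree simulation). Five hundred
markers at $n=400$ give per-gene $h^2$ standard errors near 0.09,
matching the information content of a sib-structured cohort; with 2000+
markers and no pedigree the per-gene SE roughly doubles and boundary
truncation at $h^2=0$ would bias small-$h^2$ recovery means upward. This
was fixed from these first principles before the acceptance experiments
were frozen.

### What passing tests do and do not show

The generator draws SNPs independently (no linkage disequilibrium), uses
equal-sized balanced batches, Gaussian residuals, and exact variance
fractions. Passing recovery tests therefore demonstrates that the
estimation chain is consistent and calibrated *under the assumed model*;
they do not probe robustness to LD structure, pedigree confounding,
selection, non-Gaussian expression noise, or batch-by-genotype
interaction, all of which real data contain.

## Numerical choices and degenerate inputs

* Variance floor $10^{-8}\mathrm{Var}(y)$; diagonal ridge $10^{-6}$
  (`grm_ridge()`) when the smallest GRM eigenvalue is below $10^{-8}$.
* WBC proportions of zero: $\log_2(w + 0.001)$ — bounded, monotone, and
  rare enough that the offset choice is immaterial.
* $G=I$ with no pen/litter terms leaves $\sigma^2_A$ and $\sigma^2_e$
  unidentifiable; the fit flags `non_identifiable` via the singular AI
  matrix rather than returning arbitrary numbers.
* With a block GRM, the fixed design should span company means (batch
  effects nested in company do this automatically). Otherwise the
  company-contrast direction, which has GRM eigenvalue zero, can create
  a degenerate $\sigma^2_e \to 0$ likelihood spike.
* Collinear fixed-effect columns are dropped with a warning; animals with
  missing covariates are dropped with a message, never imputed.
* RFI enters average body weight untransformed by default; metabolic
  weight ($BW^{0.75}$) is behind a flag.

## Problem sizes

The test-suite experiments are sized for a desk machine: 20 oracle
instances at $n=60$; 3 × 200 genes at $n=400$; 400 null genes at
$n=300$; 100 bivariate replicates at $n=1000$; a 200-animal, 100-gene
demonstration pipeline run twice to confirm determinism. Together they
run in well under half an hour on one CPU.

## Limitations

Single-trait and bivariate models only (no multi-trait > 2); observed-scale
analysis of binary traits; no eQTL mapping, no genomic prediction of
expression, no LD-aware window definitions; enrichment uses user-supplied
gene sets and orthology maps rather than calling annotation services.
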