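---
title: "Methods: consensus networks and organoid drug-response modeling in ocrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus networks and organoid drug-response modeling in ocrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrnet)
```

## The problem

Biomarkers for chemotherapy response selected directly from bulk tumor
expression are fragile: stromal admixture and the sheer number of genes
relative to patients produce false positives that do not transfer across
cohorts. Patient-derived organoids offer a partial remedy — they preserve
the tumor's intrinsic expression program and allow direct ex vivo drug
testing — but organoid cohorts with drug response are small and usually lack
survival follow-up. `ocrnet` implements a discovery strategy that combines
the two sources: co-expression modules are required to be *reproducible*
across tumor tissue, matched organoids and an independent drug-profiled
organoid cohort; to be *clinically relevant* (survival association in
tissue); and to be *transferable* (tumor–organoid concordance), before any
gene enters a drug-response model.

## The pipeline, stage by stage

### Signed consensus co-expression network

For each cohort, the similarity of genes $i, j$ is the signed correlation
weight $s_{ij} = (1 + \mathrm{cor}(x_i, x_j))/2$ raised to a soft power,
$a_{ij} = s_{ij}^{\beta}$. The signed transform sends $r = -1$ to adjacency
0, so anti-correlated genes are never grouped; the power $\beta$ (default
12, the conventional choice for signed networks, checked by
`pick_soft_threshold()` against the scale-free topology fit) suppresses weak
chance correlations. Adjacency is converted into the topological overlap
matrix

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

which credits shared neighbors and is therefore robust to single spurious
edges. Per-cohort TOMs are made comparable by full quantile normalization of
their upper-triangle entries (each cohort's order statistics replaced by the
across-cohort mean; tied entries receive the average of their would-be
values) and combined entry-wise into the consensus TOM. The consensus
operator defaults to the component-wise **mean**, with the component-wise
minimum available via `consensus = "min"`.

### Module detection: the adaptive cut

Genes are clustered by average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$. Two parameters are fixed at the field's conventional
values: the dendrogram cut ceiling 0.999 and the minimum module size 30
(smaller clusters are relabeled `grey`). A *literal* static cut at 0.999 is
unusable at the cohort sizes this package targets, for a structural reason:
a gene with near-zero connectivity has $\min(k_i,k_j) + 1 \approx 1$ in the
TOM denominator, which inflates its overlap with any dense module above the
module–module overlap itself, so average linkage absorbs noise genes into
every module well below any cut near 1; and with a few dozen samples the
chance-correlation floor $E[((1+r)/2)^\beta]$ keeps between-module consensus
overlap above $10^{-3}$, so a cut at $1 - 10^{-3}$ cannot separate modules
either. `detect_modules()` therefore treats 0.999 as an *eligibility
ceiling* and places the actual cut in the middle of the widest gap of the
merge-height sequence below the ceiling — module-forming merges happen far
below the heights at which stragglers attach, so the widest gap separates
the two regimes. When the heights show no gap (one homogeneous block), the
rule falls back to the static cut, which is also available explicitly as
`method = "static"`. Surviving modules are labeled by the canonical color
sequence in decreasing size order with deterministic tie-breaking.

### Eigengenes, kME and the dual module filter

A module's eigengene is the first right singular vector of its standardized
gene-by-sample block (unit norm; sign fixed so the average correlation with
the module's genes is positive, making results platform-independent), with
the explained-variance fraction reported. Module membership `kME(g, m)` is
the Pearson correlation of gene `g` with eigengene `m`; the consensus kME is
its unweighted mean across cohorts.

Modules pass the dual filter when (i) a univariate Cox proportional-hazards
fit of the tissue eigengene (partial likelihood, Efron ties, unadjusted) has
Wald $p < \alpha$ for overall survival *or* recurrence-free survival, and
(ii) the Spearman correlation between the tissue and matched-organoid
eigengenes over paired samples has $p < \alpha$. Both criteria use raw
p-values at $\alpha = 0.05$; an optional BH adjustment exists but defaults
off, matching the practice of screening a handful of modules. Hub genes are
the members of selected modules with consensus $|\mathrm{kME}| \ge 0.5$,
inclusive at the boundary.

### Drug-response models

Hub-gene expression in the drug-profiled organoid cohort is regressed on
IC50 with three candidates:

* **ridge** — exact penalized least squares on standardized predictors,
  $\min \lVert y - X\beta\rVert^2 + \lambda \lVert\beta\rVert^2$, solved by
  SVD so that at fixed $\lambda$ the coefficients equal
  $(X^\top X + \lambda I)^{-1} X^\top y$; $\lambda$ is chosen by minimum
  mean 3-fold CV MSE over 100 log-spaced values spanning the data-driven
  maximum down to $10^{-4}$ of it. An elastic-net $\alpha$ grid is available
  (delegated to glmnet); the default is pure ridge. The fit includes an
  intercept, but the exported resistance score omits it — a constant shift
  cannot change groups or log-rank results.
* **rf** — a seeded, single-threaded regression forest (500 trees,
  $\mathrm{mtry} = \lceil p/3 \rceil$) with out-of-bag permutation
  importance: each gene's column is permuted $B = 10$ times and the
  importance is the mean increase in out-of-bag MSE. The final forest is
  refit on the genes with positive importance.
* **ensemble** — the positive-importance genes refit by ridge; the resulting
  linear coefficients define the exported model.

Candidates are compared by repeated 3-fold CV (fold assignments redrawn per
repetition from the base seed; the *entire* fitting path, including the
importance filter, is re-run inside each training fold), by AUC of their
tissue-cohort scores against the OS event indicator (Mann–Whitney rank
formulation, ties counting one half), and by the log-rank separation of
their maxstat-dichotomized tissue scores. The selection rule formalizes
"lowest CV error and highest AUC with a significant log-rank test":
candidates are filtered to log-rank $p < 0.05$; a candidate best on both CV
MSE and AUC wins; otherwise CV MSE ranks with AUC as tie-breaker, with a
warning so the ranking can be audited from the stored report.

### Scoring and survival validation

A patient's drug-resistance score is
$\mathrm{Score} = \sum_{i \in G} \beta_i \cdot \mathrm{Exp}_i$ over the
model genes (forest-predicted values for the `rf` kind). Per validation
cohort, the cutpoint maximizing the absolute standardized log-rank statistic
over all admissible splits (midpoints between consecutive distinct scores
leaving at least `minprop = 0.1` of samples on each side; ties to the
smallest cutpoint) dichotomizes patients into resistant
($\text{score} \ge \text{cut}$) and sensitive groups, compared by
Kaplan–Meier curves and the log-rank test (hypergeometric variance with
ties). The cutpoint is re-estimated on every cohort. The reported p-value is
the raw log-rank p of the selected split: maximal selection inflates it, the
test suite quantifies that inflation under the null, and downstream users
should read these p-values as descriptive, not as calibrated single-split
tests.

### Baselines and enrichment

The comparison procedures are reduced designs of the same machinery:
network models built from tissue only, from the matched pair, or from the
drug-profiled organoids alone (module relevance by eigengene–IC50 Spearman
correlation in the last case); and per-gene association filtering (gene–OS
Cox adjusted for age and sex, gene–IC50 Spearman, paired tumor–organoid
Spearman; criterion 1 requires all three $p < 0.05$, criterion 2 adds sign
agreement between the OS and drug effects). Where a survival outcome must serve as a regression
response for model training (the tissue-only and matched-pair network
baselines), the response is constructed explicitly by the caller — the
binary OS event indicator is the reading used in the examples, with OS time
among uncensored samples as the documented alternative; neither is
presented as canonical, since turning censored survival into a regression
target is inherently a modeling choice. Over-representation analysis
is the upper-tail hypergeometric test against GMT gene sets intersected with
the universe (set sizes 10–500), BH-adjusted per collection.

## The synthetic cohorts

`generate_cohorts()` plants rank-one modules: module $m$ has a latent
standard-normal factor per sample; gene $g$ in module $m$ is
$\lambda_g f_m + \sigma z$ with loadings
$\lambda_g \sim U(0.4, 0.95)$ and $\sigma = 0.5$; background genes are pure
noise at the same $\sigma$. Rank-one modules match the eigengene-as-first-PC
summarization the analysis assumes, and the wide loading range gives each
module a genuine hub spectrum so that membership rankings are informative.
The matched organoid shares each tissue sample's factors up to a per-module
correlation $\rho_m$; the independent organoid cohort draws fresh factors.
IC50 is linear in the drug module's factor
($1.5 f_{\mathrm{drug}} + N(0, 0.5^2)$, i.e. 90% of IC50 variance is
signal — an ex vivo assay under controlled conditions), and tissue OS/RFS
times are exponential with rate
$0.05 \cdot \exp(0.8 f_{\mathrm{drug}})$ per month under uniform censoring
on $(0, 60)$ months, giving roughly 30% censoring and a baseline median
survival near 14 months — a plausible advanced-CRC scale. Exponential times
with a log-linear rate satisfy proportional hazards exactly, which the Cox
stage assumes; survival is generated from the module *factor*, not from raw
genes, so both module-level and hub-gene-level signal exist by
construction. Age and sex are generated independently of outcome, so
covariate-adjusted baselines can be checked for type-I error.

The canonical design (`sim_config()` defaults, seed 20240101): modules of
60/50/40 genes plus 150 background genes; cohorts of 60 tissue, 60 matched
organoid, 40 drug-profiled organoid samples;
$\rho = (0.9, 0.8, 0.2)$ with module 1 driving IC50 and survival. Module 2
is concordant but survival-null and module 3 is survival-null and
discordant, so the dual filter has genuine negatives to reject.

What the generator does *not* emulate: count-based sequencing noise,
batch effects, stromal admixture, correlated censoring, non-linear
dose–response, and multi-factor (non-rank-one) modules. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under its own assumptions, not performance on real cohorts.

## Numerical choices and degenerate inputs

* Probe collapse keeps the probe with the largest IQR (type-7 quantiles);
  ties go to the lexicographically smallest probe id.
* The log2 transform uses offset 1 by default and refuses non-positive
  arguments, naming the offending cells.
* Constant genes are rejected in adjacency construction (undefined
  correlation), dropped with a warning from eigengene blocks, and recorded
  as missing kME (excluded from hub selection).
* Quantile-calibration ties receive the average of tied order statistics;
  calibration preserves each matrix's internal ranks.
* The eigengene sign rule (positive average correlation with the module)
  removes the SVD sign ambiguity across platforms and runs.
* Spearman p-values use the t approximation for $n > 9$ and the exact
  distribution for $n \le 9$.
* Maxstat ties resolve to the smallest cutpoint; dichotomization is
  inclusive (boundary scores are resistant).
* All stochastic fits (forest, folds, permutations) consume an explicit
  seed; two runs from the same seed are bit-identical.

## Problem sizes used by the test suite and acceptance script

Statistical checks run at sizes chosen to give stable Monte-Carlo estimates
while keeping the default suite fast: type-I error bands use 2000 null
replicates; dual-filter and end-to-end recovery use 50 seeded replicates of
the canonical design (the end-to-end loop isolates the ensemble path with
`cv_reps = 0`, since the measured quantities — gene recovery and held-out
log-rank separation at $n = 200$ — do not depend on the CV comparison); the
acceptance script runs all three candidates with 20 CV repetitions and
300-tree forests. Model-comparison behavior at the default 100 repetitions
is exercised through the same code path and differs only in Monte-Carlo
precision.

## Known limitations

* The widest-gap adaptive cut assumes modules are cohesive relative to the
  noise floor; in data where module and noise merge heights interleave it
  will fall back toward coarse partitions. The static cut remains available
  for audit.
* Raw maxstat-selected log-rank p-values are anti-conservative (quantified
  in the test suite); no selection-adjusted p is offered.
* Univariate, unadjusted Cox screening of eigengenes matches the intended
  module-stage design but cannot separate module effects from correlated
  clinical covariates.
* Block-wise decomposition for networks beyond ~20k genes is out of scope;
  matrices are held dense.

## A worked example

```{r example, eval = FALSE}
fx <- default_fixture()
pl <- run_pipeline(fx, candidates = "ensemble", cv_reps = 0,
                   n_trees = 300, n_perm = 5, seed = 7)
glance(pl)

vc <- generate_validation_cohort(sim_config(), n = 200, seed = 99)
val <- validate_cohort(pl$training$final, vc$expr, vc$phenotype)
glance(val)
autoplot(val)
```
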