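---
title: "Methods: digital gene-expression analysis of retinoblastoma subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital gene-expression analysis of retinoblastoma subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbdge)
```

## The problem

Retinoblastoma tumors present in two histopathological subtypes:
undifferentiated (URB), which carries high-risk features, and differentiated
(DRB). `rbdge` implements an analysis pipeline for comparing the two
subtypes on NanoString nCounter digital gene-expression data — a counting
platform well suited to the fragmented RNA of formalin-fixed
paraffin-embedded (FFPE) tissue. The panel layout mirrors a PanCancer-style
CodeSet: 770 endogenous genes, 30 housekeeping (reference) genes, six
positive-control probes spiked at a known concentration ladder
(128/32/8/2/0.5/0.125 fM), and eight probe-free negative controls.

Because no public count data accompany the cohort this package models, the
package ships a synthetic-cohort generator with complete ground truth; every
pipeline stage is exercised and validated against that truth, and the one
part of the clinical dataset that is published in full — the clinical
characteristics table — is reproduced exactly.

## Normalization model

Raw counts go through three steps, in a fixed order:

1. **Technical (positive-control) normalization.** For lane $l$, let $g_l$
   be the geometric mean of its positive-control counts. Every count in the
   lane is multiplied by $f_l = \bar g / g_l$, where $\bar g$ is the cohort
   arithmetic mean of the $g_l$. Identical lanes therefore get $f_l = 1$.
   A zero positive-control count makes the geometric mean undefined and is
   an error, not a silent fix.
2. **Background subtraction.** On the scaled lane, the negative controls
   give $\mu_l$ and $\sigma_l$ (sample SD, $n-1$ denominator); the noise
   threshold $\tau_l = \mu_l + 2\sigma_l$ is subtracted from every
   endogenous and housekeeping count, floored at zero. Genes are never
   dropped at this stage. Control probes pass through unsubtracted so the
   audit trail stays intact.
3. **Biological (reference-gene) normalization.** Each lane is multiplied
   by $r_l = \bar h / h_l$, with $h_l$ the geometric mean over the lane's
   housekeeping probes with positive counts.

Whether background should be subtracted before or after positive-control
scaling is genuinely ambiguous; the default subtracts on the scaled lane
(`subtract_first = FALSE` in `technical_normalize()`), and the alternative
order is a switch, not a fork of the code path.

**Noise filter.** After normalization, each endogenous gene is tested with
a one-sided one-sample *t*-test against
$\mu_0 = \operatorname{mean}_l(\tau_l)$ recomputed on the normalized scale
(a per-lane variant is available via `per_lane = TRUE`). Genes with
$p > 0.05$ are flagged as not sufficiently expressed to overcome basal
noise; they are retained in the matrix but excluded from differential
testing. Zero-variance genes get the limit decision ($p = 0$ above
$\mu_0$, $1$ below, $0.5$ exactly at it) so degenerate input yields a call
rather than an exception. Whether the original noise test ran per gene
across samples or per sample across genes cannot be determined from the
description we model; the per-gene reading is implemented because it is the
one that produces a per-gene expressed/not-expressed call.

## Differential expression

Tests run on $\log_2(x+1)$-transformed normalized counts — the
transformation is a package choice (it makes the parametric branch
plausible and fold changes symmetric). Per gene:

- **Branching.** Shapiro–Wilk in each group; the classical pooled-variance
  Student's *t*-test only when *both* groups give $p > 0.05$ (the strictest
  reading of testing "each data set"), otherwise the Wilcoxon rank-sum
  test. Constant or tiny ($n < 3$) groups go non-parametric.
- **Wilcoxon dialect.** Exact enumeration when $n_a + n_b \le 12$ and
  tie-free; otherwise normal approximation with tie and continuity
  correction. The exact branch is verified against brute-force labeling
  enumeration in the test suite.
- **Multiplicity.** Benjamini–Hochberg over exactly the tested (above-noise)
  set; significance at $q \le 0.05$.
- **Effect size.** $\log_2((\bar x_A + 1)/(\bar x_B + 1))$, positive when
  higher in URB.

QC utilities (mean–variance outlier screen at 3 MADs, sample–sample
correlation matrices, PCA by SVD on centered genes, hierarchical clustering
with a supervised within-subtype mode) support the exploratory side of the
analysis.

## Clinical table battery

`build_table1()` reproduces the published battery: uncorrected Pearson
chi-squared for sex and laterality (the *uncorrected* statistic is what
reproduces the printed $p = 0.5051$ for laterality; Yates' correction gives
$\approx 0.74$), Mann–Whitney for age in months, Kruskal–Wallis for the
ordinal N/C stages, Fisher's exact test for RB1 germline status with the
point-probability two-sided rule (which reproduces the printed $0.1827$;
odds-ratio two-siding does not), and Kruskal–Wallis across the three age
bins with the subtype indicator as the response — statistically unusual,
but it mirrors the published table's layout. Two printed values are known
not to be reproducible from the printed counts (sex $p = 0.04$ vs computed
$0.0487$, presumably truncation; N stage $p = 0.06$ vs computed
$\approx 0.30$); the package reports the computed values.

`table1_annotations()` is a deterministic fixture whose margins equal the
published table. The joint assignment of covariates to samples is
arbitrary — every test in the battery depends only on margins — and the
per-patient ages reproduce only the printed medians, ranges and bins, since
the raw ages are not published.

## Marker scoring

Marker discrimination is summarized by the empirical ROC over midpoint
thresholds, with AUC in its Mann–Whitney pair-counting form (ties one
half). Internal validation is a non-stratified bootstrap of the full
cohort (default $B = 1000$) with percentile 95% intervals; resamples
missing a class are redrawn and counted. Cutoffs maximize Youden's
$J$ — the description we model says only "by their respective cut-offs",
and $J$ is the standard ROC-derived choice — with ties broken toward the
pooled median and markers with AUC $< 0.5$ flipped to `down-in-URB`.
Binarized markers ("1 equaling a better chance of an event") sum to a
per-sample composite score; the default panel is the top 5 significant
genes by oriented AUC (no published panel size exists to match).

The score-to-probability curve is a logistic function fitted by
**nonlinear (weighted) least squares**, not maximum likelihood, because
least squares is the stated estimator: damped Gauss–Newton
(Levenberg–Marquardt) from $a = b = 0$, relative tolerance $10^{-8}$, at
most 500 iterations, default unit weights (inverse-variance weights are a
flag). On separable data the objective is minimized only as
$b \to \infty$; the slope is capped at $|b| \le 50$ and in practice the
damped iteration converges with saturated predictions (both sides beyond
0.99/0.01) before reaching the cap.

## Conditional inference trees

The tree engine is implemented from scratch in its minimal two-class form
(identity influence functions, numeric covariates; categorical covariates
would be one-hot expanded). At each node, covariate $j$ is scored by the
permutation linear statistic $T_j = \sum_i x_{ij} y_i$ with conditional
moments $E[T] = \sum x \sum y / n$ and
$V[T] = \sum(x-\bar x)^2 \sum(y - \bar y)^2/(n-1)$; $p$-values are
two-sided normal on $z = (T-E)/\sqrt V$ for nodes of size $\ge 8$ and full
permutation enumeration below that (both verified against brute-force
enumeration in the tests). Selection is Bonferroni-corrected over the
covariates; growth stops when the best adjusted $p$ exceeds
$\alpha = 0.05$, which gives family-wise type-I control at the root — the
property the acceptance suite measures over 500 null simulations. Splits
maximize $|z|$ over admissible midpoints (each child $\ge$ `min_leaf`,
default 2; nodes under 4 samples are not split — defaults sized for
~21-sample cohorts). Prediction routes `<=` left; leaf ties fall back to
parent majority, then training prevalence, then the lexicographically
first class. Evaluation is leave-one-out cross-validation, which is fully
deterministic here because no Monte-Carlo p-values are used.

## Pathway overlay

Gene-level results map onto curated diagram nodes of the MAPK, PI3K-AKT
and cell-cycle pathways (bundled, user-editable JSON; the node-to-gene
mapping is a best-effort curation from standard HGNC symbols). Each node
gets a ternary state: $+1$ when significant up-regulated members (higher
in URB) outnumber down-regulated ones, $-1$ in the opposite case, $0$ on
ties or silence — the red/green/neutral coloring of pathway overlay
figures. Enrichment is a plain hypergeometric over-representation test;
this is a deliberate, documented stand-in, since no ranking statistic or
permutation scheme is specified for the enrichment analysis it emulates.

## The synthetic-data generator

`simulate_dataset()` draws an 11 URB + 10 DRB (+2 control) cohort by
default, matching the modeled study's size. The generative model:

- **Counts.** Endogenous gene $g$ in lane $i$ is negative-binomial
  (gamma-Poisson) with mean $\lambda_i \, 2^{\beta_g + \delta_{gi}}$ and
  dispersion 0.1 — NB is the accepted overdispersion model for probe
  counts; nothing in the modeled study constrains the choice. Lane factors
  $\lambda_i$ are log-normal (log-SD 0.15, a typical lane-to-lane spread).
  Negative controls are Poisson with mean $15\lambda_i$; positive controls
  scale Poisson means along the concentration ladder.
- **Baselines.** Expressed genes draw $\beta_g \sim U(6.5, 12)$ in log2
  units (roughly 90–4000 counts), i.e. clearly above background, as befits
  "transcripts with relevant gene expression"; a `background_fraction`
  (default 6%) of endogenous genes instead sits at the negative-control
  level, mirroring the ~94% above-noise structure of the real cohort.
- **Effects.** A `de_fraction` (default 0.2, the scale of the ~23%
  differential fraction reported for the real cohort) of expressed genes
  get $\pm$`lfc_magnitude`$/2$ (default total 1.5) applied symmetrically
  to the two groups, sign Bernoulli(½), so library size stays balanced and
  volcano plots are two-sided. Housekeeping genes never carry effects.
- **Clinical covariates** are drawn with the published cohort's observed
  proportions — illustrative, for end-to-end smoke tests, never
  inferential.
- **RNG.** One stream per dataset, seeded once from `seed` and restored
  afterwards; a single stream (rather than per-sample substreams) keeps
  the implementation simple while remaining bit-reproducible.

What the generator does **not** emulate: FFPE degradation profiles, probe
GC bias, cartridge batch effects, or any dependence between clinical
covariates and expression. Passing tests on synthetic cohorts therefore
demonstrate that the *procedures* are correct and calibrated — not that
the biological conclusions drawn from the real cohort would replicate.
The two non-tumor control samples are generated (the cohort we mirror had
them) but no analysis stage consumes them, which mirrors their unstated
analytic role.

## Problem sizes and numerical choices

The test suite and acceptance checks use: 20 seeds of the full 770-gene
11+10 cohort for null calibration and power/FDR recovery; 770 × 20
threshold-level genes for the noise-filter size check; 200 cohorts × 1000
bootstrap iterations for interval coverage; 500 null cohorts (n = 21, 10
covariates) for tree type-I control. These sizes give Monte-Carlo bands
(3 binomial SDs) tight enough to be meaningful while keeping a full run on
one CPU in minutes.

Tolerances and conventions worth knowing: Benjamini–Hochberg is monotone
but *not* idempotent (re-adjusting adjusted values can inflate them — a
property of the step-up rule, asserted as such in the tests); the
technical-normalization factors anchor to the cohort mean of lane
geometric means, so rescaling one lane changes all normalized values by a
single cohort-wide constant (relative expression is invariant); exact
branches switch to asymptotics at $n_a+n_b > 12$ (Wilcoxon) and node size
$\ge 8$ (tree permutation test).

## Known limitations

- The headline counts of the modeled cohort (726/770 expressed, 166/770
  differential) depend on patient RNA that is not public; the package
  reproduces the *procedure* and its calibration, and the clinical table
  exactly, but not those counts.
- The probability model's least-squares estimator is less efficient than
  logistic maximum likelihood and is used because it is the specified
  estimator.
- The tree engine implements the minimal two-class case only (no ordinal
  multiway splits, censored responses, or forests).
- The pathway node-to-gene mapping is a curation from figure-level labels;
  it is shipped as editable data precisely because it is a judgment call.
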