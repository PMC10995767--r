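---
title: "NKG2A/NKG2C immune-bias calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NKG2A/NKG2C immune-bias calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkbias)
```

## The scientific problem

NKG2A (gene *KLRC1*) is an inhibitory receptor and NKG2C (*KLRC2*) its
stimulatory counterpart; both heterodimerize with CD94 (*KLRD1*) on NK cells
and subsets of CD8⁺ T cells. Individuals differ in the balance of NKG2A⁺
versus NKG2C⁺ cells, and that balance — the *immune bias* — associates with
clinical outcomes across infection, autoimmunity and cancer. `nkbias`
implements the full analysis chain: calling NKG2A⁺/NKG2C⁺ status at the
level of single cells, bulk samples and spatial spots; aggregating cell
calls into patient-level bias labels; and the downstream association layer
(logistic odds-ratio models, survival contrasts, set-overlap tests, a
TCRβ-repertoire CMV serostatus classifier, spatial density and
ligand-receptor statistics, and CD8⁺ T cell phenotyping helpers).

Because the cohorts this kind of analysis targets are controlled-access,
the package ships a synthetic-data generator for every modality. Each
generator plants known effects and emits its ground truth, so every stage
has a parameter-recovery test that runs on any machine.

## Calling rules, by modality

**Single cells, ln(CPM+1) scale.** A cell is NKG2A⁺ when CD94 (*KLRD1*)
and NKG2A (*KLRC1*) are both ≥ 2.5 on the ln(CPM+1) scale and NKG2C
(*KLRC2*) is not; NKG2C⁺ symmetrically. CD94 co-expression is required
because the receptors only reach the surface as CD94 heterodimers. Cells
with all three markers above threshold are tracked as double-positive but
excluded from ratio computations — keeping the A:C ratio interpretable —
and their prevalence is reported so users can audit the choice.

**Single cells, Z-score scale.** When only per-gene Z-scores are
available, absolute thresholds are meaningless; a cell is NKG2A⁺ when
z(*KLRC1*) − z(*KLRC2*) ≥ 1 (one standard deviation of margin), NKG2C⁺
symmetrically. The two margins are mutually exclusive by construction.

**Bulk samples.** Each sample gets a score
log₂(KLRD1·KLRC1 + ε) − log₂(KLRD1·KLRC2 + ε) with ε = 10⁻⁹ so zero
expression never produces infinities. The top ⌊0.2 n⌋ samples by score are
labeled NKG2A⁺, the bottom ⌊0.2 n⌋ NKG2C⁺ — upper and lower pentiles.
Ties are broken by stable input order; when scores tie across a pole
boundary the top pole claims its samples first and the bottom pole takes
the first ⌊0.2 n⌋ of the remainder. Pentile membership is invariant under
any strictly monotone transform of the scores.

**Spatial spots.** Spatial counts are sparse, so positivity is literal:
a spot is T-cell positive when mean(*CD3D*, *CD3E*, *CD3G*) > 0, CD8
positive when additionally mean(*CD8A*, *CD8B*) > 0, and CD8⁺ spots split
on *KLRC1* > 0 into NKG2A⁺ and NKG2A⁻ CD8 T cell spots. A single-marker
variant calls spots positive for one receptor alone.

**Patients.** Within one cell type at one timepoint, a patient is
NKG2A-biased when the NKG2A⁺ cell count strictly exceeds a factor times
the NKG2C⁺ count — factor 3 for NK cells (which are constitutively
NKG2A-skewed) and 1 for CD8 T cells. "Three times more" is read as the
strict inequality n_A > 3·n_C: a tie is not "more". A patient is biased
when *any* acute timepoint is biased; the continuous A:C ratio
(n_A + 1)/(n_C + 1) pools acute counts with a pseudocount of 1.
Unbiased patients are coded 0 in models; that complement absorbs both
NKG2C-biased and indeterminate patients, which the output documents.

## The association layer

**Log-odds models.** Outcomes are modeled by maximum-likelihood logistic
regression (IRLS via `stats::glm`, |Δ log-likelihood| < 10⁻⁸ or 100
iterations), reporting ln(odds ratio) with Wald 95% confidence intervals
(coef ± 1.96·SE) — the forest-plot quantities. Covariate coding: female
sex = 1, age in years (standardized in the simulator), severe disease =
WHO Ordinal Scale ≥ 5. Perfect separation is escalated to an error that
recommends a penalized fit rather than silently reporting divergent
coefficients. No profile-likelihood intervals are offered; the Wald form
matches the intended forest plots.

**Survival.** Kaplan-Meier product-limit curves per group with a log-rank
chi-square test (hypergeometric variance, groups − 1 degrees of freedom),
via the survival package. With no censoring the estimate equals the
empirical survival function exactly; with no events the log-rank statistic
is undefined and the function errors.

**Set overlap.** For sets A and B in a universe of size N, the enrichment
p-value is P(X ≥ k) for X hypergeometric — the survival function at
k − 1, so the observed overlap itself counts as "as much or more". A
literal "1 − CDF at k" variant (which excludes the observed value) is
exposed behind a flag for audit. The depletion probability is defined as
the exact complement 1 − P(X ≥ k), so the two sum to one exactly by
construction. Expressed-gene universes come from two filters: top 10% of
genes by mean expression (infection contexts) or mean > 0.01 (cancer
context); the antibody set is all symbols with prefix IGH, IGK or IGL.

**Differential features.** Per feature, a two-sided Mann-Whitney U test
(exact enumeration when the combined sample size is ≤ 20 and untied,
normal approximation with tie and continuity correction otherwise) plus
the log₂ fold change of group means with pseudocount 10⁻⁹. A feature is
retained when p < 0.05 *and* the fold change is positive; the
multi-timepoint variant intersects the per-timepoint selections. Raw
p-values are reported by default — matching forest-plot style reporting —
with Benjamini-Hochberg available but off. Note that under the null the
*selected* fraction is about α/2, because the direction filter removes
half of the false positives; the p-values themselves are calibrated to α.

## CMV serostatus from TCRβ repertoires

Repertoires are sets of unique TCRβ chains keyed by the exact triple
(CDR3 amino-acid sequence, V gene, J gene). Two features summarize each
sample: the number of reference CMV-associated chains detected and the
total number of unique chains. The classifier is a linear-kernel
support-vector machine over the two features with 6-fold stratified,
seeded cross-validation choosing the cost by mean held-out AUROC.
Features are standardized before fitting: unique-chain counts are orders
of magnitude larger than match counts, and an unscaled margin objective
would ignore the informative feature. A patient is CMV positive when any
of their samples is predicted positive. AUROC is computed through the
Mann-Whitney identity (average ranks for ties), which the tests verify
against a pairwise-comparison oracle exactly.

The published 164-chain reference list is not redistributed; a synthetic
reference of the same size (unique random triples) stands in for it, and
is labeled synthetic throughout. The headline external-cohort AUROC of
published work is therefore out of scope here; what the tests establish is
that the classifier recovers planted enrichment (detection rates 0.3
versus 0.01 at depth 10⁴) with held-out AUROC ≥ 0.9 and falls to chance
under label permutation.

## Spatial statistics

**Neighbor graph.** Visium-style hex grids: two spots are neighbors iff
|Δrow| ≤ 1 with |Δcol| = 2 on the same row and |Δcol| = 1 on adjacent rows
(interleaved-column convention), giving interior spots six neighbors.
Square grids use rook adjacency.

**Density diffusion.** Positive spots diffuse outwards over the graph:
density(s) = α^d(s) with d the multi-source BFS distance to the nearest
positive spot, 1 at positive spots, 0 beyond a cutoff radius and on
unreachable spots. α defaults to 0.5 and the cutoff to 6; neither is
dictated by the underlying procedure, so the density output is documented
as visualization-grade while all quantitative tests pin the closed form
α^d itself.

**Ligand-receptor scores.** Per spot and pair, the product of a ligand
summary and a receptor summary; multi-subunit complexes are summarized by
the minimum over components (limiting-subunit convention). The default
neighborhood is the spot alone, for determinism and auditability; a
spot-plus-neighbors mode exists because juxtacrine signaling spans
adjacent spots. Differential interaction between NKG2A⁺ and NKG2A⁻ CD8 T
spot classes uses the Mann-Whitney test per pair, log₂ fold change of
class means, and the composite rank weight log₂FC · (−log₁₀ p) — the
product of the volcano-plot axes.

## Phenotyping helpers

**HVG selection.** Genes with zero total expression are removed;
dispersion = variance/mean per gene; genes are binned into 20
equal-frequency bins by mean; normalized dispersion is the dispersion
centered by bin median and scaled by bin MAD (a robust variant of the
classic mean/dispersion normalization — the method family is named in the
source procedure, not the formula, so median/MAD is this package's
documented choice). Bins whose MAD is zero carry no dispersion signal and
get normalized dispersion 0. Selection: mean strictly in (0.5, 7.5) and
normalized dispersion ≥ 0.5. Selection is invariant to gene and cell
order (average ranks in the binning).

**Cluster annotation.** Upstream embedding/clustering (PCA, batch-aware
kNN, Leiden, UMAP) is deliberately delegated to established
implementations; this module consumes a precomputed cluster assignment.
A marker is "high" in a cluster when the cluster mean exceeds the
across-cluster average of cluster means — a reproducible proxy for
annotation by inspection. Rules fire in fixed precedence: proliferation
(MKI67), MAIT (KLRB1), SLEC-like (B3GAT1/CD57 *and* IFNG), memory (IL7R),
effector (GZMB). SLEC-like precedes effector because effector is defined
as non-SLEC-like cells still expressing GZMB. Annotation is invariant to
adding a constant to all cluster means of a gene.

## What the simulators emulate — and what they do not

All generators expand one global seed into fixed per-stage child streams,
so adding a stage never perturbs another stage's draws and identical
configurations are bit-reproducible.

- `simulate_cohort()`: latent patient bias (prevalence 0.4), cells whose
  receptor expression is drawn around means 3.5 (positive) and 0.8
  (negative) with σ = 0.5 on the ln(CPM+1) scale — so the 2.5 threshold
  recovers planted cell labels with ≈ 2% error — and mortality from a
  logistic model with planted ln(OR) of −1 (bias), −0.2 (female sex) and
  0.4 (age per SD). 25 cells per patient per cell type keeps patient-level
  calls essentially error-free at the default label fractions (0.9 vs
  0.1 NKG2A among committed cells).
- `simulate_bulk()`: log-normal receptor expression around a latent bias
  axis; exponential survival with baseline hazard 10⁻³/day in the top
  pentile, hazard ratio 3 in the bottom pentile, geometric-mean hazard in
  between, independent exponential censoring.
- `simulate_spatial()`: a 20×20 hex grid with one contiguous 30-spot
  NKG2A⁺ CD8 T region and one disjoint NKG2A⁻ region; 40 ligand-receptor
  pairs of which 3 get a four-fold co-expression boost inside the NKG2A⁺
  region.
- `simulate_repertoires()`: 100 subjects, ~10⁴ unique chains each
  (depth log-normally varied, σ = 0.1 — constant depth would make the
  unique-count feature degenerate), reference-chain detection rates 0.3
  (seropositive) versus 0.01 (seronegative) over a 164-chain synthetic
  reference.
- `simulate_marker_populations()`: five populations elevating their
  markers by 2.0 ln(CPM+1) units over a baseline of 1.0, with 50
  background genes whose baselines vary uniformly on (0.5, 2.5) — real
  transcriptomes have heterogeneous means, and a homogeneous background
  makes bin-level dispersion normalization degenerate.

Noise is a log-normal-style perturbation on the normalized scale rather
than full count simulation: every calling rule operates on normalized
values, so counts would add machinery without exercising any additional
code path. The generators make no attempt to match real cohorts' marginal
distributions, library-size effects, doublets or ambient RNA. Passing
recovery tests therefore demonstrates correctness of the *rules and
models*, not robustness to every artifact of real data.

## Numerical choices and edge cases

- Validation is strict: duplicated identifiers, NaN/Inf values, non-binary
  outcomes, and constant predictors are hard errors naming the offender.
- Z-scored matrices must actually be standardized (per-gene mean within
  10⁻⁶ of 0, SD within 10⁻⁶ of 1 over genes with nonzero variance).
- Gene symbols match case-sensitively after one alias table mapping the
  protein names that the literature uses interchangeably with symbols
  (CD94→KLRD1, NKG2A→KLRC1, NKG2C→KLRC2, CD57→B3GAT1, CD56→NCAM1,
  IFNγ→IFNG); unknown symbols pass through untouched.
- Patients with zero cells of the requested type get an NA bias with a
  warning and are excluded from downstream models.
- Constant ligand-receptor pairs get p = 1 rather than an undefined test.
- The problem sizes used by the test suite and the acceptance script
  (500 logistic replicates at n = 2000; 1000 log-rank null replicates at
  50 per arm; 100 spatial slides; 100 annotation runs) were chosen to
  pin Monte-Carlo error well below the tolerances being checked while
  keeping a full run in the minutes range on a single core.

## Known limitations

- The bias coding collapses "not NKG2A-biased" into one reference class.
- The CMV classifier's external validity is untestable without the
  original cohorts; only planted-signal recovery is claimed.
- The spatial ligand-receptor product is computed within spots by
  default; whether the original computation spanned neighboring spots is
  ambiguous, so both modes are provided and neither claimed as canonical.
- The HVG "high" threshold and the marker-rule precedence are documented
  proxies for judgment calls made by inspection in the original workflow.
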