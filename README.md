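# nkbias

Calling NKG2A⁺/NKG2C⁺ immune biases from transcriptomic data, and the
association analyses built on those calls.

## The problem

NKG2A (*KLRC1*) delivers inhibitory signals to NK cells and CD8⁺ T cells;
NKG2C (*KLRC2*) is its stimulatory counterpart. Both require CD94
(*KLRD1*) as a heterodimer partner. Individuals skew toward one receptor
or the other, and this patient-level *immune bias* — defined from the
ratio of NKG2A⁺ to NKG2C⁺ cells within a cell type — associates with
survival and inflammation across infection, autoimmune disease and
cancer. `nkbias` is for computational immunologists who want that whole
analysis chain as tested, reusable functions:

- **Bias calling**, four modalities:
  single cells on the ln(CPM+1) scale (NKG2A⁺ iff KLRD1 ≥ 2.5 and
  KLRC1 ≥ 2.5 and not KLRC2 ≥ 2.5, symmetric for NKG2C⁺); Z-scored data
  (margin |z(KLRC1) − z(KLRC2)| ≥ 1); bulk samples (score
  log₂(KLRD1·KLRC1 + ε) − log₂(KLRD1·KLRC2 + ε), top/bottom pentile
  labels); spatial spots (nested CD3 → CD8 → KLRC1 positivity on sparse
  counts).
- **Patient calls**: NKG2A-biased iff n_A > 3·n_C (NK cells) or
  n_A > n_C (CD8 T cells), strict, at any acute timepoint; continuous
  ratio (n_A + 1)/(n_C + 1).
- **Association layer**: logistic ln(odds-ratio) models with Wald 95%
  CIs (female = 1, age in years, severe = WHO Ordinal Scale ≥ 5),
  Kaplan-Meier/log-rank survival on score pentiles, exact hypergeometric
  set-overlap tests (P(X ≥ k)), Mann-Whitney differential features with
  positive-fold-change filtering, Pearson/Spearman correlations.
- **CMV serostatus**: linear-SVM classifier over (matched reference
  TCRβ chains, unique TCRβ count) with stratified 6-fold CV; exact
  (CDR3, V, J) triple matching; AUROC via the Mann-Whitney identity.
- **Spatial statistics**: hex/square neighbor graphs, multi-source
  density diffusion α^d, ligand-receptor product scores with
  limiting-subunit complexes, and differential interaction ranking by
  log₂FC · (−log₁₀ p).
- **Phenotyping**: dispersion-based HVG selection (mean ∈ (0.5, 7.5),
  normalized dispersion ≥ 0.5) and ordered marker-rule cluster
  annotation (proliferation/MAIT/SLEC-like/memory/effector).
- **Synthetic data** for every modality with planted, recorded ground
  truth, so each stage has a parameter-recovery test with no external
  downloads.

See `vignettes/nkbias-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a 400-patient cohort with a planted protective bias effect
(ln OR = −1 on mortality), call cells and patients, and fit the
covariate-adjusted model:

```r
library(nkbias)

cfg <- sim_config(seed = 11, n_patients = 400)
cohort <- simulate_cohort(cfg)

cohort$cells$bias <- as.character(call_cells_lncpm(cohort$expr))
bias <- call_cohort_bias(cohort$cells, cell_type = "CD8T")
head(bias, 3)
#>   patient_id cell_type n_a n_c biased ac_ratio n_cells
#> 1      P0001      CD8T   2  14      0     0.20      25
#> 2      P0002      CD8T   2  11      0     0.25      25
#> 3      P0003      CD8T  15   1      1     8.00      25

fit_logit(cohort$patients$deceased,
          data.frame(bias = bias$biased,
                     sex  = cohort$patients$sex_female,
                     age  = cohort$patients$age_std))
#> Logit model (n = 400, converged = TRUE)
#>          term estimate     se    ci_lo    ci_hi         p
#> 1 (Intercept)  -0.6873 0.1761 -1.03244 -0.34226 9.466e-05
#> 2        bias  -0.6812 0.2564 -1.18371 -0.17877 7.876e-03
#> 3         sex  -0.4193 0.2388 -0.88744  0.04876 7.912e-02
#> 4         age   0.3052 0.1207  0.06859  0.54176 1.146e-02
```

The `bias` coefficient is the ln(odds ratio) of death for NKG2A-biased
patients: −0.68 with 95% CI (−1.18, −0.18) here, i.e. roughly a halving
of the odds, consistent with the planted −1 at this cohort size (the
point estimate sits well inside its own CI of the truth). `sex` and
`age` recover their planted effects (−0.2 and 0.4 per SD) in direction.

Survival on bulk pentiles — top (NKG2A⁺) versus bottom (NKG2C⁺) fifth of
the bias score, with a planted hazard ratio of 3:

```r
bulk <- simulate_bulk(cfg)
poles <- subset(bulk$samples, pentile != "UNASSIGNED")
km_logrank(poles$time, poles$event, poles$pentile)
#> Log-rank chi-square = 51.176 (df = 1), p = 8.44e-13
```

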