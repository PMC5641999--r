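# serumNMR

Cohort-scale serum ¹H NMR metabonomics in R: spectral processing,
O-PLS-DA chemometrics, model validation and STOCSY, plus a synthetic
serum-cohort generator with known ground truth.

## Who this is for

Metabonomics analysts who need the classical serum NMR workflow as
scriptable, tested R functions: process CPMG free-induction decays (or
ready spectra) into a binned feature matrix, gate outliers, fit and
*validate* discriminant models between clinical groups, and trace which
metabolites drive a separation. Because patient spectra behind published
serum studies are rarely deposited, the package ships a first-class
simulator so every stage can be exercised against cohorts whose true group
effects are known by construction.

## The models in brief

* **Processing** — apodization (`exp(-π·lb·t)`, lb = 1 Hz), zero-fill to
  64k, FFT, automatic zero-order phasing, asymmetric-least-squares
  baseline, referencing of the α-glucose anomeric line to 5.236 ppm,
  0.004-ppm binning over 0.5–9.0 ppm (2125 bins), removal of the water
  region 4.23–5.18 ppm, integer-bin alignment of the drift-prone segments
  1.43–1.50 / 6.98–7.10 / 7.70–7.84 ppm, and total-sum normalisation.
* **PCA / Hotelling T²** — outlier gating at the F-based 95% limit
  `A(n−1)(n+1)/(n(n−A))·F₀.₉₅(A, n−A)` on 2 score dimensions.
* **PLS-DA / O-PLS-DA** — NIPALS PLS1 and the single-response orthogonal
  filter (one predictive + one orthogonal component) on unit-variance
  data; back-scaled loadings `p·sd` colour-coded by the Pearson
  correlation `r` of each bin with the predictive score, flagged at the
  critical correlation `t/√(t² + n − 2)` (0.32–0.48 across typical n).
* **Validation** — stratified sevenfold cross-validated
  `Q² = 1 − PRESS/SSy`, a 200-permutation test (pass ⇔ real Q² beats the
  permutation maximum), CV-ANOVA
  `F = ((SSy − PRESS)/2)/(PRESS/(n − 3))`, ROC AUC of the cross-validated
  scores, and a verdict that requires the permutation test *and* CV-ANOVA
  to pass simultaneously.
* **STOCSY** — correlation of a driver bin against all bins, and
  region-to-region peak correlations with exact-t p-values.

## Worked example

```r
library(serumNMR)

design <- cohortDesign(
  groups  = c(control = 15, case = 15),
  effects = list(glucose = c(case = 1.4), citrate = c(case = 1.6)),
  intensityCv = 0.1, seed = 7)
cohort <- simulateCohort(design)
binned <- processCohort(cohort)
binned
#> class: BinnedSpectra
#> dim: 1887 30
#> ...
#> bin width:0.004ppm;1 excluded region(s); normalized: TRUE

report <- validateContrast(binned, groupsOf(binned), positive = "case",
                           nPerm = 200, seed = 7)
report
#> ValidationReport [case vs control], n = 30
#>   Q2(PLS-DA) = 0.500   Q2(O-PLS-DA) = 0.483   R2 = 0.995
#>   permutation (200): pass   CV-ANOVA p = 0.000135: pass   AUC = 0.982
#>   verdict: VALID

model   <- fitOplsDa(scaleMatrix(binned), groupsOf(binned), positive = "case")
profile <- backscaledLoadings(model, binned)
head(significantBins(profile, assignments = list(
  citrate = c(2.50, 2.70), glucose = c(3.2, 4.0))), 5)
#>        ppm metabolite direction         r   backscaled
#> 2.550 2.55    citrate        up 0.8951572 2.123013e-05
#> 3.530 3.53    glucose        up 0.8699458 9.398071e-05
#> 3.890 3.89    glucose        up 0.8640906 5.773187e-05
#> 2.650 2.65    citrate        up 0.8476810 2.023130e-05
#> 2.670 2.67    citrate        up 0.8424210 1.563227e-05
```

Reading this: the 30-sample cohort separates cleanly (cross-validated
Q² ≈ 0.5, AUC ≈ 0.98), the model is declared valid because both the
permutation test and CV-ANOVA pass, and the significant-bin table points
at exactly the two metabolites that were raised in the cases, both marked
"up" (higher in cases than controls).

Full end-to-end runs — simulate or ingest, process, gate outliers, fit and
validate every configured contrast, write tables/models/provenance — go
through `runPipeline(pipelineConfig(...))` or a YAML file via
`readPipelineConfig()`; see `inst/extdata/example_run.yaml`.

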