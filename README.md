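# protonSelect

Delineation-based decision support for selecting head-and-neck cancer
patients for proton therapy.

## The problem

Under model-based selection (the Dutch procedure), a head-and-neck
patient qualifies for intensity-modulated proton therapy (IMPT) when a
photon-vs-proton treatment plan comparison shows a sufficiently large
expected toxicity reduction: the normal tissue complication
probability (NTCP) difference profile
ΔNTCP = NTCP(VMAT) − NTCP(IMPT) must exceed protocol thresholds.
Making both plans for every patient is slow and expensive, and the
wait delays treatment start. `protonSelect` implements a decision
support tool that predicts the full ΔNTCP profile *immediately after
delineation*, before any treatment planning, from target-overlap
geometry alone — so that referral for a formal plan comparison can be
limited to patients who are likely to qualify.

It is intended for radiotherapy physicists and clinical researchers
who want to study, refit or deploy delineation-based pre-selection on
their own planning data.

## The method

For each organ at risk (OAR) *o* and each modality
*m* ∈ {VMAT, IMPT}, the mean dose is modelled linearly in two
geometric predictors computed after expanding both planning target
volumes (PTVs) isotropically by a penumbra-scale margin *r*:

    Dmean(o, m) = b0 + b1 · pct_in70(o; r) + b2 · pct_in54_out70(o; r)

where `pct_in70` is the % of the OAR volume inside the expanded 70 Gy
target and `pct_in54_out70` the % inside the expanded 54.25 Gy target
but outside the 70 Gy one. Models are fitted by OLS over a margin
grid (0, 3, 5, 7, 10, 15 mm) for the eight protocol OARs (oral
cavity, both parotid and submandibular glands, and the three
pharyngeal constrictor muscles); for each OAR × modality the margin
with the highest in-sample R² is kept. Predicted doses feed four
logistic NTCP models (grade ≥2 / ≥3 xerostomia and dysphagia, with
baseline complaint covariates), giving the predicted ΔNTCP profile,
to which the protocol thresholds are applied:

1. ΔNTCP ≥ 10 % for a single grade ≥2 endpoint, or
2. ΔNTCP ≥ 5 % for a single grade ≥3 endpoint, or
3. ΣΔNTCP ≥ 15 % over grade ≥2 endpoints (counting endpoints
   individually ≥ 5 %), or
4. ΣΔNTCP ≥ 5 % over grade ≥3 endpoints (counting endpoints
   individually ≥ 3.75 %).

The package also provides the three post-hoc sensitivity adjustments
(IMPT dose rescaling, 95 % CI-bound coefficients, residual-SD
shifts), a hybrid mode comparing an *actual* VMAT plan against the
predicted IMPT plan, diagnostic evaluation of predicted against
actual plan-comparison decisions (sensitivity / specificity / PPV /
NPV / accuracy with Wilson or Clopper–Pearson CIs, learning-curve and
tumor-location subgroups), voxel-phantom and cohort simulators, and a
CLI. Mask input is NIfTI or NRRD; expansion honors anisotropic voxel
spacing via an exact Euclidean distance transform.

NTCP model coefficients are configuration (`readNtcpModels()`): the
clinical national-protocol coefficients are not redistributed here,
and a clearly synthetic fixture set ships for testing
(`inst/extdata/synthetic_ntcp_models.json`).

## Worked example

```r
library(protonSelect)

## a synthetic 151-patient cohort with known generative truth
cohort <- generateCohort(cohortSpec(n_patients = 151, seed = 42))

## fit the margin grid and keep the best margin per OAR x modality
grid <- fitMarginGrid(cohort$features, cohort$dmeans)
grid
#> DmeanModelGrid: 8 OARs x 6 margins x 2 modalities = 96 cells (96 fitted, 0 failed)

sel <- selectAllMargins(grid)
sel[["parotid_left|IMPT"]]
#> DmeanModel parotid_left / IMPT @ 7 mm: Dmean = 2.490 + 0.6422*in70 + 0.3046*in54out70  (R2 = 0.980, sigma = 1.96 Gy, n = 151)

## one patient, end to end: features -> doses -> NTCP -> decision
fe <- cohort$features[cohort$features$patient_id == "P001", ]
bl <- as.list(cohort$covariates[cohort$covariates$patient_id == "P001", ])
runPatient(fe, sel, cohort$spec$ntcp_models, bl)
#> DecisionResult (predicted): QUALIFIES via sum_g2
#>   dNTCP [pp]: dysphagia_g2 9.88, xerostomia_g2 8.81, dysphagia_g3 1.16, xerostomia_g3 1.35

## score the tool against the cohort's actual-plan decisions
pred <- vapply(cohort$labels$patient_id, function(p) {
  f <- cohort$features[cohort$features$patient_id == p, ]
  b <- as.list(cohort$covariates[cohort$covariates$patient_id == p, ])
  qualifies(runPatient(f, sel, cohort$spec$ntcp_models, b))
}, logical(1))
diagnosticsWithCi(confusionCounts(pred, cohort$labels$actual_qualifies))
#>      measure numerator denominator estimate ci_low ci_high
#>  sensitivity       101         111    0.910  0.842   0.950
#>  specificity        24          40    0.600  0.446   0.737
#>          ppv       101         117    0.863  0.789   0.914
#>          npv        24          34    0.706  0.538   0.832
#>     accuracy       125         151    0.828  0.760   0.880
```

The `DmeanModel` line shows the selected expansion margin (7 mm) and
the fitted dose–overlap relation with its in-sample R² and residual
SD in Gy. The `DecisionResult` shows the four ΔNTCP values in
percentage points and which protocol criterion fired (here the summed
grade ≥2 criterion: 9.88 + 8.81 = 18.7 ≥ 15 with both endpoints
≥ 5). The diagnostic table reads the usual way — e.g. on this
synthetic cohort a positive tool outcome is right 86 % of the time
(PPV), with 95 % Wilson intervals.

The same pipeline runs from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","proton-select",package="protonSelect"))')
Rscript $CLI simulate --outdir work --n 151 --seed 42
Rscript $CLI fit      --features work/features.csv --dmeans work/dmeans.csv --out work/models.json
Rscript $CLI select   --models work/models.json --out work/selected.json
Rscript $CLI predict  --features work/features.csv --models work/selected.json --out work/predicted.csv
Rscript $CLI decide   --predicted work/predicted.csv --ntcp work/ntcp_models.json \
                      --covariates work/covariates.csv --out work/decisions.csv
Rscript $CLI evaluate --decisions work/decisions.csv --labels work/labels.csv \
                      --covariates work/covariates.csv --out work/report.json
```

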