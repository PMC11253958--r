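# iohexolGFR

Measured glomerular filtration rate (GFR) from iohexol plasma clearance,
with the method-agreement toolkit needed to decide whether a simplified
sampling protocol can replace a reference one.

## Who this is for

Renal-physiology laboratories and clinical researchers who measure GFR by
iohexol plasma clearance in adults with chronic kidney disease, and
biostatisticians evaluating simplified (shortened or sparse-sampling)
clearance protocols against reference protocols on repeated-measures data.

## What it computes

**Clearance pipeline.** After an iohexol bolus, plasma concentration follows
a bi-exponential `C(t) = A·e^(−αt) + B·e^(−βt)` and the clearance is
`Cl = Dose / AUC` with `AUC = A/α + B/β`. The package implements:

* the 10-hour, 16-sample two-compartment reference fit (`ref_2c_10h`);
* elimination-phase-only one-compartment (slope–intercept) fits for the
  8/7/6/5/4-hour protocols, corrected with the Bröchner–Mortensen quadratic
  `Cl_BM = 0.990778·Cl − 0.001218·Cl²` (`oc_8h_bm` … `oc_4h_bm`);
* an explicit 4-point (10/30/120/300 min) reduced two-compartment
  approximation (`popPK_approx`);
* DuBois body-surface-area normalization to mL/min/1.73 m², and the
  CKD-EPI 2009 and IDMS-MDRD serum-creatinine eGFR comparators.

**Agreement statistics** for test-vs-reference GFR pairs with repeated
studies per patient: Lin's concordance correlation coefficient (CCC), total
deviation index (TDI), coverage probability (CP), P10/P15, Bland–Altman bias
and limits of agreement, mountain (folded-percentile) curves, a
random-intercept regression (lme4), and patient-clustered bootstrap
confidence intervals — assembled by `agreement_report()`.

**Synthetic cohort generator.** `simulate_cohort()` produces CKD cohorts
(GFR ~15–57 mL/min/1.73 m²) with exact two-compartment kinetics, repeated
studies per patient and proportional lognormal assay error, so the entire
pipeline is testable without patient data and every fit can be checked
against the analytic identity `Dose/AUC = Cl`.

## Worked example

```r
library(iohexolGFR)

cfg    <- phase_preset("phase_b", seed = 1, n_patients = 30, assay_cv = 0.025)
cohort <- simulate_cohort(cfg)
tab    <- measure_gfr_table(cohort$studies,
                            methods = c("oc_8h_bm", "oc_7h_bm",
                                        "oc_6h_bm", "oc_5h_bm"))
head(tab, 4)
#>   patient_id study_index oc_8h_bm oc_7h_bm oc_6h_bm oc_5h_bm ckd_epi  mdrd
#> 1       P001           1    31.48    31.24    31.04    31.01   32.92 30.52
#> 2       P002           1    32.30    32.22    32.63    33.52   28.87 29.02
#> 3       P002           2    31.57    31.16    30.92    30.73   28.87 29.02
#> 4       P003           1    27.19    27.74    29.15    31.32   24.06 22.80

colMeans(tab[, 3:6])
#> oc_8h_bm oc_7h_bm oc_6h_bm oc_5h_bm
#>    27.96    28.15    28.51    28.95
```

Each row is one clearance study; columns are BSA-normalized GFR
(mL/min/1.73 m²) per protocol plus the creatinine equations. The column
means already show the characteristic truncation bias: the shorter the
sampling window, the larger the mean GFR, because the mono-exponential fit
absorbs more distribution-phase contamination.

```r
pairs <- paired_gfr(tab$patient_id, tab$study_index,
                    tab$oc_8h_bm, tab$oc_7h_bm)
agreement_report(pairs, B = 500, seed = 1)
#> <agreement_report> 59 studies in 30 patients
#>   CCC 0.998 (0.997 to 0.999)
#>   TDI 3.121 (2.218 to 3.921) % (p = 0.9)
#>   CP  100.000 (100.000 to 100.000) % (delta = 5 absolute)
#>   P10 100.0; P15 100.0
#>   bias 0.72 (percent), limits of agreement -2.75 to 4.19
```

Read: across 59 simulated studies, the 7-hour protocol agrees with the
8-hour reference to a CCC of 0.998 (above the 0.9 concordance bar), 90% of
its values fall within ±3.1% of the reference (TDI, below the 10% adequacy
bar), and every difference lies within the 5 mL/min/1.73 m² tolerance
(CP 100%). Parenthesized ranges are 95% patient-clustered bootstrap
intervals.

The same pipeline runs from the shell via the wrapper in `inst/cli/`:

```sh
gfr simulate --preset phase_b --n-patients 30 --seed 1 --out cohort/
gfr fit --concentrations cohort/concentrations.csv \
        --covariates cohort/covariates.csv --out gfr/
gfr agreement --gfr-table gfr/gfr_table.csv \
              --reference oc_8h_bm --test oc_7h_bm,oc_6h_bm,oc_5h_bm \
              --seed 1 --plots --out agreement/
```

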