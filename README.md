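# chedecomp

Measurement of catastrophic health expenditure (CHE) from household survey
microdata and twofold decomposition of the insured/non-insured gap in CHE
incidence.

Who it is for: health-financing and equity analysts working with household
expenditure surveys in settings with community-based health insurance
(CBHI), who need to go from raw records to a publishable decomposition
table — and to validate the whole chain on simulated data when the real
microdata cannot be shared.

## What it computes

A household incurs CHE when its annual health expenditure — direct medical
plus direct non-medical plus indirect costs by the human-capital approach
(lost days × daily valuation) — strictly exceeds a threshold share τ
(default 0.10) of total household expenditure. The package measures this,
builds an asset-based wealth index (prevalence filter 5%/95%, iterative
correlation filter on the band [0.1, 0.9], first principal component of
the standardized asset matrix, tie-preserving quintiles), screens
explanatory variables by Pearson chi-square, and then decomposes the
probability-scale gap between groups A (non-insured) and B (insured) with
group-specific logit fits β_A, β_B and logistic cdf F:

    R = mean F(X_A β_A) − mean F(X_B β_B)
      = [mean F(X_A β_A) − mean F(X_B β_A)]   = E  (endowments, "explained")
      + [mean F(X_B β_A) − mean F(X_B β_B)]   = C  (coefficients, "unexplained")

with Yun first-order weights attributing E and C to individual model terms,
delta-method (default) or household-bootstrap standard errors, and an
optional deviation-from-mean normalization that makes detailed categorical
contributions invariant to the reference-level choice. E + C = R and the
exhaustiveness of the detailed terms hold to 1e-10 and are asserted on
every run.

A synthetic household-survey generator (outcome-level, with known group
coefficients and analytically computed true E and C; and expenditure-level,
with lognormal spending calibrated to a target CHE prevalence and a
PCA-recoverable one-factor asset inventory) provides the ground truth that
the test suite checks the estimator against.

## Worked example

```r
library(chedecomp)

## protocol arithmetic: single population proportion, 10% non-response,
## design effect 2
n <- sample_size(0.5, 0.05, 1.96, nonresponse = 0.10, design_effect = 2)
#> base 384 -> with non-response 423 -> designed size 846

## simulate a two-stratum survey under the default study conditions
gen <- generate_outcome_level(synthetic_config(seed = 1))
che_headcount(gen$records)$proportion        # 0.2339 overall incidence
hc  <- che_headcount(gen$records, stratum = "non_insured")
c(hc$within_stratum, hc$share_of_total)      # 0.2441, 0.1867

## decompose the gap over a compact covariate set
res <- decompose_gap(gen$records,
                     c(head_age_group = "<=30", chronic_condition = "yes",
                       traditional_medicine = "yes", family_size_cat = "<=4"))
print(res)
```

```
Twofold logit decomposition of non_insured - insured gap
  n_A = 631, n_B = 194, SEs: delta, normalization: none
  Raw gap R:          0.04303 (-0.01876, 0.10481)  %100.00  p=0.1723
  Endowments E:      -0.04670 (-0.06471, -0.02870)  %-108.55  p=3.672e-07
  Coefficients C:     0.08973 (0.02372, 0.15574)  %208.55  p=0.007716

Detailed attribution:
                   term        E  pct_E      p_E        C  pct_C   p_C
            (Intercept)  0.00000   0.00       NA  0.00559  12.98 0.962
    head_age_group31-45  0.00667  15.50 1.50e-01 -0.01109 -25.78 0.766
    head_age_group46-60 -0.02224 -51.69 9.68e-03  0.01140  26.50 0.790
      head_age_group>60 -0.00299  -6.94 1.51e-06  0.00434  10.09 0.837
    chronic_conditionno -0.02911 -67.66 8.05e-08 -0.00311  -7.24 0.943
 traditional_medicineno  0.00166   3.86 3.08e-03  0.06086 141.45 0.317
      family_size_cat>4 -0.00070  -1.62 1.27e-02  0.02174  50.54 0.327
```

Reading this: at these simulated conditions the non-insured incidence
exceeds the insured by 4.3 percentage points (R = 0.043). If the
non-insured had the insured group's covariate mix (at their own
coefficients) the gap would *widen* by 4.7 points (E = −0.047, −108.6% of
the gap, driven mostly by the chronic-condition composition), while
differences in coefficients account for C = 0.090 (+208.6%). Percentages
outside [0, 100] are legitimate — only their sum is constrained to 100.
`write_decomposition()` exports the publication-shaped CSV/JSON;
`run_pipeline()` drives the whole chain (CHE table, wealth model,
screening report, decomposition, reproducibility manifest) from a single
config, and `inst/cli/chedecomp.R` wraps it for the shell.

See the vignette (`vignettes/che-gap-decomposition.Rmd`) for the model,
its assumptions, the generator's design, and numerical conventions.

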