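---
title: "Measuring catastrophic health expenditure and decomposing the insured/non-insured gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring catastrophic health expenditure and decomposing the insured/non-insured gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chedecomp)
```

## The problem

Out-of-pocket payment at the point of care is the dominant way households in
many low-income settings finance health care. A household is said to incur
*catastrophic health expenditure* (CHE) when its health spending exceeds a
fixed share of its capacity to pay; the headcount of such households is a
standard indicator of financial risk protection. Community-based health
insurance (CBHI) schemes are meant to reduce that risk, so the natural
equity question is: how large is the gap in CHE incidence between
non-insured and insured households, and how much of it is due to the two
groups simply *being different* (age structure, family size, wealth,
chronic illness) versus the same characteristics *acting differently* in
the two groups?

`chedecomp` implements that full analysis chain for household survey
microdata: CHE measurement, an asset-based wealth index, chi-square
variable screening, and a logit-based twofold decomposition of the CHE gap
with detailed per-covariate attribution. Because survey microdata of this
kind are typically not deposited, the package ships a synthetic household
generator with known ground truth, which is how the pipeline is validated.

## CHE measurement

Annual household health expenditure is the sum of three channels over a
12-month recall window:

* direct medical spending;
* direct non-medical spending (transport, cafeteria, lodging);
* indirect costs by the human-capital approach: lost days (patient plus
  caregiver) times a per-household daily valuation. Pre-monetized losses
  (premature death, early retirement) are expected to be folded into that
  product by the data supplier, since no separate valuation formula is
  defined.

With health expenditure $H$ and denominator $D$, the share is $H/D$ and the
CHE flag is $H/D > \tau$ — a *strict* inequality, because the definition is
"exceeds"; ties are measure-zero on real currency data and are pinned by a
unit test. The default threshold is $\tau = 0.10$, configurable in
$[0.10, 0.40]$.

Two denominator conventions circulate in this literature and the package
exposes both as flags rather than deciding silently:

* `denominator_kind = "total"` (default): total household expenditure
  (food + non-food + health), i.e. the budget-share convention with health
  spending included in the total;
* `denominator_kind = "nonfood"`: total minus food (a crude
  capacity-to-pay proxy); `include_health = FALSE` removes health spending
  from the denominator.

Headcounts are reported with both stratum conventions — within-stratum
(flagged in stratum / stratum size) and share-of-total (flagged in stratum
/ full analytic sample) — because published reports use both and they
answer different questions. Currency is treated as a unitless positive
real; all quantities are within-survey shares, so flags are invariant to a
common rescaling of every component (tested).

## Asset-based wealth index

Wealth is scored from a binary asset inventory (default 35 indicators) in
four steps:

1. **Prevalence filter.** Indicators with positive frequency above 0.95 or
   below 0.05 are dropped (boundaries inclusive for retention, since the
   exclusion rule is strictly "greater/less than"): near-constant items
   carry almost no signal and destabilize a correlation PCA.
2. **Correlation filter.** The band rule — pairwise absolute correlations
   must lie in $[0.1, 0.9]$ — is stated entry-wise in the field, but
   deleting *entries* is undefined for a PCA input. The package therefore
   applies it greedily per variable: at each round the variable with the
   most out-of-band pairwise correlations is removed (ties broken by lower
   prevalence, then name), correlations are recomputed, and the loop stops
   when no violations remain (or at a configurable minimum of 3
   survivors). Every removal is logged with its round and violation count.
3. **First principal component** of the *standardized* (correlation)
   matrix — binary indicators with heterogeneous prevalence make the
   covariance PCA prevalence-driven. The unit-norm loading vector is
   oriented so that an anchor asset (default: the highest-prevalence one)
   loads positively.
4. **Quintiles** at the 20/40/60/80 rank percentiles of the in-sample
   scores, labels ascending in score. All households sharing a tied score
   land in one bin, so bin sizes need not be equal — with clustered asset
   patterns, unequal quintile sizes are the expected outcome, not an
   error.

On the one-factor synthetic generator (n = 2000) the PC1 score correlates
with the latent wealth above 0.9 and the quintile assignment has Spearman
correlation above 0.85 with it; both bounds are asserted in the test
suite.

## Screening

Each candidate explanatory variable is cross-tabulated against the CHE
flag and tested with the Pearson chi-square statistic
$\sum (O - E)^2 / E$, with **no** Yates continuity correction by default —
software defaults vary, so the choice is pinned and exposed as a flag.
Variables with $p < \alpha$ (default 0.05) enter the decomposition, and the
full report is retained for audit. Rows carrying the explicit
`"missing"` sentinel (only `referral_history` may carry it) are excluded
per table with the excluded count reported. Type-I calibration is verified
by simulation (null rejection rate within [0.03, 0.07] at $\alpha = 0.05$).

## The twofold decomposition

With groups $A$ (comparison; non-insured by default) and $B$ (reference;
insured), group-specific logit fits $\beta_A, \beta_B$, and $F$ the
logistic cdf, the probability-scale gap over each group's observed design
rows is

$$
R \;=\; \overline{F(X_A \beta_A)} - \overline{F(X_B \beta_B)}
  \;=\; \underbrace{\left[\overline{F(X_A \beta_A)} -
        \overline{F(X_B \beta_A)}\right]}_{E\ \text{(endowments)}}
  \;+\; \underbrace{\left[\overline{F(X_B \beta_A)} -
        \overline{F(X_B \beta_B)}\right]}_{C\ \text{(coefficients)}} .
$$

$E$ is the part of the gap attributable to covariate-distribution
differences evaluated at the comparison group's coefficients; $C$ is the
part attributable to coefficient differences evaluated over the reference
group's design. The identity $E + C = R$ holds by construction and is
asserted at $10^{-10}$ on every run, as is the exhaustiveness of the
detailed terms below. A positive $R$ means higher CHE incidence among the
non-insured (the insured = 0 / non-insured = 1 coding convention).
Swapping $A$ and $B$ negates $R$ exactly and yields the dual split.

**Group logits** are fitted by Newton-Raphson (equivalently IRLS) with
step-halving whenever a full step would decrease the log-likelihood,
gradient tolerance $10^{-8}$, at most 100 iterations, and covariance from
the inverse observed information. These constants are fixed so results are
bit-stable. Perfect (or quasi-) separation — a covariate pattern
predicting the outcome deterministically, e.g. a sparse dummy cell with
zero events — makes the MLE diverge; the fitter reports it as an error
naming the runaway covariate once $|\beta_j| > 15$ with a non-vanishing
gradient, rather than returning a meaningless estimate. The fit is
cross-checked against `stats::glm` to $10^{-6}$ in the test suite, and an
intercept-only fit against the closed form $\log(p/(1-p))$ to $10^{-10}$.

**Detailed attribution** uses Yun-style first-order weights:

$$
E_k = E \cdot \frac{\beta_{A,k}(\bar X_{A,k} - \bar X_{B,k})}
      {\sum_j \beta_{A,j}(\bar X_{A,j} - \bar X_{B,j})}, \qquad
C_k = C \cdot \frac{\bar X_{B,k}(\beta_{A,k} - \beta_{B,k})}
      {\sum_j \bar X_{B,j}(\beta_{A,j} - \beta_{B,j})},
$$

with the intercept carried among the $C$ terms (its $\bar X$ component
is 1) and contributing zero to $E$. Weights sum to one within each family,
so detailed terms exhaust the aggregates. When a weight denominator
vanishes (below $10^{-12}$) the detailed attribution for that family is
flagged unstable and zeroed while the aggregates remain valid. A
substitution oracle (shifting one covariate's distribution at a time)
bounds the linearization error of $E_k$ at 10% relative on a two-covariate
instance in the tests. Percent-explained columns are
$100 \cdot \text{component}/R$; individual percentages may legitimately
fall outside $[0, 100]$ — only their sum is constrained to 100. When
$R = 0$ the percent columns are reported as undefined.

**Reference-level dependence.** Under treatment coding the detailed split
of a categorical variable depends on which level is the reference (the
reference row carries no contribution of its own, as in published tables).
With `normalization = "deviation"` each categorical block is re-expressed
in deviation-from-mean form — every level, including the reference, gets a
coefficient, the block sums to zero, and the linear predictor is
unchanged — which makes the detailed contributions invariant to the
reference choice (property-tested over all reference choices of a 3-level
covariate). The default is `"none"`, matching the conventional published
layout with explicit reference rows.

**Standard errors.** The default is the delta method: the full mapping
$(\beta_A, \beta_B) \mapsto (R, E, C, E_1, \dots, C_1, \dots)$ is
differentiated by central finite differences (relative step $10^{-6}$) and
the two coefficient covariances are propagated through the Jacobian, with
the design means treated as fixed — the convention of the estimator family
this implements. Routing the point estimates and the Jacobian through one
function means the estimate and its SE can never disagree about the
estimand. Wald 95% intervals use the normal quantile. A nonparametric
bootstrap (household resampling within group, default 500 replicates,
seed-controlled) is provided as a cross-check; resamples whose refit
separates are dropped and counted. One structural caveat, verified
numerically: for the endowment component $E$ the bootstrap SE is
systematically *larger* than the delta SE (ratios around 0.4–0.6 at
n = 1000 per group), because resampling households also propagates
covariate-composition variability, which the X-conditional delta method
deliberately excludes. For $R$ and $C$, where coefficient uncertainty
dominates, the two methods agree within about 20%. Users who want
X-unconditional uncertainty for $E$ should prefer the bootstrap.

## The synthetic generator

Real microdata of this kind are rarely deposited, so validation rests on a
generator whose defaults emulate the study conditions of a two-stratum
CBHI town survey: 194 insured and 631 non-insured households, group-specific
categorical marginals over eleven household covariates, and an overall CHE
target prevalence of 0.2994 at the 10% threshold.

* **Outcome level**: covariates are drawn independently within group from
  the marginals and the CHE flag is Bernoulli with probability
  $F(x'\beta_g)$ under known group coefficients. The generator returns the
  truth two ways: *realized* $R/E/C$ (counterfactual means over the drawn
  designs — the estimand the fitted decomposition targets, conditional on
  X) and *population* $R/E/C$ (exact enumeration of the independent-
  marginal cell grid, free of design noise; identical marginals give
  population $E = 0$ exactly). Default coefficients are moderate
  ($|\beta| \le 1.6$) with intercepts placing within-group incidence near
  0.25 (non-insured) and 0.15 (insured) — an insurance scheme that dampens
  but does not remove expenditure risk — and attenuated covariate effects
  in the insured group.
* **Expenditure level**: lognormal spending components (strictly positive
  and right-skewed, the standard shape for household spending), Poisson
  lost days valued at a flat daily rate, and a one-factor asset inventory:
  a standard-normal latent wealth score $z$ per household with each
  asset Bernoulli$(\,F(\text{logit}(p_a) + \lambda z)\,)$, base
  prevalences spanning 0.10–0.90 and loading $\lambda = 1.2$. The
  `direct_medical` scale is calibrated by bisection until the realized
  headcount is within ±1 percentage point of the target (per group if the
  target is per-group). Currency values are rounded to 2 decimals so file
  round-trips are exact.

Covariates are independent within group because only marginals are
specified — the minimal assumption, and a real limitation: the generator
does not reproduce covariate dependence (e.g. age–marital-status
association), survey design effects, interviewer or recall error, or
any direct structural link between insurance and spending beyond the
group-specific parameters. Passing the recovery tests therefore shows the
*estimator* is correct under the stated model, not that the model captures
every feature of field data.

A sparse-cell consequence worth knowing: with the insured group's
`separated` marital share at 5/194 and realistic incidence, a zero-event
cell arises in roughly one in ten replicates at n = 1000 per group. Such
samples are inestimable by any logit; the fitter reports separation, and
the Monte-Carlo validation draws a replacement seed (the truth is
recomputed per drawn sample, so the comparison remains valid).

## Validation scale and numerical choices

The test suite validates, among others: round-trip file I/O on an
825-household sample; marginal recovery at $n = 10^5$ within
$3\sqrt{p(1-p)/n}$ for every category; coefficient recovery at $n = 10^5$
within 3 SEs; decomposition identities at $10^{-10}$ across randomized
runs; 200-replicate recovery of $E$ and $C$ at n = 1000 per group with
delta-method CI coverage required in $[0.91, 0.985]$; chi-square null
calibration over 2000 replicates of a 2×5 table at n = 800; and wealth
recovery at n = 2000. These sizes were chosen as the smallest at which the
stochastic bounds are sharp.

Other pinned choices: the sample-size helper reproduces the protocol
arithmetic chain exactly as printed in field protocols (base value
truncated — 384.16 becomes 384 — the non-response step rounded up — 422.4
becomes 423 — then the design-effect multiplication: 846), because the
goal is to reproduce the study's arithmetic, not an idealized
ceiling-everywhere convention; `referral_history` missingness is encoded
by an explicit `"missing"` sentinel, never an empty cell, and the pipeline
offers both `listwise` deletion and `drop_variable` modes because the
handling of the 130 reduced-n households is not derivable from the source
tables; all other missingness is a hard error.

## Limitations

* Logit link only; no probit or Poisson variants, no survey weights, no
  threefold (interaction) decomposition.
* No impoverishment metrics (overshoot, mean positive overshoot,
  poverty-line logic).
* The wealth index is plain PCA on binary indicators — no polychoric
  PCA or MCA, no urban/rural split.
* Detailed attribution is first-order (Yun weights); the linearization
  error grows with effect sizes and gap magnitude.

## A worked run

```{r, eval = FALSE}
cfg <- synthetic_config(seed = 1)          # study-condition defaults
gen <- generate_outcome_level(cfg)
res <- decompose_gap(gen$records)          # A = non-insured vs B = insured
print(res)
write_decomposition(res, "decomposition.csv", "decomposition.json")
```

For a config-driven end-to-end run (CHE table, wealth model, screening
report, decomposition, manifest) see `run_pipeline()`; a thin command-line
front end with `samplesize`, `simulate` and `run` verbs is installed under
`inst/cli/chedecomp.R`.
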