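---
title: "Methods: the dietary amino acid composition index and its cohort analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dietary amino acid composition index and its cohort analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Diets differ not only in how much protein they supply but in the *mix* of
essential amino acids that protein carries. The WHO/FAO/UNU human
requirement amino acid pattern (HRAAP) describes the proportions in which
adults need the essential and conditionally essential amino acids. This
package scores how closely a diet's amino-acid composition adheres to that
pattern — the Amino Acid Composition Index (AACI) — and provides the
epidemiological machinery to ask whether poor adherence predicts incident
type 2 diabetes (T2DM), whether it shifts the fasting serum amino-acid
profile, and how much of the diet–diabetes association travels *through*
specific serum amino acids.

## The index

Eleven amino acids are scored: isoleucine, leucine, lysine, methionine,
phenylalanine, threonine, tryptophan, valine, histidine, cysteine and
tyrosine. Tryptophan — the scarcest essential amino acid in most diets —
serves as the denominator. With reference levels $h_i$ (any consistent
unit; the shipped default is the adult pattern in mg per g protein) the
reference composition ratios are

$$\beta_i = h_i / h_{Trp},$$

and for a diet with daily intakes $d_i$ each amino acid receives a
satisfaction score

$$q_i = \left|\frac{d_i / d_{Trp}}{\beta_i} - 1\right|,
\qquad \mathrm{AACI} = \sum_{i=1}^{11} q_i .$$

Zero means the composition is exactly proportional to the requirement
pattern; larger values mean worse adherence in either direction —
deficiency and excess both score positive. The tryptophan term is
identically zero (its ratio to itself is 1 and $\beta_{Trp}=1$) but is kept
in the sum for fidelity to the printed formula; it has no numerical
consequence. Two properties follow directly and are enforced by tests:
the index is invariant to rescaling all intakes by a common factor (only
composition matters, so mg/day and mg/g protein give identical values),
and moving any single amino acid's intake monotonically away from its
proportional point strictly increases its score.

### The reference pattern

The default table (`hraap_default()`) uses the adult WHO/FAO/UNU (2007)
levels: His 15, Ile 30, Leu 59, Lys 45, Thr 23, Trp 6, Val 39 mg/g
protein. The report lists the combined sulphur requirement (22) with a
16/6 methionine/cysteine sub-division, which we adopt. It gives no split
for the combined aromatic requirement (38); we divide it evenly
(Phe 19 / Tyr 19). This split is an assumption: it affects the two
aromatic satisfaction terms but not the index's invariants, and any user
table in the same two-column format (`read_hraap()`) replaces it. Every
pipeline run records the pattern file hash so the pattern in force is
always reconstructable.

## From food records to intakes

Food-frequency questionnaire (FFQ) records are long-format rows
(subject, food, events/day, grams/event). Daily intake of nutrient $x$ is
$\sum_{\text{items}} \text{frequency} \times \text{portion} \times
c_x/100$ with $c_x$ the per-100 g content from a food-composition table.
Weekly and monthly frequency encodings are normalised by 7 and 30.44
(`frequency_per_day()`). The original Chinese Food Composition Table is
not redistributable; the package generates a clearly-labelled synthetic
composition table for testing (`simulate_ffq()`) and accepts any user
table in the declared schema.

Cohort inclusion mirrors the study design: age 20–74, energy 500–4500
kcal/day, diabetes-free at baseline, serum amino acids measured. The
filters are applied in that fixed order and each excluded subject is
counted once under the first criterion it fails, so the exclusion ledger
is deterministic and always sums, with the retained count, to the input
count. The ordering itself is a package choice — the design lists
criteria without an order — and changing it changes only the ledger
attribution, never the retained set.

## Association models

**Case definition.** Incident T2DM is self-reported diagnosis, treatment,
fasting glucose ≥ 7.0 mmol/L, or 2-h post-load glucose ≥ 11.1 mmol/L
(both thresholds inclusive). Missing components never qualify a subject;
a subject with all four components missing is indeterminate (`NA`).

**Tertile logistic models.** The index is split at its 33.3%/66.7% sample
quantiles (linear-interpolation quantiles, R type 7) with intervals closed
above, so a value tied with a cutpoint falls in the lower tertile — this
reproduces "< c₁ / c₁–c₂ / > c₂" style category labels. Logistic models
with the lowest tertile as reference are fitted over a nested covariate
ladder (demographics; + lifestyle/adiposity; + diet and overall diet
quality; + HOMA-IR and lipids). The exact ladder used in the source
cohorts is not printed; ours is a documented default and every result
names its covariates. Estimates are exponentiated coefficients — odds
ratios, labelled "RR" following common cohort usage — with Wald intervals.
The trend test refits with the ordinal tertile score (1, 2, 3) as a single
linear term; per-category medians are a possible alternative coding but
score coding is the dominant convention and is what the package uses.
Missing model variables cause listwise deletion with a logged count; no
imputation is attempted. A category with no cases (or no non-cases) is
non-estimable: it is reported as `NA` and its rows are excluded from the
factor fit rather than letting the coefficient diverge.

**Serum profile models.** For each of the 18 serum amino acids (and for
HbA1c) the exposure and the outcome are z-scored within the analysis
sample and the outcome is regressed on the standardized exposure plus the
model's unstandardized covariates; the reported β is the standardized
exposure coefficient. Raw p-values are reported with significance marks
at 0.05 and 0.01 and no multiplicity correction — deliberately mirroring
the convention of serum-panel reporting; readers who want family-wise
control should apply it downstream (`stats::p.adjust`).

**Single-mediator quartile models.** One serum amino acid at a time is
split at cohort-specific quartiles and modelled against incident T2DM
with quartile 1 as reference; the adjustment set deliberately includes
the index itself, so these estimate the serum association *conditional
on* diet.

## The mediation model

The mediation stage decomposes the covariate-adjusted index–diabetes
association into a direct path and indirect paths through serum valine,
glutamic acid and histidine, treated as *parallel* mediators (they enter
the outcome model jointly; no mediator→mediator paths):

* $a_j$: standardized exposure coefficient in a linear model of mediator
  $j$ on exposure + covariates;
* $b_j$ and the direct effect: standardized coefficients in the outcome
  model containing exposure and all mediators;
* total effect $\beta_{tot}$: the exposure coefficient in the outcome
  model without mediators;
* indirect effect $a_j b_j$; percent mediated
  $100\,a_j b_j/\beta_{tot}$, summed signed.

**Binary outcome scale.** A binary outcome has no natural SD for
standardization, so the default treats the fitted probit's latent index
as the outcome scale ("y*-standardization"): coefficients are divided by
$\sqrt{\operatorname{var}(X\hat\beta) + c}$ with $c = 1$ (probit) or
$\pi^2/3$ (logit). This mirrors the structural-equation convention for
categorical outcomes and has a useful property under the probit link with
normally distributed mediator residuals: marginalising the mediators out
of the outcome model yields another probit, so the population
decomposition $\beta_{tot} = \text{direct} + \sum a_j b_j$ holds exactly
and the generator's injected percent mediated is available in closed form
(`sim_ground_truth()`). Under the logit link the identity is approximate
(normal-to-logistic folding). With the `linear` link the outcome is
standardized by its sample SD and the decomposition identity is an exact
algebraic property of nested least-squares fits, which the tests assert
to 10⁻⁸.

**Signs.** Percentages are reported signed, and the total is the signed
sum. This matters for a protective mediator of a harmful exposure: the
index *lowers* serum histidine ($a<0$) and lower histidine *raises* risk
($b<0$), so the histidine indirect effect is a positive product and its
percentage adds to the total — the convention under which all published
per-mediator percentages are positive. Inconsistent (suppression)
mediation produces negative components and is flagged in output. When the
total effect is numerically zero the percentage is undefined and reported
`NA` with a warning rather than an unstable ratio.

**Uncertainty.** Percentile bootstrap (default 1000 case resamples,
2.5/97.5 quantiles) for every path, indirect effect and percentage,
deterministic given the spec's seed. Resamples in which the binary
outcome is all-case or all-non-case are dropped and counted, with a
warning above 10% dropped. `n_bootstrap = 1` is read as "no resampling"
and returns degenerate intervals at the point estimate. Near-collinear
mediators trigger a condition-number warning rather than an error.

## The synthetic cohort generator

No cohort data are deposited, so the generator is the test surface; it
produces data with the exact structure the analyses assume, plus the
ground truth they should recover.

* **Intakes**: $d_i = \text{protein}_g \times h_i \times e^{\epsilon_i}$,
  $\epsilon_i \sim N(0, \sigma_{dev}^2)$ i.i.d. per amino acid.
  `deviation_scale` $\sigma_{dev}$ (default 0.25) controls adherence;
  0 gives AACI ≡ 0, and the association stages then refuse the degenerate
  exposure (tested).
* **Covariates**: magnitudes emulating a middle-aged urban Chinese cohort
  — age N(48, 10) truncated 20–74, energy N(2300, 850) truncated
  500–4500 kcal/day, BMI N(25, 3.5), etc. These are emulation targets for
  testing, not estimates of any real cohort.
* **Serum**: on the standardized scale
  $\tilde M_j = \beta_j z(\mathrm{AACI}) + \sqrt{1-\beta_j^2}\,e_j$,
  rescaled to reference means/SDs in µmol/L, so each injected $\beta_j$
  *is* the population standardized slope. Default signs follow the six
  consistently associated amino acids (valine, isoleucine, glutamic acid,
  phenylalanine positive; glycine, histidine negative).
* **Outcome**: $P(\text{case}) = G(b_0 + \theta_d z(\mathrm{AACI}) +
  \sum_j \theta_j \tilde M_j)$ with $G$ logistic (default) or probit;
  intercepts are set so cumulative incidence lands near the 8–10% of the
  emulated cohorts. Fasting and 2-h glucose are then drawn from
  case/non-case conditional distributions that straddle the 7.0/11.1
  mmol/L thresholds, so re-running the case-ascertainment rule on the
  generated glucose reproduces the sampled flags exactly.
* **FFQ**: a 30-item, 13-group synthetic composition table whose items
  are pattern-proportional except rice, which is deliberately poor in
  lysine (×0.35) and threonine (×0.5); raising the rice share therefore
  raises the index on average, reproducing the qualitative food-group
  gradient the analyses look for.

One global seed drives everything; each stage draws from a
deterministically derived sub-stream, so stages can be regenerated
independently and a fixed seed yields a bit-identical dataset.

`calibrate_mediation_sim()` closes the loop: given a target total percent
mediated (e.g. 30%), it solves the closed-form calibration
$s = \frac{P/100\;\theta_d}{(1-P/100)\sum_j \beta_j u_j}$ for the mediator
effect scale under the probit link, so the injected truth is exact, not
approximate. `calibrate_total_effect()` does the same for a target
standardized total effect.

## Numerical choices

* Quantiles: type 7 everywhere (tertiles, quartiles, bootstrap
  percentiles); category intervals closed above.
* Degeneracy: a vector whose SD is below $10^{-12} + 10^{-10}|\bar x|$ is
  treated as constant, so an index that is zero only up to floating
  rounding still refuses tertile assignment and standardization.
* Logistic fits abort on non-convergence or quasi-complete separation
  (fitted probabilities pinned at 0/1, or |coefficient| > 15) with a
  diagnostic, rather than returning a silently unstable estimate.
* Mediation point estimates and bootstrap replicates share one code path
  on prebuilt design matrices (QR for the linear fits, `glm.fit` for the
  binary links); standard errors are only computed where reported.

## Problem sizes used in validation

The shipped validation uses sizes chosen to give stable Monte-Carlo
behaviour at desk scale: index invariants and the scalar-loop oracle on
1000 random profiles (agreement to 10⁻¹²); the hand-rolled IRLS
cross-check on a 200-row cohort (10⁻⁶); recovery of an injected 30% total
mediation on 200 cohorts of n = 2000 with 200 bootstrap resamples each
(the truth must fall inside the 95% interval in ≥ 90% of cohorts); and
null calibration of the trend test over 500 cohorts of n = 2000
(Kolmogorov–Smirnov test against uniformity). Larger single runs
(n = 20 000) verify point recovery of injected serum slopes, total
effects and percentages.

## What passing tests do and do not show

The generator draws amino-acid deviations independently across amino
acids, serum levels linearly in the index with Gaussian noise, and
mediators that are conditionally independent given the index. Real diets
have correlated amino-acid patterns (foods, not nutrients, are chosen),
serum–diet relations need not be linear, and unmeasured confounding is
absent by construction. Passing recovery tests therefore demonstrates
that the estimators are correct *for the model they assume* — they say
nothing about whether that model holds in any real cohort, and the
mediation decomposition remains an associational, not causal, statement
(no exposure–mediator interaction, no counterfactual identification).
Cox-type time-to-event modelling is deliberately out of scope: the
analyses use cumulative-incidence logistic models.
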