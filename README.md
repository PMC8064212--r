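# aaci — the dietary Amino Acid Composition Index and its cohort analyses

`aaci` scores how closely a diet's essential-amino-acid composition
adheres to the WHO/FAO/UNU human requirement amino acid pattern (HRAAP),
and implements the full epidemiological analysis built on that score:
derivation of amino-acid intakes from food-frequency questionnaires,
tertile logistic models for incident type 2 diabetes with trend tests,
standardized linear models for the index against 18 serum amino acids,
and a parallel three-mediator decomposition (serum valine, glutamic acid,
histidine) with bootstrap confidence intervals. Because cohort data of
this kind are rarely shareable, a synthetic-cohort generator with known
ground truth is a first-class component: every stage of the pipeline can
be validated end to end without any real data.

It is written for nutritional epidemiologists and biostatisticians:
every user-facing function takes a data frame and returns a tibble, so
the stages chain with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## The index

Eleven amino acids are scored (Ile, Leu, Lys, Met, Phe, Thr, Trp, Val,
His, Cys, Tyr), with tryptophan as the ratio denominator. Given
requirement levels *h<sub>i</sub>* and daily intakes *d<sub>i</sub>*:

```
beta_i = h_i / h_Trp
q_i    = | (d_i / d_Trp) / beta_i  -  1 |
AACI   = sum_{i=1..11} q_i
```

AACI = 0 means the dietary composition is exactly proportional to the
requirement pattern; higher is worse adherence (deficiency and excess
both count). Only composition matters — the index is invariant to
rescaling all intakes — so any consistent intake unit works.

## Worked example

A diet exactly proportional to the default adult pattern scores zero:

```r
library(aaci)
intake <- tibble::tibble(
  subject_id = "good_diet", ile = 2100, leu = 4130, lys = 3150, met = 1120,
  phe = 1330, thr = 1610, trp = 420, val = 2730, his = 1050, cys = 420,
  tyr = 1330
)
compute_aaci(intake)
#> # A tibble: 1 x 13
#>   subject_id q_ile q_leu q_lys q_met q_phe q_thr q_trp q_val q_his q_cys q_tyr
#>   <chr>      <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 good_diet      0     0     0     0     0     0     0     0     0     0     0
#> # i 1 more variable: aaci <dbl>
```

(Each intake is 70 g protein × the pattern level in mg/g, so every
satisfaction score `q_i` is 0 and their sum `aaci` is 0.)

On a simulated cohort with a positive diet–diabetes effect and three
serum mediators, the association and mediation stages recover the
injected structure:

```r
sim <- simulate_cohort(sim_config(n = 4000, seed = 2024))
co  <- sim$cohort

fit_tertile_logistic(co, models = c("model1", "model3"))
#> <association of tertile with t2dm>
#> # A tibble: 6 x 10
#>   model  category     n cases estimate conf_low conf_high   p_value reference
#>   <chr>  <chr>    <int> <int>    <dbl>    <dbl>     <dbl>     <dbl> <lgl>
#> 1 model1 T1        1334    71     1      NA         NA    NA        TRUE
#> 2 model1 T2        1333    88     1.26    0.915      1.74  0.156    FALSE
#> 3 model1 T3        1333   115     1.68    1.23       2.28  0.000931 FALSE
#> 4 model3 T1        1334    71     1      NA         NA    NA        TRUE
#> 5 model3 T2        1333    88     1.27    0.922      1.76  0.142    FALSE
#> 6 model3 T3        1333   115     1.70    1.25       2.31  0.000707 FALSE
#> p for trend: model1 = 0.0008098, model3 = 0.0006125
```

Subjects in the worst-adherence tertile (T3) have ~1.7 times the odds of
incident diabetes relative to the best tertile, with a significant
monotone trend; the estimate barely moves when dietary covariates are
added (model3), as designed into the generator.

```r
mediate_aaci(co, mediation_spec(covariates = model_ladder()$model3,
                                n_bootstrap = 500, seed = 7))
#> Parallel mediation: aaci -> {serum_valine, serum_glutamic_acid, serum_histidine} -> t2dm (probit link, n = 4000)
#>   total effect    0.148   direct   0.110   indirect   0.039
#>   aaci -(a=0.140)-> serum_valine -(b=0.143)-> t2dm : indirect 0.020 (13.6% mediated)
#>   aaci -(a=0.116)-> serum_glutamic_acid -(b=0.138)-> t2dm : indirect 0.016 (10.8% mediated)
#>   aaci -(a=-0.082)-> serum_histidine -(b=-0.034)-> t2dm : indirect 0.003 (1.9% mediated)
#>   total percent mediated: 26.3% [16.8, 45.1] (500 bootstrap replicates)
```

Note the histidine row: the index *lowers* serum histidine (a < 0) and
lower histidine raises risk (b < 0), so its indirect effect is a positive
product — the signed-product convention described in the methods
vignette.

The full pipeline (score → inclusion filters → associations → mediation,
with CSV/JSON outputs and a provenance manifest) runs from a single
configuration list or YAML file via `run_pipeline()`; synthetic FFQ data
come from `simulate_ffq()`.

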