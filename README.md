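# brmcda

Quantitative benefit–risk (B-R) assessment for two-arm time-to-first-event
trials, written for biostatisticians and regulatory scientists who need to
put heterogeneous efficacy and safety endpoints on one scale.

The motivating setting is antithrombotic therapy after peripheral arterial
revascularization — rivaroxaban plus aspirin versus aspirin alone — where
ischemic events prevented must be weighed against major bleeding caused.
The package implements the full workflow:

* **Unweighted B-R**: exposure-adjusted incidence-rate differences per
  10 000 patient-years with Wald 95% CIs
  (SE = 10⁴·√(d_a/PY_a² + d_c/PY_c²)), NNT/NNH, and forest-style tables,
  under intention-to-treat and on-treatment data scopes.
* **Weighted B-R (MCDA)**: a linear additive multi-criteria decision
  analysis with health state utility values as weights,

  &nbsp;&nbsp;ΔS = Σᵢ wᵢ·Δrᵢ, &nbsp; wᵢ = 1 − uᵢ,

  so the balance reads in *utility death equivalents per 10 000
  patient-years* (negative favours the active arm).
* **Monte Carlo uncertainty**: rate and weight distributions propagated
  into the ΔS distribution, its percentile CI, and the probability that
  benefits outweigh risks, P(ΔS < 0).
* **Sensitivity and time**: one-way ±2 SD weight (tornado) analysis, and a
  temporal B-R trajectory on a 3-month Kaplan–Meier grid with Greenwood-
  based uncertainty bands (at-risk-restricted KM difference curves
  included).
* **Synthetic trial generator**: a calibrated two-arm exponential-hazard
  simulator (enrollment staggering, discontinuation, fatal-event routing)
  so the whole pipeline is testable end to end without any trial data.

The published aggregate inputs of the motivating trial ship as
`voyager_table1()` (per-arm rates, rate differences with CIs, mean
weights), so the headline analysis reproduces at desk scale.

## Worked example

```r
library(brmcda)

rd  <- aggregate_rate_table(voyager_table1())
fit <- br_mcda(rd, voyager_weights(), model = 1, tree = voyager_value_tree())
summary(fit)
```

```
Utility-weighted MCDA benefit-risk (model 1)

               endpoint  delta weight contribution
        fatal_composite   36.5   1.00         36.5
    nonfatal_amputation  -21.9   0.59        -12.9
     nonfatal_ich_bleed    2.5   0.42          1.0
           nonfatal_ali -100.3   0.36        -36.1
        nonfatal_stroke  -14.1   0.35         -4.9
            nonfatal_mi  -13.3   0.22         -2.9
 nonfatal_non_ich_bleed   25.7   0.22          5.7

Score difference: -13.7 utility death equivalents per 10 000 patient-years
Per-arm scores: active 488.4, control 502.1
(negative favours the active arm)
```

Each contribution is `weight × rate difference`: acute limb ischemia
prevented (−36.1 death equivalents) is the dominant benefit, the fatal
composite (+36.5) the dominant risk, and the net −13.7 means the active
arm saves the utility equivalent of 13.7 deaths per 10 000 patient-years.
Uncertainty propagation:

```r
mc <- run_monte_carlo(rd, voyager_weights(), model = 1,
                      tree = voyager_value_tree(),
                      config = mc_config(n_runs = 1e6, seed = 1))
mc
```

```
Monte Carlo MCDA score difference (1 000 000 runs)
  mean -13.7 (95% CI -77 to 47.7)
  P(benefits outweigh risks) = 66.4%
```

With weights fixed at their means the closed form Φ(−μ/σ) gives 67.8%;
propagating beta-distributed weight uncertainty (utility SD 0.10) lowers it
to ~66.4%, bracketing the published 64.4%. The tornado
(`one_way_sensitivity()`) shows the result is most sensitive to the acute
limb ischemia weight, whose bar (width 40.1) dwarfs all others.

Patient-level workflows start from the simulator instead:

```r
trial  <- simulate_trial(voyager_sim_config(seed = 7))
bundle <- run_pipeline(trial, scope = scope_config("on_treatment"))
plot(bundle, "temporal")
```

A thin command-line driver with `simulate`/`rates`/`mcda`/`mc`/
`sensitivity`/`temporal`/`all` subcommands lives at
`inst/scripts/br-analysis.R`.

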