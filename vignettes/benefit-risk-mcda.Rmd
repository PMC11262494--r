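---
title: "Utility-weighted benefit-risk analysis: models and methods"
author: "brmcda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility-weighted benefit-risk analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brmcda)
```

## The problem

Randomized trials of antithrombotic therapy trade ischemic events prevented
against bleeding events caused, and the endpoints involved differ enormously
in clinical weight: a cardiovascular death is not exchangeable with a
nonfatal bleed. `brmcda` implements a quantitative benefit-risk (B-R)
workflow for two-arm time-to-first-event trials built around two ideas:

1. **Unweighted**: express every endpoint as a between-arm incidence-rate
   difference per 10 000 patient-years, so benefits and risks are counts of
   patients affected in a common hypothetical population, displayed as a
   forest table with number needed to treat/harm.
2. **Weighted**: score the endpoints together in a linear additive
   multi-criteria decision analysis (MCDA) with health state utility values
   (HSUVs) as weights, yielding a single balance in *utility death
   equivalents per 10 000 patient-years*.

The shipped worked example is the peripheral-artery-disease anticoagulation
trial whose published aggregate inputs are bundled as `voyager_table1()`:
about 6 500 patients randomized 1:1 to rivaroxaban 2.5 mg twice daily plus
aspirin versus aspirin alone after lower-extremity revascularization.

## The value tree and double counting

Endpoints form a value tree (`voyager_value_tree()`): ischemic benefits
(acute limb ischemia, major vascular amputation, myocardial infarction,
ischemic stroke) against bleeding risks (intracranial and non-intracranial
major bleeding), with fatal events collected in a single fatal endpoint so
deaths are never counted twice. Model 1 uses a composite of cardiovascular
death and fatal major bleeding; model 2 replaces it with all-cause death and
is otherwise identical — the two fits differ only through that substitution,
which is tested structurally. All endpoints are time-to-first-event and are
analyzed *marginally*: a patient can contribute a nonfatal stroke and,
later, a fatal event; a fatal occurrence is attributed only to the fatal
endpoint; death truncates all further observation.

## Analysis scopes

Two data scopes reproduce the usual populations of an event-driven trial.
The *ITT* scope keeps all randomized patients with follow-up to the
administrative cutoff. The *on-treatment* scope keeps treated patients and
censors at the last study-drug dose plus a washout window. The window
defaults to 2 days; an event exactly at `last_dose + 2` is **included**
(closed interval) — the convention had to be fixed one way and the closed
choice keeps the on-treatment event set a superset of any open-interval
variant. Structural invariants (on-treatment exposure and events are strict
subsets of ITT on data with discontinuation) are part of the test suite.

## Rates, Wald intervals, NNT/NNH

For endpoint $i$ and arm $a$, with $d$ first events over $PY$ patient-years
(exact days at 365.25 days/year), the rate is $10^4 \, d/PY$. The rate
difference $\Delta r = r_{\text{active}} - r_{\text{control}}$ gets a
normal-approximation (Wald) interval with the Poisson variance of each
rate:

$$\mathrm{SE} = 10^4\sqrt{d_a/PY_a^2 + d_c/PY_c^2}, \qquad
  \Delta r \pm 1.96\,\mathrm{SE}.$$

The literature names several Wald variants for rate differences without
always printing formulas; the package uses the plain Poisson-variance form
above and bounds its adequacy two ways: a parametric-bootstrap oracle
(Poisson resampling of the counts) reproduces the interval to within 2% of
its width at moderate counts, and simulated coverage at expected counts of
40 vs 30 per arm is 94.9% (93–97% asserted over 2 000 replicates in the
suite). NNT/NNH is $10^4/|\Delta r|$ patient-years per event prevented or
caused; a zero difference is flagged undefined rather than raised as an
error.

## Kaplan-Meier machinery

`km_curve()` delegates the product-limit estimate and Greenwood variance to
`survival::survfit()` with the standard simultaneous-death tie convention;
tests check it against an independent hand-enumerated product-limit
computation and the no-censoring ECDF identity at $10^{-10}$.
`km_difference_curve()` subtracts cumulative incidences on the merged event
grid and truncates where either arm's at-risk fraction falls below a floor
(default 10%, after Pocock's plotting recommendation); the floor is exact —
truncation happens at the last merged-grid time at which both arms still
hold the floor.

## The MCDA model

A health state utility $u \in [0,1]$ (1 = perfect health, 0 = death) turns
into a weight $w = 1 - u$, so one weighted event is worth $w$ deaths. The
score difference is the linear additive form

$$\Delta S = \sum_i w_i \, \Delta r_i,$$

with no range normalization and no interaction terms — deliberately the
simplest MCDA variant, which is what makes the "utility death equivalents"
reading exact. Published mean weights for the worked example: 1.00 (fatal
composite), 0.59 (amputation), 0.42 (intracranial bleed), 0.36 (acute limb
ischemia), 0.35 (ischemic stroke), 0.22 (myocardial infarction), 0.22
(non-intracranial bleed). Weights are carried at full precision; one-decimal
display is formatting only. Feeding the printed ITT rate differences through
the model gives $\Delta S = -13.69 \approx -13.7$: the utility equivalent of
13.7 fewer deaths per 10 000 patient-years with the active treatment.

A wrinkle worth knowing: the published per-arm rates are themselves rounded
to one decimal, so the recomputed differences can disagree with the printed
difference column by up to 0.1 (they do, for amputation). The printed
difference column is treated as the model input; the exact identity
$\Delta S = S_{\text{active}} - S_{\text{control}}$ is asserted on
self-consistent (derived-delta or patient-level) tables.

## Monte Carlo uncertainty

`run_monte_carlo()` redraws every rate difference and every weight
independently per run and recomputes $\Delta S$; the probability that
benefits outweigh risks is $P(\Delta S < 0)$, read off the empirical CDF at
zero, and the 95% interval is the 2.5th/97.5th percentile pair. Two rate
models cover the two input paths:

* `gamma-by-counts` (patient-level): per-arm rates drawn from
  $\mathrm{Gamma}(d, PY) \times 10^4$, the conjugate model for a Poisson
  count over fixed exposure. A zero count uses shape $d + 0.5$ — a
  Jeffreys-style fallback that keeps the distribution proper instead of a
  point mass at zero.
* `normal-by-ci` (aggregate): Gaussian draws centred on the printed
  difference with SD = CI width / 3.92. This is the only path available
  from a published table and is what the desk-scale reproduction uses.

Weight families: beta (moment-matched to mean and SD; infeasible moment
pairs are a configuration error), truncated normal on $[0,1]$ via inverse
CDF, or fixed. Endpoints and arms are treated as independent throughout,
matching the additive model's own assumption; a correlation structure is a
documented extension point, not implemented.

The published analysis used 5 000 000 runs; the package default is
$10^6$, which puts the binomial SE of the probability below 0.0005 and runs
in seconds — the figures quoted anywhere by this package were computed at
that size. Percentile rather than normal-theory intervals are reported
because the simulated distribution is the object of interest (its CDF *is*
the decision output). The empirical CDF is evaluated left-continuously
($P(\Delta S < t)$) so its value at 0 equals the net-benefit probability
exactly, with no tie ambiguity.

### What the desk reproduction can and cannot pin down

With fixed weights the score difference is exactly Gaussian, so
$P(\Delta S < 0) = \Phi(-\mu/\sigma)$ is a closed-form oracle: with the
published inputs it gives 67.8%, and the Monte Carlo agrees within binomial
noise. The published 64.4% additionally propagates weight uncertainty,
whose supplementary SDs are not in the available text. The package default
— utility SD 0.10 with a beta family for every nonfatal endpoint, a typical
between-study dispersion for literature-extracted HSUVs, chosen once and
documented here — yields about 66.4%. Widening weight SDs can only flatten
the CDF toward 50%, never sharpen it, which the suite asserts as a
monotonicity property. The on-treatment headline numbers (−68.1, 98.7%)
need per-endpoint on-treatment rates that were never printed; they are
covered by structural scope tests on synthetic data, not by numeric
reproduction.

## Sensitivity and the temporal trajectory

One-way weight sensitivity moves each nonfatal endpoint's weight to its
mean ± 2 SD (clamped to $[0,1]$) holding the rest fixed; by linearity the
pre-clamp bar half-width is exactly $2\,\mathrm{SD}_j\,|\Delta r_j|$, which
doubles as a $10^{-12}$-level test of the implementation. The fatal
endpoint is never varied — its weight is 1 by construction. With the
published inputs the acute-limb-ischemia bar dominates: it carries the
largest nonfatal rate difference.

The temporal view replaces constant rates with Kaplan-Meier cumulative
incidences on a 3-month grid (days 90–1100 by default, configurable):
$\Delta S(t) = 10^4 \sum_i w_i (F_{a,i}(t) - F_{c,i}(t))$, in utility death
equivalents *per 10 000 patients by time t* — a per-population scale,
deliberately distinct from the per-patient-year scale of the rate-based
score. No band construction was specified for this display in the source
analysis, so the package labels its choice: Monte Carlo over Gaussian
perturbations of each cumulative incidence with its Greenwood SE plus the
weight distributions (default), or cheaper fixed-weight normal-theory
bands, selected by `band=` and recorded in the result's attribute.

## The synthetic trial generator

`voyager_sim_config()` encodes the study conditions the analysis assumes:
3 286 vs 3 278 patients, constant per-endpoint hazards equal to the
published per-arm rates (events per patient-year), permanent
discontinuation at 0.14/patient-year (about 13.1% by one year, matching
$1 - e^{-0.14}$), uniform enrollment over 2 years with an administrative
cutoff at 3.583 years. The last two numbers follow from the published
median follow-up of ~31 months with a 12-month IQR: uniform entry over
$E$ years with cutoff $T$ gives median follow-up $T - E/2$ and IQR $E/2$,
so $E = 2$, $T = 2.583 + 1$. Event times are exponential and independent
across endpoints except that a fatal event truncates all observation —
the same independence assumption the MCDA itself makes. Per-endpoint fatal
fractions are free parameters defaulting to zero because the published
rates are already post-routing (the fatal composite is simulated directly
at its own rate); a nonzero fraction re-labels drawn occurrences to the
fatal composite, implementing the double-counting rule at the data level.
One L'Ecuyer-CMRG substream per patient index makes the generator
bit-reproducible and lets an arm grow without perturbing existing patients.

What the generator does *not* emulate: covariates (age, clopidogrel use),
non-proportional hazards, recurrent events, and correlated endpoint risks.
Passing tests on synthetic data therefore demonstrate the estimators'
correctness under the stated model, not robustness to real-data violations
of it. The generator simulates the model-1 endpoint list; model-2
(all-cause death) behaviour is exercised on aggregate tables.

## Numerical and design choices, in brief

* Exposure accounting at exact days / 365.25; rates invariant to the unit
  chosen given consistent accounting.
* Display rounding (one decimal on the per-10 000 scale) only in rendered
  tables and CSVs; stored JSON results are full precision and
  byte-identical across runs at a fixed seed (timestamps excluded).
* Problem sizes used by the shipped checks: $10^6$ Monte Carlo runs for
  probability statements, 2 000 replicate trials for Wald coverage,
  10 000 patients/arm for simulator rate recovery — sizes at which the
  relevant standard errors are comfortably below the asserted bands.
* `br_mcda()` returns a classed fit with `print`, `summary`, `coef`
  (contributions), `confint` (Monte Carlo percentile) and `simulate`
  (score-difference draws) methods; `predict`/`residuals` have no meaning
  for a weighted sum of aggregate differences and are deliberately absent.

## Known limitations

The additive, independence-assuming MCDA inherits the standard caveats:
HSUVs gathered from heterogeneous literature are applied to a mix of acute
and chronic states without time integration (no quality-adjusted life-year
accumulation); linear value functions are unconstrained over the endpoint
ranges; and hazard ratios, covariate adjustment and competing-risk
estimands are out of scope. These choices mirror the source analysis; the
package makes them explicit and testable rather than attempting to improve
on them.
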