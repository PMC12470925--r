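---
title: "Potential-outcome mediation for stratified count data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-outcome mediation for stratified count data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomediate)
```

## The problem

Black infants in the United States die before their first birthday at about
twice the rate of all other infants combined. Much of that gap travels
through birth outcomes: Black infants are far more likely to be born very
small and very early, and those strata carry mortality risks up to two
orders of magnitude above a normal-weight term birth. `pomediate`
quantifies how much of the disparity a hypothetical intervention on the
mediators would remove, treating the two mediators — birthweight category
and length-of-gestation category — as a single interaction node with up to
5 × 5 levels, rather than forcing them into separate single-mediator
pathways.

## Model and assumptions

Within each stratum (race × birthweight category × gestation category) the
death count is binomial with a stratum-specific rate, the *potential
outcome* (PO): the death probability shared by every infant with that
covariate vector. Each PO carries a `beta(a, b)` prior, by default
`beta(1, 10)`: weakly informative toward small probabilities, appropriate
for an outcome whose population rate is a few per thousand. Because the
model is conjugate and strata are independent, every posterior is
`Beta(a + r, b + n − r)` exactly.

Three assumptions give the estimates their causal reading: consistency
(well-defined mediator categories, independent of how they came about),
positivity in the observed strata, and no unmeasured confounding of the
race–outcome relationship beyond the stratification. Structurally absent
mediator combinations (macrosomic extremely/very preterm births) are
reported as not observed rather than estimated; their posterior would be
the prior and would say nothing.

### Exact sampling instead of MCMC

All posterior quantities are computed from independent draws of the
closed-form conjugate posteriors. A Markov-chain sampler for this model
would have each stratum's full conditional equal to that same beta
distribution — the conjugate posterior *is* the chain's stationary law — so
direct sampling is exact, needs no burn-in or convergence monitoring, and
is cheap enough that 10,000 draws (the package default) complete in
milliseconds. Summaries are the median and the 2.5th/97.5th percentiles
(the 95% credibility interval), computed by linear interpolation between
order statistics; any standard percentile definition differs by
`O(1/n_draws)`, far below reporting precision. Closed-form quantiles
(`posterior_quantile()`) serve as the analytic oracle the Monte-Carlo
summaries are tested against.

## The mediation calculus

All derived quantities live on one drawwise-aligned sample: a run draws the
race-marginal POs (hence the total effect `TE`), the reference-stratum POs,
and propagates every ratio and difference per draw, so identities such as
`PA = 100(TE − CDE)/TE` hold exactly, draw by draw.

A *control strategy* names targeted strata and the reference rate they are
hypothetically moved to. For each targeted stratum, the counterfactual
stratum death count is births times the reference PO draw (`s.r`, kept
real-valued: it is an expectation, and rounding would bias small strata);
subtracting each stratum's excess from the race totals gives the
counterfactual population count `p.r`, the counterfactual marginal rate
`new.PO`, the controlled direct effect `CDE` (Black minus non-Black), and
the percentage attributable `PA`.

Two reference rules are exposed because the single-mediator strategies are
genuinely ambiguous: `joint_normal` moves every targeted stratum to the
jointly-normal cell, while `match_other_mediator` normalizes only the
intervened mediator, keeping the other mediator's level fixed. The package
defaults to `match_other_mediator` for single-mediator targets — it is the
minimal intervention consistent with "set birthweight to normal" — and to
`joint_normal` everywhere else; the joint strategy under either scheme is
identical (and the binary "both mediators" strategy reproduces, draw for
draw, the five-level strategy that targets all 24 non-reference strata,
when both tables aggregate the same records).

When only a published worked example is available — stratum counts, race
totals and the *printed* counterfactual stratum medians, but no
reference-stratum counts — `mediate_control(s_r_fixed = ...)` propagates
the printed values through the same pipeline. Race totals may likewise be
supplied directly to `strata_counts()` when only a subset of strata is
tabulated; the missing strata then contribute through the totals alone.

### When PA is interpretable

`PA` divides by the total effect. If the population has no disparity, `TE`
draws are centred at zero and `PA` becomes the ratio of two independent
near-zero quantities: its posterior median sits near 100 (the median of
`1 − CDE/TE` when `CDE/TE` is a symmetric ratio centred at zero) and its
interval spans tens to hundreds of percentage points. This is not a defect
of the sampler — the estimand itself is undefined at `TE = 0` — but it
means `PA` should only be read when the total-effect interval is bounded
away from zero. The test suite asserts exactly this behaviour: null
populations give null `TE` and `CDE` and an attribution interval too wide
to be informative.

### What the attribution interval covers

The propagation treats the observed stratum deaths and births as known
constants — the intended use is a census-scale vital-statistics file, where
the population counts are themselves the estimand and the only uncertainty
is in the rates. Consequently the `PA` interval is a *finite-population*
interval. In the package's recovery experiment (100 replicate cohorts of
10^6 births from the default generator), the 95% intervals cover the
generating (superpopulation) stratum mortalities at 0.957 and the
generating total effect at 0.95, but the superpopulation attributable
percentage at only about 0.83: the interval carries no stratum-count
sampling noise, and that shortfall is scale-invariant because both noise
sources shrink at the same root-n rate. Against the finite-cohort
attributable percentage — the same propagation evaluated at the realized
counts with the true reference rate — coverage is essentially complete.
`recovery_experiment()` reports both, and analyses of subsampled (rather
than census) data should read the `PA` interval as conditional on the
observed strata.

## Descriptive companions

For each stratum the 5×5 table also reports the incidence relative risk —
the Black/non-Black ratio of stratum-membership probabilities, each given
an independent Jeffreys `beta(1/2, 1/2)` posterior on (stratum births, race
total births), a deliberately light model whose median matches the plug-in
ratio at reporting precision — and the conditional mortality rate ratio,
the drawwise ratio of the stratum's PO draws. Strata observed for only one
race keep their estimates but are flagged: the missing race's posterior is
prior-dominated and the ratio interval unstable.

## Prior sensitivity

`compare_priors()` repeats the full 5×5 run under two priors with the same
seed and draw count, so differences reflect the prior alone. The default
comparison is `beta(1, 10)` against the flat `beta(1, 1)` (the uniform
prior, represented as a beta so one code path serves both). Cells whose PO
median moves by more than half a unit in the third decimal (configurable)
are flagged; with realistic cohort sizes only the sparse cells move — a
zero-event cell of 14 births has median 0.028 under `beta(1, 10)` versus
0.045 under the flat prior, while a cell with tens of thousands of events
shifts by less than `5e-4` — and the attributable percentages are robust
because they depend on the reference-cell and marginal POs, which are
data-dominated.

## The synthetic cohort generator

`default_spec()` encodes a two-race singleton-birth population at published
U.S. magnitudes, chosen once as the package's standing test-bed: the Black
group carries 10% of births; non-Black stratum incidence is set at
realistic scale (the extreme stratum at 3.8 per 1,000, the jointly-normal
cell holding ≥ 0.78 of mass) with Black incidence equal to non-Black times
each stratum's published incidence ratio (2.75 for the extreme stratum);
per-stratum mortality spans 0.0017–0.0028 in the jointly-normal cell to
0.41–0.42 in the extreme one; macrosomic extremely/very preterm strata are
structural zeros. The implied closed-form marginals are 0.0090 (Black) and
0.0045 (non-Black): a total effect of 0.0044 and relative risk 1.98, and an
analytic attributable percentage of 61.0 for controlling the extreme
stratum — the magnitudes of the motivating cohort.

Generation follows the model exactly: a multinomial allocation of births
over strata, then independent binomial deaths per stratum.
`generate_records()` expands counts to one row per birth, with grams and
weeks uniform within each category's interval — categorization is the only
consumer of the within-cell values, so their law is irrelevant downstream —
and guarantees that classify-then-aggregate reproduces the generated counts
bit for bit. Optional missingness blanks fields for the missing-data
filter's tests. The generator deliberately omits what the model omits:
family clustering (mothers with several births over the window), covariate
structure (maternal age, plurality, geography), and temporal trend. Passing
recovery tests therefore certify the estimation pipeline under the model's
own assumptions, not robustness to their violation — with real data,
within-family correlation would make the intervals slightly narrow.

Ground truths (`true_marginal_rates()`, `true_total_effect()`,
`true_percent_attributable()`) are closed-form mixture arithmetic on the
generating parameters, computed by routines independent of the estimation
code, so recovery experiments are free of circularity.

## Numerical and edge-case choices

- Category boundaries follow the clinical convention: birthweight bins
  `[0,1000)`, `[1000,1500)`, `[1500,2500)`, `[2500,4000]`, `(4000,∞)`
  grams — 4000 g exactly is normal weight — and completed-week bins `<28`,
  `28–31`, `32–36`, `37–41`, `≥42`, so 41 completed weeks is term.
- Records missing both mediators are counted once, under birthweight, in
  the drop log (deterministic reporting); missing or nonpositive values
  are unclassifiable and excluded before aggregation.
- Targeting a stratum with zero births is a no-op (`s.r ≡ 0`), and the
  reference stratum cannot be its own control target.
- Draws with `TE = 0` (impossible at realistic scales, possible in toy
  data) are excluded from `PA` with a warning.
- One seed governs a whole run; the draw order is fixed and documented, so
  identical configurations give byte-identical reports.
- Human-readable CSV reports round probabilities to 4 decimals and
  percentages to 1; the JSON results keep full precision.

## Problem sizes

The test suite runs at sizes chosen to keep Monte-Carlo error well below
the tolerances it asserts: 10^4 draws for reproduction checks against
printed three-to-four-decimal values, 10^5 draws (against 10^6-draw
independent brute-force sampling) for the dual-route attribution check,
and 100 replicate cohorts of 10^6 births for coverage. The acceptance
script uses 10^4 draws throughout, matching the default reporting
precision.

## Known limitations

- The attribution interval is finite-population (see above); it does not
  include stratum-count sampling noise.
- Single-mediator control strategies depend on the reference rule; both
  variants are reported rather than adjudicated.
- Sparse strata are prior-sensitive; the sensitivity report flags them,
  and unobserved strata are reported as unobserved rather than imputed.
- No adjustment beyond stratification: confounding by unmodelled factors
  (social determinants, family structure) is out of scope, as is any
  natural direct/indirect decomposition — the controlled-direct-effect
  framing asks "what if these strata had the reference rate", not "how
  much flows through the mediator".
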