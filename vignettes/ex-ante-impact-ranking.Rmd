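---
title: "Ex-ante multi-criteria impact assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ex-ante multi-criteria impact assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exanterank)
```

## The problem

Research programs that breed improved staple-crop varieties for stressed
environments (drought-prone drylands, low-fertility soils) must choose
among dozens of candidate technologies years before any is released.
`exanterank` implements a three-criterion ex-ante assessment — economic
returns, poverty reduction, and child nutrition — and combines the
criteria into a single ranking with TOPSIS, weighting each criterion by
how much it matters in the target region.

## The economic-surplus model

Adoption of a technology shifts the supply curve of the target crop. We
use the closed-economy, linear-curve, parallel-shift economic-surplus
model that is standard in ex-ante assessment of agricultural research.
For country $n$ in year $t$ the per-unit (relative) supply shift is

$$K_{t,n} = \left(\frac{g}{\varepsilon_n} - \frac{c}{1+g}\right)
  \, p \, A_t, \qquad K_{t,n} \ge 0,$$

where $g$ is the proportional yield gain, $c$ the proportional change in
per-hectare production cost (negative for savings; the $1+g$ denominator
converts it to a per-unit-of-output change), $\varepsilon_n$ the supply
elasticity, $p$ the probability of research success and $A_t$ the adopted
acreage share. The clamp at zero encodes that a technology is only
offered where it does not shift supply backwards. The surplus change is

$$\Delta ES_t = \sum_n K_{t,n} P_{0n} Q_{0n}
  \left(1 + \tfrac12 K_{t,n} Z_n\right), \qquad
  Z_n = \frac{\varepsilon_n}{\varepsilon_n + \eta_n},$$

with $P_{0n}$, $Q_{0n}$ the baseline producer price and quantity and
$\eta_n$ the absolute demand elasticity. This functional form is a
declared design choice: the assessment literature this package follows
defers the surplus computation to a standard model rather than printing
one, and the closed-economy parallel-shift form is the canonical choice
with the fewest free assumptions. Open-economy and price-transmission
extensions are out of scope.

**Adoption curve.** Only the ceiling and the years-to-ceiling are
elicited from experts, so the curve shape is open. The default is a
linear ramp from release to the ceiling, the simplest monotone shape
consistent with "maximum adoption reached after $N$ years"; a logistic
alternative (rescaled to hit the same endpoints exactly) is available via
`shape = "logistic"` in `build_adoption_path()`. Adoption is zero before
release (`release_lag` years after research starts).

**Costs.** $C_t$ has two elicited components: the annual research cost
for the stated number of research years, and dissemination at a cost per
adopted hectare, i.e. `dissemination_cost_per_ha × A_t × area` each year.
Whether dissemination is per-hectare-recurring or lump-sum is not
determined by the source material; the recurring per-adopted-hectare
reading is declared here and is configurable through the profile
parameters (set the per-ha cost to zero and fold lump sums into the
research stream if preferred).

**Discounting.** The benefit-cost ratio discounts both streams over
years $t = 1..T$ at $r = 10\%$ (configurable), horizon $T = 25$ years
(configurable). Both defaults are the study conditions, not tuning
knobs.

## Poverty

$$\Delta P = \frac{\Delta ES_T}{AgGDP}\;
  \frac{\Delta P / P}{\Delta Y / Y}\; P$$

evaluated at $T$ = the year maximum adoption is reached
(`release_lag + years_to_max`), per country, summed over the
environment. The surplus share of agricultural GDP and the poverty
elasticity are both per-unit quantities; writing the share in percent
with a per-percent elasticity gives the identical product, so the
formula is implemented as the plain fraction product. Negative $\Delta
P$ means poverty is reduced; the ranking criterion is $-\Delta P$
(people lifted out of poverty) so that larger is better.

## Child malnutrition

The share of malnourished children under five evolves as

$$PMC_t = PMC_{t-1}
  + e_{kcal}\,\log\!\frac{PcKcal_t}{PcKcal_{t-1}}
  + c_{lfexp}\,\Delta LfExp_t + c_{schl}\,\Delta Schl_t
  + c_{water}\,\Delta Water_t,$$

with $e_{kcal} = -25.24$ (elasticity w.r.t. per-capita kilocalorie
availability), $c_{lfexp} = -71.755094$ (female/male life-expectancy
ratio), $c_{schl} = -0.219831$ (percent female secondary enrollment).
No published value exists for the safe-water coefficient: it defaults to
0 and the constructor warns unless a value is supplied explicitly —
inventing a coefficient would be worse than omitting the channel. The
share is clamped to $[0, 100]$ since it is a percentage; counts are
$MC_t = PopC_t \cdot PMC_t / 100$.

The full global partial-equilibrium machinery that originally drives
$PcKcal_t$ (endogenous prices, trade, exogenous productivity trends) is
replaced by a transparent linkage: extra production
$g \, p \, A_t \, Q_0$ is converted at a crop energy content
(default $3.5 \times 10^6$ kcal/tonne, a typical dry-grain value for
cereals and grain legumes) and spread over the population and the year,

$$PcKcal^{scen}_t = PcKcal^{base}_t +
  \frac{\Delta Q_t \cdot kcal/t}{population \cdot 365}.$$

This is declared plumbing, not a reconstruction of the original model;
covariates other than calories are held at baseline in the technology
scenario, and the baseline itself is time-constant (mirroring the
constant-climate assumption of the study conditions). The criterion is
$MC^{scen}(T) - MC^{base}(T)$, negative when the technology improves
nutrition.

**Pre-path reference.** The recursion needs a year-0 state. `pmc0` is
user-supplied; the year-0 calorie level `pckcal0` defaults to the
path's first-year value (making the first increment zero) but scenario
paths constructed by `nutrition_outcome()` share the *baseline's*
reference, so calories added in year 1 already count. With a shared
reference and no binding clamp the calorie terms telescope,
$PMC_t = PMC_0 + e_{kcal}\log(PcKcal_t/PcKcal_0) + \dots$, which yields
two testable invariants: scale-invariance of the calorie path (only
ratios enter) and pointwise monotonicity (more calories never raise the
share). The clamp can break monotonicity only in pathological
swing-and-collapse paths far outside the study conditions.

## Criteria weights and TOPSIS

Weights come from three regional development indicators: the share of
agriculture in GDP (importance of economic returns), the poverty
headcount, and the child-stunting headcount. Each target-region
indicator is divided by its reference region's value (sub-Saharan Africa
for African drylands, South Asia for South-Asian drylands) and the three
ratios are normalized to sum to one. Weights are carried unrounded
through all computations; rounding to the reporting precision happens
only at serialization. (The published weight table contains rows whose
printed ratios are inconsistent with its rounded indicator percentages —
evidently computed from unrounded indicators — so the verification
targets use the self-consistent rows.)

TOPSIS proceeds in six steps: (1) each raw criterion column is divided by
its Euclidean norm (which makes the ranking invariant to positive
rescaling of any criterion and preserves signs); (2) weights multiply
the normalized columns; (3) the positive ideal takes the best weighted
value per criterion — maximum for the benefit criteria (BCR, poverty
reduction), minimum for the cost criterion (malnutrition change, where
more negative is better) — and the negative ideal the worst; (4)
Euclidean distances $S^\pm_i$ to both ideals; (5) closeness
$C^+_i = S^-_i / (S^-_i + S^+_i) \in [0, 1]$; (6) ranking by descending
closeness. This criterion encoding (poverty as the positive count of
people lifted out, malnutrition as the signed change) is the one
consistent with the published worked ideal-solution vectors.

**Numerical choices.** Ties share the minimum (competition) rank. A
technology whose positive and negative ideals coincide (e.g. a
single-technology matrix) gets closeness 1 with a warning — it is its
own positive ideal. An identically-zero criterion column cannot be
vector-normalized and raises an error naming the criterion. No
tolerance-based tie snapping is performed; ties are exact equality.

## Synthetic data

No machine-readable parameter tables are deposited with the source
study, so `generator_config()` + `generate_*()` emulate their structure:
uniform draws within expert-style bounds (the published parameters came
from an 18-expert elicitation with no reported distributions, so uniform
within bounds is the least-committal choice; every bound is
configurable). The default bounds bracket the one fully published
exemplar technology (drought-tolerant cowpea: 70% yield gain, 80%
success, −10% cost, 40% adoption ceiling in 10 years, US$300k/yr × 10 yr
research, US$50/ha dissemination), which can be pinned as the first
profile with `include_exemplar = TRUE`. Macro bounds are set to typical
dryland staple-crop magnitudes (production 5×10⁴–2×10⁶ t, price US$150–
800/t, elasticities 0.3–1.5, poverty elasticity −1.2 to −0.3).
Everything is a deterministic function of one integer seed through base
R's Mersenne-Twister, and the generator restores the caller's RNG state.

What passing tests on synthetic data do and do not show: they verify the
arithmetic, invariances and plumbing of the pipeline under realistic
magnitudes, but synthetic environments cannot reproduce the published
region-specific headline results (those require unpublished per-country
tables and external macro data), and uniform parameter draws carry none
of the correlation structure of real elicited technologies. The
published worked numbers that *are* reproducible — the weight-table rows
and the ideal-distance/closeness arithmetic — are asserted exactly in
the test suite.

## Problem sizes and determinism

The bundled fixture study uses 12 technologies and 3 countries over a
25-year horizon — large enough to exercise ties, dominance and
sensitivity behaviour while keeping any run of the full pipeline
essentially instantaneous. Property-style tests run dozens of seeded
random cases per invariant; the TOPSIS path is checked against an
independent straight-line recomputation at $10^{-12}$ and discounting
against a loop-based present-value oracle at $10^{-9}$.

## Known limitations

- The surplus model is closed-economy with linear curves and a parallel
  shift; no trade, price transmission, or seasonal price dynamics.
- The production-to-calories linkage ignores substitution between crops,
  so it cannot produce the nutrition-worsening crowding-out effects that
  a full multi-market model can (a cash crop displacing staples).
- The safe-water channel of the malnutrition recursion is inactive by
  default for lack of a published coefficient.
- Weights are indicator ratios by construction; no stakeholder
  elicitation (e.g. pairwise comparison methods) is implemented, though
  `sensitivity_sweep()` shows how rankings respond to any weighting.
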