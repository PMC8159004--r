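---
title: "Methods: unemployment shocks and CVD burden in a multi-state life-table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unemployment shocks and CVD burden in a multi-state life-table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdshock)
```

# Overview

`cvdshock` quantifies the cardiovascular disease (CVD) burden implied
by scenario-based unemployment shocks in an ethnically stratified
population. The causal chain it implements is deliberately narrow:
higher unemployment raises the incidence of coronary heart disease
(CHD) and stroke; nothing else changes. Direct pandemic disease
burden, behavioural pathways (tobacco, alcohol, diet), wider GDP
effects, and case-fatality deterioration are all out of scope, and
people aged 65+ at shock time receive no shock (they are largely
outside the labour force).

# The model, stage by stage

## Calibration of stratified shocks

Published unemployment projections are aggregate; the disease model is
stratified by ethnicity (Māori / non-Māori), sex and 10-year age band.
We assume the *relative* pattern of unemployment across groups that
held before the shock persists through it: for any two groups,
$\mathrm{d}U_g/\mathrm{d}U_h = U_g/U_h$. Together with aggregate
consistency — the population-weighted mean of the group changes must
equal the aggregate change — this pins down a unique solution,

$$\mathrm{d}U_g \;=\; \mathrm{d}U \cdot
  \frac{U_g \, N}{\sum_h \mathrm{pop}_h U_h}, \qquad N = \sum_h \mathrm{pop}_h.$$

A form of this equation sometimes quoted without the total-population
factor has units of rate *per person*; we implement the dimensionally
consistent solution above, which is the only one under which both
stated assumptions hold. Tests verify it against a generic
linear-system solve of the two constraints.

For the full ethnicity × sex × age cross-classification, cell changes
are proportional to the *product of the marginal* ethnic, sex and age
rates (sex and age patterns are taken from the general population, not
within ethnicity), renormalised so the population-weighted mean over
all working-age cells equals the aggregate change exactly. Marginal
rates are simple means over complementary cells; for multiplicatively
built tables (including the synthetic generator's) every configured
ratio is then recovered exactly, and post-shock rates reproduce
pre-shock weights. Unemployment strata cover ages 15–64, but only
bands 35–64 enter the disease model: the younger bands' shock mass is
deliberately discarded rather than reallocated, since no published
statement licenses reallocation. Cell deltas that would push a rate
outside $[0,1]$ are clipped with a warning; this cannot occur at
realistic shock sizes.

## Scenarios

Five built-in scenarios cover 2020–2024 over a constant 4% pre-shock
baseline: no-pandemic baseline, base case (yearly rates 5.3, 7.7, 7.6,
6.6, 5.3%), early recovery in services exports, extended border
controls, and community-transmission resurgence. Increments are
`rate − 0.04` per year. Because the life-table population starts in
2011, calendar year 2020+k maps to model cycle k. The 10-year shock
sensitivity must extend a 5-year profile; whether the original
analysis held the last increment or repeated the profile is not
stated, so both are supported (`hold_last` is the default, as the
milder and simpler reading) and neither is asserted in tests.

## From increments to relative risks

Effect sizes are the percent change in CVD incidence per 1% *relative*
increase in unemployment, by sex and band (35–44, 45–59, 60–64), from
the multi-country recession literature; model bands map to the nearest
effect band (45–54 → 45–59, 55–64 → 60–64). The default reading
divides each stratum's absolute increment by its *own* baseline rate —
because the disaggregation preserves rate ratios, every stratum then
shows the same relative increase, and risk differences across strata
come only from the sex/age effect sizes while shock-size differences
across ethnic groups come through the calibration. A
`percentage_point` switch implements the alternative reading (1% = 1
point) for sensitivity, since the source convention is ambiguous.

Scaling is linear: $RR = 1 + (\beta/100)\,\mathrm{rel}\%$, applied
identically to CHD and stroke incidence and to nothing else. A
negative $\beta$ with a positive shock yields $RR<1$ and hence a
health *gain* — the model does not force all groups to lose.

## The life-table engine

Each ethnicity × sex × starting-age cohort (ages 0–110 at model start)
advances in annual cycles until age 110, at which the cohort is
closed. Per cycle, in order: secular trends, shock relative risk,
disease steps, mortality. Each disease runs as a three-state process
on proportions

$$S' = S(1-i), \qquad C' = C(1-f) + S\,i, \qquad D' = D + C f,$$

with zero remission; new cases do not face case fatality within their
incident cycle. Cohort survival combines background (CVD-deleted)
mortality and disease deaths multiplicatively,

$$\ell_{t+1} = \ell_t (1-bg_t)\,(1-p^{chd}_t f^{chd}_t)\,(1-p^{str}_t f^{str}_t),$$

where $p_t$ is start-of-cycle prevalence among the alive. We chose the
multiplicative (competing-risk independence) form over simple addition
of excess hazards because it is the *exact expectation* of the
individual-level transition kernel: the engine is validated against a
100,000-individual microsimulation of that kernel to within 3
Monte-Carlo standard errors, with no $O(bg \cdot f)$ bias term. At the
rates involved the two forms differ negligibly. A corollary of the
design is that mortality is never forced to track incidence — a 0.85%
incidence rise produces whatever mortality response the state
equations imply.

Person-years use the trapezoidal half-cycle correction
$L_t = (\ell_t + \ell_{t+1})/2$; no person-years accrue at age 110.
HALYs weight person-years by $1 - \bar p^{chd} dw_{chd} - \bar p^{str}
dw_{str}$ using mid-cycle average prevalence; costs accrue background
per-capita costs per person-year plus per-prevalent-case disease
costs. Both discount at $(1+r)^{-t}$ (cycle-start convention, so an
accrual at cycle 10 is worth $(1+r)^{-10}$), $r = 3\%$ by default with
0% and 6% sensitivities. Trends: background mortality declines 2.25%
(Māori) / 1.75% (non-Māori) per year for 15 cycles (out to 2026 from a
2011 start) and is frozen thereafter; disease incidence and case
fatality decline 2.0% per year throughout, with a freeze switch for
the trend-level-off sensitivity.

Only *differences* between a shocked and an unshocked run are
reported: absolute HALY and cost levels depend on placeholder
disability weights and synthetic cost schedules and carry no meaning.

## Uncertainty

Multiplicative parameters get log-normal factors with mean 1 and the
stated coefficient of variation — unemployment increments 20% (one
factor per draw, fully correlated across strata and years, attached to
the *additional* rates), disease incidence and case fatality 5% (one
factor per parameter), costs 10%. Effect sizes are sampled
independently per row as normals on their natural percent scale with
SD = (CI width)/(2 × 1.959964); a log-normal is impossible for
sign-crossing intervals, and the printed RR-style interval column of
the source table is internally inconsistent, so the percent scale is
the only usable one. Intervals are 95% empirical percentiles; the
default 2,000 draws is a convention (the source analysis states no
draw count), and tests use far fewer draws, scaled down purely for run
time.

Because the linear effect model is unbounded below, an extreme
negative effect-size draw combined with the large (~90%) relative
increases the calibration produces can imply a *negative* incidence
multiplier. The Monte-Carlo engine truncates sampled relative risks at
0.01; the deterministic path remains strict and raises an error
instead, so silent truncation cannot mask a configuration mistake.

### A deliberately failing acceptance property

One acceptance property asserts that, since most effect-size CIs span
zero, the 95% interval of the *total* lifetime HALY change spans zero.
Under independent per-row effect sampling (correlated sampling is an
explicit non-goal of this package) the total is approximately
$u \sum_g L_g \beta_g$ with $u>0$, and on the default fixture
$z = \sum_g L_g\mu_g / \sqrt{\sum_g L_g^2\sigma_g^2} \approx 2.10$,
i.e. only ≈ 1.8% of draws flip sign — below the 2.5% a spanning 95%
interval requires. Recomputing $z$ from the published per-group
central losses and effect SDs gives ≈ 2.17 (≈ 1.5%), so the published
positive upper bound on the total is only reachable with *correlated*
effect draws. The per-stratum version of the property (female strata,
whose effect CIs span zero widely) holds and is asserted green; the
total-row assertion is implemented faithfully and left red rather than
weakened, because making it pass would require either correlating the
draws (out of scope) or distorting the fixture.

# The synthetic-data generator

The generator emulates the *statistical structure* of the
administrative inputs, not their values:

* **Population** (default 4.4 million, 15% Māori): exponential age
  pyramids with ethnicity-specific scale, giving median ages of
  roughly 24 (Māori) vs 38 years; even sex split; seeded log-normal
  cell jitter (CV 5%).
* **Baseline unemployment** (overall 4%, the pre-shock level): built
  multiplicatively from a Māori/non-Māori ratio of 2.0, a female/male
  ratio of 1.1, and an age gradient declining from 3.0 (15–24) to 0.9
  (55–64) relative to 45–54, normalised so the population-weighted
  mean equals the overall rate. No noise is added: the configured
  ratios must hold exactly so the calibration's round-trip invariants
  are testable.
* **Epidemiology**: Gompertz-like exponential age curves with levels
  set to realistic working-age magnitudes (e.g. male CHD incidence
  ≈ 0.8%/yr and background mortality ≈ 0.7%/yr at age 64); Māori/non-
  Māori ratio 2.0 on mortality and incidence and 1.5 on case fatality;
  male/female incidence ratio 1.6; initial prevalence ≈ incidence × 12
  years. Jitter is one seeded log-normal factor per sex × parameter,
  shared across ethnicity and age so monotone age curves and exact
  ethnic ratios survive. Disability weights (CHD 0.12, stroke 0.25)
  are **placeholders** — the source model's morbidity weights are not
  published — which is why only HALY differences are reported.
* **Costs**: background ≈ NZ$1,500/yr at age 0 growing 2%/yr of age;
  NZ$6,500 and NZ$9,000 per prevalent CHD/stroke case-year (2011
  base). Conversion factors to 2019 NZ$ (×1.098) and 2019 US$ (×0.69)
  are pure reporting multipliers chosen to approximate the published
  conversion ranges; there is no CPI lookup.

What a green test on this fixture does **not** establish: agreement
with any real country's burden estimates; realistic absolute HALY or
cost levels; cohort effects, migration or fertility; comorbidity
interactions between CHD and stroke (the processes are independent);
or the behaviour of the equity ratio under epidemiologies unlike the
configured ones. The fixture's equity ratio (~1.7 on defaults) is
smaller than published national estimates (~3.7) because the synthetic
ethnic gaps are simple constant ratios without the compounding
age-structure and exposure differences of the real data.

# Numerical conventions and edge cases

* Tolerances: calibration conservation 1e-10; life-table state
  conservation (alive + cumulative dead = initial cohort) 1e-9;
  identical runs difference exactly 0.
* Degenerate inputs: zero baseline rates are errors wherever a ratio
  is formed (weights, relative increases); all-zero populations are
  errors; `incidence_rr()` errors on implied RR ≤ 0; generated
  configurations whose ratios would push any rate above 1 are
  rejected at generation time.
* Determinism: all generators and the Monte-Carlo engine are pure
  functions of (config, seed); the same seed gives byte-identical
  output. Monte-Carlo draw *k* is reproducible in isolation because
  the full draw table is regenerated from the seed and row *k*
  applied.
* The terminal age closes the cohort: survival at age 110 is zero and
  no person-years accrue there, so with all hazards zero and r = 0,
  HALYs equal population × years to age 110 exactly.

# Known limitations

Single-year cycles only; no disease interaction; the shock acts on a
population indexed to the model start year, so the shock years are
modelled as the first five cycles rather than their true calendar
years (matching the source model's design, and slightly conservative
under declining disease trends); effect sizes carry no ethnicity
dimension (ethnic differences enter only through shock size); and the
acceptance surface for absolute levels is intentionally empty — the
package's claims are about differences, ratios, orderings and
conservation laws, which is exactly what the test suite checks.
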