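---
title: "The PALY life-table model behind palyburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PALY life-table model behind palyburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palyburden)
```

## The problem and the measure

Uncorrected and under-corrected presbyopia — age-related near-vision
impairment without adequate optical correction — reduces on-the-job
productivity without raising mortality. Its population-level burden can be
expressed in productivity-adjusted life years (PALYs): years of life lived
weighted by a productivity index in $[0, 1]$, the productivity analogue of
a QALY. `palyburden` estimates, for a panel of low- and middle-income
countries, the PALYs and the money lost to the condition both
cross-sectionally (one base year) and longitudinally (each prevalent case
followed to retirement).

## The model

**Productivity index.** An unaffected person has index 1. An affected
person has index

$$ PI = 1 - p - \frac{d}{w}, $$

where $p$ is presenteeism (the proportional productivity reduction while
at work; default 0.109), $d$ is absenteeism in lost work days per year
(default 0) and $w$ the work days in a full year (default 250). The
absenteeism pathway is implemented for reuse even though the default
analysis sets it to zero. We call $f = p + d/w$ the *loss fraction*.

**Life table.** Each country × 5-year age band contributes one cohort of
the prevalent cases. The cohort enters at the band midpoint age $a + 2$
and is followed in annual cycles while younger than the retirement age
(default 65), under the country's age-specific annual death probabilities
$q_x$:

$$ \ell_{t+1} = \ell_t \,(1 - q_{a_0 + t}), \qquad \ell_0 = N. $$

Deaths occur at year-end, so the person-years lived in cycle $t$ are
$\ell_t$ (decedents contribute a full year in their death year). Years are
discounted at annual rate $r$ (default 3%) with the base year undiscounted:
discounted person-years are $\sum_t \ell_t (1+r)^{-t}$.

**PALYs and PALYs lost.** The condition is non-fatal, so the affected and
the hypothetical unaffected cohort share one trajectory and differ only in
the index:

$$ \mathrm{PALY}_\text{healthy} = \sum_t \ell_t (1+r)^{-t}, \qquad
   \mathrm{PALY}_\text{affected} = (1-f)\,\mathrm{PALY}_\text{healthy}. $$

This forces the exact identity

$$ \frac{\mathrm{PALYs\ lost}}{\mathrm{PALY}_\text{healthy}} = f $$

for *every* mortality schedule and discount rate. With the defaults the
lifetime PALYs-lost fraction is 10.9% — not an empirical finding of the
simulation but an algebraic consequence of the no-excess-mortality
assumption, and therefore a stringent correctness check: any half-cycle
correction, differential mortality, or index misapplication breaks it.

**Money.** PALYs lost are valued through the total-productivity-loss
product

$$ TPL = TC \times ER \times LPR \times \text{PALYs lost per person}
        \times GDP_{pc}, $$

with $TC$ the working-age cases, $ER$ the employment-to-population ratio,
$LPR$ the labor-force participation rate and $GDP_{pc}$ GDP per capita in
current US\$. The formula multiplies **both** $ER$ and $LPR$, although the
employment ratio already embeds participation; the product is implemented
verbatim as stated, and flagged here because users replacing the inputs
with their own should be aware of the possible double-counting. When an
econ table carries a non-missing `gdp_per_worker` column, that value
replaces $GDP_{pc}$ as the annual value of one PALY. The cross-sectional
(annual) loss is the same product with PALYs lost per person replaced by
the one-year loss fraction $f$, undiscounted.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `presenteeism` | fraction | 0.109 | pooled estimate of the relative productivity reduction from prior presbyopia studies |
| `absenteeism_days` | days/year | 0 | assumed absent for this condition; pathway kept for reuse |
| `workdays_per_year` | days | 250 | conversion constant for absenteeism (5-day weeks, ~2 weeks leave) |
| `discount_rate` | fraction/year | 0.03 | WHO standard annual discount on life-years and PALYs |
| `retirement_age` | years | 65 | end of simulated working lifetime |
| `base_year` | year | 2019 | calendar year of the cross-sectional inputs |

Ratios are stored as fractions in $[0,1]$ throughout — input files carrying
percentages must be pre-scaled — because a single internal convention
prevents silent 100× errors.

## Conventions where the design was open

Several conventions are deliberate modelling choices, stated rather than
inferred:

- **Annual cycles**, not 5-year ones: only annual cycles truncate exactly
  at age 65 for cohorts entering mid-band.
- **Band midpoint entry** ($a+2$ for band $[a, a+4]$): the unbiased
  central age when the within-band age distribution is unknown.
- **Deaths at year-end, no half-cycle correction**: with no stated
  within-year convention, this choice keeps the PALYs-lost identity exact
  and the engine auditable; a half-cycle correction would change absolute
  PALY levels but cancel out of the loss *fraction* anyway.
- **Discounting from $t = 0$** with the first year undiscounted, the
  standard health-economics convention.
- **Fractional persons**: the life table is a deterministic expected-value
  model; no stochastic rounding, so results are exactly reproducible and
  linear in cohort size.
- **Scenarios re-run the whole pipeline** instead of rescaling cached
  outputs, so interacting perturbations (e.g. a case bound together with a
  different discount rate) remain representable even though the standard
  grid varies one factor at a time.
- In the one-way grid, the discount-rate scenarios are 5% and 1.5%
  (increase and decrease around the 3% standard); per-person losses in
  each scenario use that scenario's own case count.

## The synthetic generator

Real inputs for this model are country extracts (GBD-style prevalence with
95% bounds, ILO employment ratios, World-Bank GDP, life tables) that are
not redistributable at desk scale, so `gen_dataset()` draws panels with the
statistical structure the analysis assumes: prevalence starting at 25% of
the 40–44 band and rising ×1.25 per 5-year band (capped at 0.95), band
populations lognormal across countries and gently shrinking with age,
Gompertz mortality $q(a) = a_0 e^{b(a-40)}$ with $a_0 = 0.004$ at age 40
and $b = 0.085$ per year (doubling roughly every 8 years, the classic
adult-mortality shape), GDP per capita drawn within the 2019 World Bank
income-class ranges, $ER \le LPR$ by construction, and symmetric ±40%
case bounds, close to the relative width of published presbyopia
uncertainty intervals. Everything is reproducible from a single seed, and
the generator restores the caller's RNG stream.

What it does **not** emulate: the asymmetric, correlated uncertainty of a
DisMod-style estimation pipeline; calendar trends in mortality or
employment; within-country heterogeneity. Passing tests on synthetic data
therefore demonstrate the *model mechanics* (identities, monotonicities,
additivity, determinism), not the accuracy of any real-world estimate.
`gen_worked_fixture()` is a fixed 3-country, 2-band panel with constant
within-country mortality, so every pipeline quantity reduces to a
geometric sum checkable by hand; it ships as CSVs under `inst/extdata/`.

## Numerical notes

Survivorship uses a single cumulative product; person-years and PALYs are
plain sums, so results are exact to double precision (~1e-15 relative) and
platform-stable. Degenerate inputs behave sensibly: $q \equiv 0$ gives the
annuity-due closed form, $q \equiv 1$ one person-year per person,
`ci_width = 0` collapses all case-bound scenarios onto the point estimate,
presenteeism 0 gives zero loss everywhere. Aggregation sums numerators and
denominators and recomputes ratio columns — never averages of ratios. Ties
in the top-$k$ country ranking break lexicographically by country id.
Rounding to the published 2-decimal table style happens only in the
`render_*` functions; every stored tibble and CSV keeps full precision.

Test problem sizes: property suites run on panels of 4–12 countries and on
50 randomly drawn single cohorts per suite, which exercises every code
path in a few seconds while the identities being checked are
size-independent.

## Limitations

The model inherits the limitations of its class: prevalence-based (no
future onset of new cases, which understates lifetime losses), static
age-specific mortality over calendar time, a single pooled presenteeism
applied to all ages, countries and income groups, and valuation at GDP per
capita (or per worker) with both ER and LPR multiplied as stated above. No
probabilistic sensitivity analysis is provided; uncertainty is explored
only through the deterministic one-way grid.
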