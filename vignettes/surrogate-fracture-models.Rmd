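---
title: "Surrogate fracture probability models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate fracture probability models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrofrax)
```

## The problem

Ten-year fracture probability — the quantity clinicians use to decide whether
to treat osteoporosis — requires two country-specific inputs: age- and
sex-specific fracture incidence and age- and sex-specific mortality. Many
countries have reliable mortality statistics but no fracture registry. The
accepted recourse, endorsed by the International Society for Clinical
Densitometry and the International Osteoporosis Foundation, is a *surrogate*
model: borrow fracture incidence from a country (usually nearby, ethnically
comparable) where rates are considered representative, and combine it with the
index country's own mortality. `surrofrax` implements that construction, the
competing-risk probability engine needed to evaluate it, a protocol for
comparing surrogate against reference model, and national burden projection.

## The competing-risk probability model

An individual alive and fracture-free at age $a_0$ faces two exits: first
fracture, with annual hazard $h_f(a)$, and death before fracture, with hazard
$h_d(a)$. The 10-year fracture probability is the cause-specific cumulative
incidence

$$P = \int_{a_0}^{a_0+10} h_f(a)\, \exp\!\Big(-\int_{a_0}^{a} (h_f+h_d)\,du\Big)\, da ,$$

*not* $1-\exp(-\int h_f)$: dying first removes the chance to fracture, so a
country with higher mortality has lower fracture probability at identical
incidence. Because both hazards are band-constant (5-year age bands by
default), the integral is evaluated exactly: on a segment of length $\Delta$
with constant $h_f, h_d$ and entry survival $S$, the contribution is
$S\,\frac{h_f}{h_f+h_d}\big(1-e^{-(h_f+h_d)\Delta}\big)$, and $S$ picks up the
factor $e^{-(h_f+h_d)\Delta}$. Segments split at every band boundary crossed
by the horizon and at the horizon end. The tests cross-check this closed form
against an independent Monte-Carlo simulation of paired competing exponential
event times (27 parameter triples, $10^6$ draws each, agreement within 3
Monte-Carlo standard errors).

Two numerical details matter. The per-segment mass uses `expm1`, so
vanishing-horizon behaviour ($P/h \to h_f$ as $h \to 0$) holds to $10^{-10}$
rather than being lost to cancellation in `1 - exp(-x)`; and segment lengths
are computed as offsets from the start age, because `(a0 + 1e-8) - a0` in
floating point is not `1e-8`. Splitting any band into sub-segments leaves the
result unchanged to machine precision — an invariant under test.

## The hazard layers

**Baseline tables.** Rates are per 100,000 person-years on disk (the scale
epidemiological sources print) and per person-year in memory. Age bands are
half-open $[lo, hi+1)$ in integer years, 50–54 … 85–89 plus 90+ by default;
within-band hazards are step-constant with no interpolation, matching
life-table convention, and ages beyond the last closed band use the open
band's rate for the remainder of the horizon. The source banding (5- versus
1-year) is not dictated by any convention we must follow; 5-year bands are
the shipped default and the floor (50) is configurable.

**MOF imputation.** Incidence of the composite major osteoporotic fracture
(MOF: hip, clinical spine, distal forearm, proximal humerus) is rarely
observed; it is imputed band-wise as hip incidence times an age/sex-specific
MOF:hip multiplier assumed transportable from a well-characterized reference
population. The shipped multipliers are a synthetic default — age-declining
from about 6 (women) / 5 (men) at 50 toward 1.5 at 90+, female ≥ male — and
are **not** the Malmö values, which are not public in tabular form. Multipliers
below 1 are rejected (hip is a subset of MOF).

**Relative-risk layer.** An individual's fracture hazard is baseline times
the product of active clinical-risk-factor (CRF) hazard ratios, times
$g^{(t_{\mathrm{ref}} - t)}$ where $g$ is the gradient of risk per SD decrease
in femoral-neck T-score $t$, divided by a population-calibration divisor.
Authentic FRAX coefficients are proprietary and unpublished, so the layer is
loaded from a flat config file and the shipped defaults (CRF hazard ratios
1.3–2.0, gradient 1.6/SD, divisor 1) are clearly labelled synthetic. Three
consequences, stated openly:

* absolute probabilities from the default coefficients are illustrative, not
  clinically calibrated — with divisor 1 the baseline table is treated as the
  reference-profile rate, so grid profiles with several CRFs active reach
  higher probabilities than a calibrated calculator would print;
* CRF effects on the death hazard are supported per-CRF but default to HR 1,
  since their authentic magnitudes are equally unavailable; whether the BMD
  term should also perturb mortality is left off by default for the same
  reason;
* the T-score is taken as given input (its reference population is a
  densitometry convention outside this package's scope).

The surrogate construction itself (`build_surrogate`) inherits the reference
model's incidence and coefficient layer unchanged and swaps in the index
country's mortality — only incidence and mortality distinguish the two
models. No smoothing is applied to any rate table before or after the
substitution.

## The comparison protocol

Two models are compared at ages 50, 60, 70 and 80, separately by sex and
outcome (MOF, hip), over the **full factorial array** — not a population
sample — of all $2^6 = 64$ CRF on/off states crossed with 8 T-scores (0 to
−3.5 SD in 0.5 SD steps), BMI fixed at 26 kg/m²: 512 profiles per (age, sex),
in deterministic order (T-score outermost, CRF states as a binary counter) so
outputs are byte-stable. Summaries per cell:

* **Pearson correlation** between paired probabilities (identical columns
  short-circuit to exactly 1);
* **piecewise linear regression** of comparator on reference with one fixed
  knot at 35% on the reference axis, continuity enforced by the
  truncated-line basis; when no profile exceeds the knot the slope change is
  structurally zero and flagged;
* **medians and 95% tolerance intervals.** The reference median for $n=512$
  is the mean of the 256th and 257th order statistics; the comparator median
  is the comparator value of the straddling profiles. The tolerance interval
  — an interval for individual cases, not a confidence interval for a mean —
  is deliberately nonparametric: the empirical 2.5th/97.5th percentiles of
  the comparator−reference differences among the 101 profiles whose reference
  ranks are nearest the median, added to the reference median. A
  regression-residual variant is exposed (`method = "residual"`) since the
  construction admits either reading; the percentile form is the default
  because it is distribution-free and collapses exactly to a zero-width
  interval when the models agree. Grid profiles are equally weighted
  throughout (no population prevalence weighting).

## The synthetic generator

Real reference-country incidence and index-country mortality tables are
licensed compilations, so the package generates fixtures with the statistical
structure the method assumes: Gompertz (exponential-in-age) hazards for both
mortality and hip incidence — the simplest shapes matching the universal
age pattern — with male mortality above female, a 1.5-fold female excess in
hip incidence from age 60, age-declining MOF:hip ratios, and a young
population pyramid (band weights declining geometrically with age) growing 2%
per year with a mild ageing drift. The demo index country's mortality is the
reference's times a multiplier rising from ~1.05 at 50 to ~1.9 at 90+, so the
surrogate reproduces the qualitative signature of interest: probabilities
nearly equal at 50, increasingly lower at 70–80, with rank order essentially
preserved (r ≥ 0.99 in every cell).

The generator is fully deterministic closed-form; the seed only drives an
optional multiplicative log-normal jitter (`jitter_sd`, default 0), and
drawing it leaves the caller's RNG stream untouched. What the fixtures do
**not** emulate: registry artefacts (coding changes, under-ascertainment),
urban–rural and secular incidence variation, cohort effects in mortality, and
any real country's absolute levels. Passing tests therefore demonstrate the
machinery's correctness and the construction's structural properties, not
agreement with any real national estimate.

## Problem sizes and runtime choices

The shipped test suite evaluates 512-profile grids at up to four ages and
both sexes per comparison (a grid evaluation is vectorized across profiles:
baseline segment rates are computed once per (model, age, sex) and scaled by
per-profile factors), uses $10^6$ Monte-Carlo draws per oracle triple, 200
random tables for the imputation property, 1,000 random profiles for the
hip ≤ MOF property, and 100 replicates of 512 points for regression
recovery — sizes chosen so each property is tested at the protocol's actual
scale while the whole suite runs in well under a minute.

## Known limitations

* The coefficient layer is synthetic; outputs are not comparable to any
  published calculator's absolute values.
* Burden projections are expected-value arithmetic (rate × mid-year
  population as person-years); no uncertainty intervals, no secular-trend
  scenarios.
* One-year probabilities, T-score computation from raw BMD, and parsing of
  native WHO/UN download formats are out of scope; users pre-flatten tables
  to the documented CSV dialect.
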