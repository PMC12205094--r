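---
title: "coldtrial: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coldtrial: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtrial)
```

This vignette is the package's own account of its statistics: the models,
their assumptions, the tunable parameters, the numerical conventions, and
the choices made where more than one defensible option existed. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The monitoring model

A single-arm phase-II trial observes binary objective responses. The
response rate $p$ carries a conjugate Beta prior,

$$p \sim \mathrm{Beta}(a, b), \qquad
  r \mid n, p \sim \mathrm{Binomial}(n, p), \qquad
  p \mid r, n \sim \mathrm{Beta}(a + r,\; b + n - r),$$

and the trial is monitored at interim looks after the first
`n_first_interim` evaluable patients and every `cohort_step` thereafter,
up to `n_max`. The key assumptions are exchangeable patients, a response
probability constant over accrual, and evaluability independent of
response.

**Defaults** (all exposed in `trial_design()`):

| parameter | default | meaning |
|---|---|---|
| `prior_alpha`, `prior_beta` | 1, 1 | uniform prior (pseudo-counts) |
| `p_futility` | 0.10 | null ORR; futility event $p \le 0.10$ |
| `p_efficacy` | 0.25 | target ORR; efficacy event $p \ge 0.25$ |
| `threshold_futility`, `threshold_efficacy` | 0.80 | stopping bars |
| `n_first_interim`, `cohort_step`, `n_max` | 10, 5, 50 | look schedule |
| `evaluation_window_weeks` | 16 | observation window before a patient is interim-evaluable |
| `rule` | `"posterior"` | stopping-rule interpretation |

The uniform prior is the default because it is the weakest proper
conjugate choice and because, combined with 4 responders among 43
evaluable patients, it reproduces a reported posterior mean of
$(1+4)/(2+43) = 11.1\%$ to within rounding of a published 11.0% figure.
The prior is a plain argument, not a constant, so informative choices are
one call away.

### Two readings of "predictive probability"

Trial protocols often describe stopping rules with the word *predictive*
while stating events about the **parameter** ("the ORR falls at or below
10%"), which is literally a posterior-probability statement. Both
readings are implemented:

* `rule = "posterior"` (default): compare
  $P(p \le p_{fut} \mid \text{data})$ and
  $P(p \ge p_{eff} \mid \text{data})$ to the thresholds. This is the
  literal event reading, and the default because the events as stated
  concern $p$ itself.
* `rule = "predictive"`: with $m = n_{max} - n$ patients to come and
  $k \sim \mathrm{BetaBin}(m, a + r, b + n - r)$ future responders,
  compute the probability that the **final** posterior at $n_{max}$
  meets the corresponding criterion. This is the textbook
  predictive-probability design; at $n = n_{max}$ it degenerates to the
  0/1 indicator of the final criterion.

When both events clear their bars simultaneously, futility wins
(conservative precedence). With the default thresholds this situation is
impossible at any scheduled look — a fact asserted by a sweep test over
all $r = 0, \dots, n$ at every look, under both rules.

The 16-week evaluation window gates only *when* a patient counts toward
an interim analysis; it never changes the decision arithmetic, so the
package carries it as design metadata used by callers that sequence
interim data.

### Numerical conventions

Posterior credible intervals are **equal-tailed** beta quantiles
(`qbeta`), the default convention behind an unqualified "95% credible
interval"; a highest-posterior-density interval is available via
`hpd = TRUE` (computed by minimising interval width over the lower tail
probability; for shapes $\le 1$ where the density has no interior mode
the HPD request falls back to equal tails). The beta-binomial predictive
mass function is evaluated on the log scale
(`lchoose + lbeta` differences) for stability at large $m$.

Operating characteristics use counter-based seeding — trial $i$ at grid
point $g$ is seeded with `seed + (g-1)·n_sims + i` — so estimates are
reproducible and independent of evaluation order, and any single
trajectory can be regenerated in isolation.

## 2. Survival endpoints

Kaplan–Meier curves are fitted by `survival::survfit` (the
field-standard product-limit implementation; ties between events and
censorings at the same time are resolved events-first, the standard KM
convention). The package owns the conventions on top of the curve:

* **Median** = smallest observed time with $\hat S(t) \le 0.5$
  (`survfit`'s own median uses a midpoint rule on flat stretches; the
  smallest-time convention is applied here so a curve stepping exactly
  onto 0.5 reports that time). "Not reached" is an explicit flag, never
  a sentinel number.
* **Median CI** by inversion of the pointwise band
  (Brookmeyer–Crowley style): the lower bound is the first time the
  lower band reaches 0.5, the upper bound the first time the upper band
  does; either may be not reached. Bands are log(−log)-transformed by
  default — they respect $[0,1]$ and handle "NR" upper bounds naturally —
  with plain Greenwood (`conf_type = "linear"`) available, since which
  transformation a given report used is rarely stated.
* **Milestones** are step-function values with the same bands; a
  landmark before the first event returns 1 with a degenerate interval,
  and a landmark beyond follow-up returns the last value flagged
  `truncated`.

Duration of response is progression/censoring time minus response onset,
restricted to responders (a responder without an onset time is a
validation error, not a silent drop). Disease control lasting ≥ 6 months
uses the fixed conversion 1 month = 365/12 days.

The **growth-modulation index** divides current-line by prior-line PFS;
the benefit rule is inclusive ($\ge 1.33$). Censored current-line PFS
makes the GMI a lower bound; such pairs are included and flagged by
default (common GMI practice), with `include_censored = FALSE` as the
sensitivity switch. Reported percentages round half away from zero to
one decimal (base `round()` would round half to even).

## 3. Spatial biomarker statistics

A `cell_map` holds one region's phenotyped cells (µm coordinates, binary
flags) and its analysed area; the CD3 flag is enforced for every CD4+ or
CD8+ cell. Statistics:

* **Density** = flagged-cell count / area (cells/mm²).
* **Colocalization**: a source cell (default CD20+, a B cell) counts as
  colocalized when at least one *distinct* cell with any target flag
  (default CD4 or CD8) lies within `radius_um` (default 10 µm,
  **closed** ball — "within a radius" is read inclusively, and the
  boundary convention is a parameter in effect because the comparison is
  `<=` on exact squared distances). A double-positive cell is never its
  own neighbour. The neighbour search uses a bucket grid with cell width
  equal to the radius (3×3 neighbourhood scan); a brute-force all-pairs
  mode is kept as a first-class code path and the two are asserted
  identical on random and clustered maps.
* **Marker fractions**: PD-1-positive share of a base phenotype, with an
  explicit empty-denominator flag; "expression" is implemented as a
  positive-cell fraction (the alternative — mean intensity — is not a
  cell-map quantity; an intensity column, if present upstream, can be
  thresholded before ingest).
* Paired pre/post comparisons are **per sample**: one value per map,
  tested across patients. Pooling cells across samples before computing
  fractions would weight patients by cellularity and break pairing;
  per-sample is the default and the pooled variant is a one-line
  aggregation the caller can do explicitly.

No edge correction is applied at region borders: fractions are reported
raw, as assay reports typically do. This biases colocalization slightly
downward near borders — a documented limitation, shared equally by the
pre and post member of each pair.

### The exact signed-rank test

Paired tests use the Wilcoxon signed-rank statistic $V$ (sum of positive
ranks, midranks under ties). For up to 25 non-zero pairs the two-sided
p-value is **exact**: the null distribution of $V$ conditional on the
observed $|d_i|$ is built by dynamic-programming convolution over the
(doubled, hence integer) ranks — mathematically identical to enumerating
all $2^n$ sign assignments, but $O(n \cdot \sum \text{ranks})$. Unlike
`stats::wilcox.test`, exactness survives tied ranks. Zero differences
are dropped before ranking (the classical convention; `"pratt"` keeps
them in the ranking and drops them from the statistic); an all-zero
difference vector returns $p = 1$ with a `degenerate` flag rather than
an error, so screening loops never crash on a flat phenotype. Above 25
pairs a normal approximation with continuity correction and
tie-corrected variance takes over.

With 7 pairs the smallest achievable two-sided exact p is
$2/2^7 = 0.015625$, and the test's achievable size at $\alpha = 0.05$ is
$6/128 \approx 4.7\%$, not 5% — the null-calibration acceptance test
therefore checks a ±2% band around the nominal level rather than
equality, which is exactly what discreteness permits.

## 4. What the synthetic generators emulate

`cohort_scenario()` states a world chosen once to mirror the published
cohort: 50 patients, true ORR 0.10, marginal PFS median 1.8 months,
marginal OS median 15.1 months, median duration of response 7.8 months,
uniform accrual at 1.85 patients/month (50 patients over ~27 months),
database lock 7 months after the end of accrual, 86% evaluability
(43/50), and log-normal prior-line PFS with median 3 months
(`sdlog = 0.8`) — a realistic scale for a heavily pre-treated sarcoma
population whose previous line yielded a few months of control.

Construction:

* Survival is **exponential** — the single-parameter family pinned down
  by a median alone, which is all the emulated reports state; a heavier
  tail can be emulated by the caller via the exposed rates.
* Responders respond at the first 8-week assessment (onset fixed at
  $56/30.42 \approx 1.84$ months — assessments happen on schedule) and
  progress at onset + Exp(median 7.8). Because that lifts the cohort's
  PFS mixture, the **non-responder rate is calibrated** (by `uniroot` on
  the closed-form mixture survival) so the *marginal* PFS median equals
  the stated 1.8 months. This calibration is part of the stated world,
  fixed before any test was run: without it the generator would
  contradict the very median it claims to emulate. The closed form is
  exported as `true_pfs_survival()` and serves as the oracle in the
  recovery tests.
* OS = PFS + an independent exponential residual whose rate is
  calibrated (numerically, via quadrature on the convolution) so the
  marginal OS median equals 15.1 months. The additive construction
  guarantees OS ≥ PFS patient by patient — no inconsistent joint draws
  exist by design. `true_os_survival()` exposes this truth.
* Administrative censoring comes from uniform accrual plus the lock:
  patient follow-up is `accrual_end + censor_admin_months − entry`,
  always positive.
* Histology labels (45% leiomyosarcoma, 18% synovial sarcoma, remainder
  other) are cosmetic, consumed by no statistic.

`spatial_scenario()` states the biopsy world: 7 patients, 1 mm² regions,
baseline densities CD8 150, CD4 200, CD20 100, CD163 300 cells/mm²
(T-cell totals of a few hundred per mm², the scale reported for sarcoma
cohorts), a shared per-patient log-normal abundance effect
(`sd = 0.4`) that induces the pairing, on-treatment fold changes
CD8 2.0, CD4 1.5, CD20 1.8, CD163 1.5 (infiltration increases in most of
seven patients), and PD-1 fractions 0.20 → 0.35 on T cells. Coordinates
are homogeneous Poisson by default; a Thomas cluster process
(`clustering` = parent intensity, 30 µm offspring dispersion) is
available chiefly to stress the neighbour search, since no spatial model
for real tissue is asserted.

**What a green test does and does not establish.** The generators make
every pipeline stage runnable and make parameter-recovery and
null-calibration claims checkable against known truths. They do not
emulate segmentation error, marker-threshold misclassification,
intra-tumor heterogeneity beyond a scalar abundance effect, informative
censoring, response-dependent dropout, or real spatial architecture
(follicles, vessels, tissue borders). A passing suite therefore
establishes correctness of the *statistics on their stated inputs*, not
robustness to upstream assay artifacts.

## 5. Degenerate inputs and edge policies

* `trial_state` rejects $r > n$ and negative counts; decisions beyond
  `n_max` are errors.
* An empty patient table yields `orr_defined = FALSE` rather than 0/0.
* A map with no source cells reports colocalization 0 with
  `empty_source = TRUE`; no base cells likewise for marker fractions.
* A single censored survival record yields a curve identically 1 with an
  NR median.
* The trapezoid-integration oracle used to validate credible intervals
  is applied only for shapes ≥ 1, where the beta density is bounded and
  the rule converges; singular shapes are outside its validity domain.

## 6. Known limitations

* No frequentist group-sequential machinery (alpha spending), no
  multi-arm borrowing: single-arm beta-binomial only.
* No Cox or parametric survival regression; endpoints are univariate.
* Spatial statistics ignore edge effects and assume phenotype flags are
  correct as given.
* The predictive rule enumerates $k = 0..m$ exactly; no normal
  approximation is offered for very large `n_max` (unnecessary at
  phase-II scales).
* A published report's internally inconsistent denominators (e.g. 43
  evaluable stated alongside category percentages implying 44) cannot be
  resolved from printed numbers; the package takes counts as given and
  documents, rather than reconciles, such discrepancies.
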