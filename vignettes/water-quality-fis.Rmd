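---
title: "A hierarchical Mamdani fuzzy model for drinking-water quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Mamdani fuzzy model for drinking-water quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquafis)
library(dplyr)
```

## The problem

Routine drinking-water surveillance produces per-sample panels of
physicochemical measurements — alkalinity, hardness, pH, calcium, magnesium,
iron, fluoride, nitrate and sulfate — that must be condensed into a single,
interpretable quality statement. Crisp threshold rules ("compliant /
non-compliant") discard how close a measurement sits to its limit and how
several borderline parameters compound. Fuzzy inference handles exactly this
kind of graded, multi-criteria judgment: each measurement is translated into
degrees of membership in linguistic categories (*low*, *medium*, *high*),
expert-style if–then rules combine the categories, and the combined fuzzy
verdict is collapsed back to a 0–100 % score with a named quality class.

`aquafis` implements this as a **hierarchy of four Mamdani models**. Three
sub-models each take three related parameters:

* **FWQ1** — alkalinity, pH, hardness (the carbonate system),
* **FWQ2** — calcium, magnesium, iron (major cations and iron),
* **FWQ3** — sulfate, nitrate, fluoride (anions of health concern),

and produce intermediate scores on 0–100 %. A fourth model, **FWQ**, takes
the three crisp sub-scores as its own inputs and produces the final score.
Splitting nine inputs into 3 + 3 + 3 + 3 keeps every rule base at
3³ = 27 rules; a flat nine-input model would need 3⁹ ≈ 20,000.

## Membership functions and the variable catalog

All terms use triangular membership functions `(a, b, c)` (feet and peak),
evaluated by piecewise-linear interpolation and clamped to \[0, 1\]. The
extreme terms are *shoulders*: `a == b` saturates the left side (membership 1
for `x ≤ b`) and `b == c` the right side. The guideline ranges in
`wq_catalog()` only fix each term's support, so the package adopts one
convention for peaks:

* *low* = `(lo, lo, upper-of-low-range)` — a left shoulder,
* *high* = `(lower-of-high-range, hi, hi)` — a right shoulder,
* *medium* = a triangle peaking at the midpoint of its range.

The midpoint convention is self-consistent with the catalog: every medium
range is centred exactly on the low/high boundary (alkalinity's medium
100–700 peaks at 400, which is both the low upper bound and the high lower
bound), so the three curves of each variable form a clean overlapping
partition.

Each term also carries **quality points**: 0 (poor), 1 (moderate), 2 (good).
For every concentration-like parameter *low* is good and *high* is poor; pH
is the exception — its *medium* band (5.5–9.5) is the good one, acidic water
is poor and alkaline water moderate.

```{r catalog}
cat9 <- wq_catalog()
tidy(cat9$alkalinity)
autoplot(cat9$fe)
```

## Rule bases

A rule base must name one output class for each of the 27 antecedent
combinations. The shipped default derives the consequent from the sum of the
three antecedent quality points: sums 0–6 index the seven output classes
VVL, VL, L, M, H, VH, VVH (very, very low … very, very high), triangles with
peaks every 100/6 points on \[0, 100\]. All-poor antecedents land on VVL,
all-good on VVH, and each one-step degradation of any input moves the
consequent down exactly one class. The scheme is monotone by construction,
which the test suite verifies behaviourally (50-point sweeps of every input
must never raise the score by more than 1 point).

Rule tables are data, not code: `wq_rules()` accepts any complete
27-row table, and the YAML configuration (`wq_config_write()` /
`wq_config_read()`) round-trips hand-edited tables, so the derived scheme is
a default, not a constraint.

```{r rules}
head(export_rules(wq_submodel("FWQ1")), 3)
```

## Inference and defuzzification

Inference is classic Mamdani max–min: rule strength is the **min** of the
antecedent degrees (conjunctive rules, clipping implication) and the clipped
consequent triangles are combined by pointwise **max** on a uniformly
discretised output universe (default 1001 points on \[0, 100\], i.e. a 0.1 %
grid — an order of magnitude finer than the 1-decimal reporting precision;
the aggregation error of centroid/bisector halves again at 2001 points,
which the grid-convergence test checks). Five defuzzifiers are available:

* **centroid** — ∫x·f(x)dx / ∫f(x)dx by trapezoidal quadrature,
* **bisector** — the abscissa splitting the area into equal halves, linearly
  interpolated inside the crossing cell,
* **som / mom / lom** — smallest / mean / largest of the maximising set.

Degrees within `1e-6` of the maximum count as maximising; an exact
floating-point test would make the plateau endpoints fragile. An aggregate
with no fired rule is representable (`fuzzy_aggregate()` of an empty table)
but refuses to defuzzify with a "no rule fired" error — under the shipped
models this cannot occur for in-domain inputs because every variable's terms
cover its domain (enforced at construction).

Out-of-domain measurements are **rejected by default**, with the variable
named in the error; the domains define where the model is calibrated, and a
silently clamped pH of 16 would be a data error scored as "alkaline".
`clamp = TRUE` (or `--clamp` on the command line) opts into truncation with
a warning for screening use.

## Calibrated defaults

Two places in the hierarchy are not fixed by the catalog and carry
calibrated defaults, chosen once so that the shipped configuration
reproduces the reference input→score pairs frozen in the acceptance tests
(e.g. FWQ1 at the Rome network averages (435, 7.4, 329) scoring 69.7 % by
centroid, 60 % by SOM; the final model combining (69.7, 84.5, 94.5) into
86.9 %):

* **FWQ3 term breakpoints.** The default sulfate/nitrate/fluoride terms
  break at (150, 250, 300), (60, 100, 120) and (0.6, 1.0, 1.2) mg/L — a
  substantially stricter partition than the generic guideline ranges in the
  catalog. Only this parameterisation reproduces the full reference score
  set for the anion sub-model; the catalog-range construction matches the
  all-good region (it also yields ≈94.4 % at the Rome averages, where a
  single rule fires) but diverges sharply for mixed samples. Both are
  available: `wq_submodel("FWQ3", fwq3 = "catalog")` builds the literal
  catalog version. The calibrated high terms are shoulders, so the full
  catalog domains (up to 800, 180 and 6 mg/L) remain valid inputs.
* **Final-model input terms.** The 0–100 % sub-scores entering FWQ use
  low = (0, 0, 50), medium = (20, 50, 80), high = (40, 100, 100), with
  quality points 0/1/2 (here *high* is the good direction). These
  breakpoints are config-tunable like everything else.

Because the original rule tables are reconstructed rather than copied, the
golden-pair tests use tolerances (±0.5 to ±5 points depending on how tightly
the pair constrains the reconstruction) instead of exact equality.

## Scoring samples

The data-frame-first surface: one row per sample, nine measurement columns
(case-insensitive, `sulphate`/`nitrates`/`iron`/`calcium`/`magnesium`
accepted), sub-scores and final score appended.

```{r score}
rome_sample("rounded") |> wq_score() |> select(fwq1:class)
```

Sub-scores are computed and propagated at full precision; `digits = 1`
rounds only the report. The final class is the output-partition term with
maximal membership at the score, exact ties resolving to the better class.

## The deterministic cross-check: WQI with AHP weights

As an independent, defuzzification-free yardstick, `wq_index()` computes the
classical weighted water-quality index
\(\mathrm{WQI} = \sum_i W_i I_i\) with per-parameter sub-indices
\(I_i = (C_s - C_i) / (C_s - C_{\min})\), where \(C_s\) is the desirable
limit from the catalog and \(C_{\min}\) the best-quality concentration (0
everywhere except pH, whose optimum is 7). Sub-indices are deliberately
**not clamped**: a measurement beyond its limit contributes negatively,
which is informative; `clamp_subindex = TRUE` truncates to \[0, 1\] when a
bounded index is wanted.

Weights come from a Saaty pairwise-comparison matrix via `ahp_weights()`
(column-normalise, then row-average — the simple AHP estimator, which
recovers the priority vector exactly for consistent matrices) with
`consistency_ratio()` as the standard coherence guard (principal eigenvalue,
Saaty's random-index table, warning above 0.1). No authoritative judgment
matrix ships for the nine parameters: the default is equal weights, and
`inst/extdata/ahp_example_synthetic.csv` is a **synthetic illustrative
matrix** (constructed from a plausible health-relevance ranking, CR ≈ 0.008)
— `wq_validate()` results under it are demonstrations, not reference values.
For the Rome averages, three parameters (alkalinity at 435 vs a 200 mg/L
limit, hardness 329 vs 300, calcium 100.6 vs 75) sit beyond their desirable
limits, so the equal-weight
WQI lands far below the fuzzy score; the two scales answer different
questions (regulatory distance-to-limit vs graded expert judgment) and the
comparison is reported side by side rather than forced to agree.

## Synthetic samples

`wq_simulate()` generates seeded reproducible panels: either uniform over
the catalog domains (stress-testing the whole input space) or truncated
normals centred on the Rome network averages with a configurable coefficient
of variation (default 0.15, a typical relative spread for distribution-network
chemistry; sampling is inverse-CDF, so the RNG draw count per sample is
fixed). A `p_out` fraction of samples gets one deliberately out-of-range
value for exercising error paths. The generator emulates the *marginal*
behaviour of network monitoring only: it does not model the strong
geochemical correlations (hardness–calcium–alkalinity co-vary in real
water), spatial structure or seasonal drift, so passing tests say nothing
about multivariate realism — they pin down determinism, domain coverage and
the scoring pipeline under load.

## Problem sizes and limitations

The test suite runs entirely on constructed fixtures: universes of 501–10001
points, 1,000 random aggregates for the defuzzifier-ordering property,
50-point monotonicity sweeps per input, and synthetic panels up to 1,000
samples. Known limitations:

* Only triangular membership functions and conjunctive complete rule bases
  are supported (no Sugeno/TSK inference, product implication, trapezoidal
  or Gaussian terms, rule weights, or type-2 sets).
* The shipped rule bases are a calibrated reconstruction; alternative
  27-rule tables consistent with the same golden pairs exist, and scores for
  mixed-quality samples can differ by a few points between such tables.
* The WQI module's weights are as good as the judgment matrix supplied;
  the equal-weight default is a neutral placeholder, not an expert elicitation.
* Scores address physicochemical quality only — microbiological and
  turbidity parameters are out of scope.
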