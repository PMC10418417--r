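# aquafis

Hierarchical Mamdani fuzzy inference for drinking-water quality assessment.

`aquafis` is for water-quality analysts and environmental-informatics
researchers who need to condense a nine-parameter physicochemical panel
(alkalinity, hardness, pH, Ca, Mg, Fe, fluoride, nitrate, sulfate) into one
interpretable 0–100 % score with a linguistic quality class. Crisp
pass/fail thresholds throw away how close a measurement is to its limit and
how several borderline values compound; fuzzy rules grade both.

## The model

Three 3-input Mamdani sub-models feed a final model:

```
FWQ1(alkalinity, pH, hardness) ─┐
FWQ2(Ca, Mg, Fe)                ├─► FWQ(FWQ1, FWQ2, FWQ3) ─► score + class
FWQ3(sulfate, nitrate, fluoride)┘
```

Each input has triangular *low/medium/high* terms (shoulders at the domain
edges); each model has the complete 3³ = 27 conjunctive rule base, derived
by default from per-term quality points (0 poor / 1 moderate / 2 good): the
consequent class index is the sum of the three antecedent quality points,
mapping sums 0–6 onto the seven output classes VVL, VL, L, M, H, VH, VVH —
triangles with peaks every 100/6 points on [0, 100].

Inference is max–min: rule strength = min of antecedent degrees μ(x)
(clipping implication), aggregation = pointwise max of the clipped
consequents on a 1001-point universe. Five defuzzifiers collapse the
aggregate f(x): **centroid** (∫x·f(x)dx / ∫f(x)dx, trapezoidal quadrature),
**bisector** (equal-area abscissa), and **som/mom/lom** (smallest / mean /
largest of the maximising set).

For cross-validation, the package also computes the deterministic
water-quality index WQI = Σᵢ Wᵢ·Iᵢ with sub-indices
Iᵢ = (Cₛ − Cᵢ)/(Cₛ − C_min) (Cₛ = desirable limit, C_min = best-quality
concentration: 0 except pH = 7), weighted by an analytic-hierarchy-process
(AHP) vector obtained from a Saaty pairwise matrix by column normalisation
and row averaging, with the standard consistency-ratio check.

## Worked example

Score the Rome network-average sample:

```r
library(aquafis)

rome_sample("rounded") |> wq_score(digits = 1)
#>   fwq1 fwq2 fwq3  fwq     class
#> 1   69 84.3 94.2 85.8 very high
```

The carbonate-system sub-model FWQ1 lands at 69 % (alkalinity 435 mg/L and
hardness 329 mg/L are both past their desirable limits, pH 7.4 is ideal),
the cation sub-model FWQ2 at 84.3 % (only calcium is elevated), the anion
sub-model FWQ3 at 94.2 % (sulfate, nitrate and fluoride are all far below
their limits), and the final model grades the water **very high** at 85.8 %.
Individual models and defuzzifiers are directly accessible:

```r
fis_eval(wq_submodel("FWQ1"), c(alkalinity = 435, ph = 7.4, hardness = 329), "som")
#> [1] 59.6
```

The deterministic index tells a harsher story, because three parameters
exceed their regulatory limits and contribute negative sub-indices:

```r
wq_validate(rome_sample("rounded"))[c("fwq", "wqi", "difference")]
#>    fwq   wqi difference
#> 1 85.8 0.356      0.502
```

Other entry points: `wq_surface()` (two-parameter sensitivity grids),
`export_rules()` (rule tables as if–then text), `wq_simulate()` (seeded
synthetic sample panels), `wq_config_write()`/`wq_config_read()` (full model
configuration as YAML), `ahp_weights()`/`consistency_ratio()` (AHP), and
`autoplot()` methods for membership functions and aggregates. A thin
command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "aquafis.R", package = "aquafis"))')" \
  score --alkalinity 435 --ph 7.4 --hardness 329 --ca 101 --mg 19 \
        --fe 0.0118 --sulfate 13.7 --nitrate 3.5 --fluoride 0.14
```

See `vignettes/water-quality-fis.Rmd` for the membership-function
conventions, the calibrated FWQ3 and final-model defaults, and the numerical
choices behind the defuzzifiers.

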