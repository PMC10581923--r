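---
title: "Methods: marker-based digestibility, TSAA algebra and dose-response requirement estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based digestibility, TSAA algebra and dose-response requirement estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrireq)
```

## The scientific problem

Requirement trials for a limiting nutrient feed graded doses to replicate
tanks and read the requirement off the dose at which a response (growth,
feed efficiency, a plasma enzyme, a histological trait) peaks or plateaus.
`nutrireq` implements the full quantitative chain for sulfur amino acid
(SAA) trials in fish: tank metrics, inert-marker digestibility, dose algebra
on three bases, and nonlinear dose-response fitting with analytic optimum
estimation. The reference design is a juvenile giant grouper trial: five
graded methionine levels (9.5–21.5 g/kg DM) at near-constant cysteine
(~4.5 g/kg), plus a taurine-supplemented contrast diet, in triplicate tanks
of 14 fish over 38 days.

## Models and assumptions

### Performance metrics

Weight gain (%), SGR (%/day, log-ratio of final to initial weight over the
trial days) and FCR (feed per unit gain) are computed **at tank level from
tank-mean weights**. This matters: per-fish aggregates of ratios differ from
ratios of means, and published trial tables typically print the former while
only diet-level means are recoverable later. The aggregation level and the
feed-intake basis are recorded in the output's `aggregation` attribute.

Feed intake is used **as fed** by default. The reference trial's daily
digestible-intake table is reproduced exactly on the as-fed basis and not on
a dry-matter basis, which settles an otherwise ambiguous unit question;
`dm_basis = TRUE` applies each diet's dry-matter fraction for users whose
intake records are as-fed but who want DM-basis FCRs.

### Marker-based digestibility

`ADC (%) = (1 − (N_f/N_d)·(M_d/M_f)) × 100` with an indigestible marker M.
The ratio structure makes the formula unit-invariant, so contents in g/kg DM
work identically to percentages. Two deliberate choices:

- **No clipping.** Noisy marker chemistry can push ADCs above 100% or below
  0%. These are retained with a warning, never clipped — silent clipping
  would bias every downstream requirement estimate.
- **Pool-then-compute.** Feces are matched to diets by id; where multiple
  pools exist the caller decides the pooling order. The default convention
  is one pooled sample per diet.

Daily digestible intake divides the daily digestible nutrient mass by the
**geometric body weight** `√(W_i·W_f)` in kg — the standard normaliser for
intake over an interval of exponential growth. The digestibility multiplier
is implemented as ADC/100 (the formula as printed in some sources multiplies
by "ADC (%)", which only works dimensionally after that correction; the
/100 form reproduces the reference intake table exactly).

### TSAA algebra

Two requirement conventions coexist in the SAA literature:
`TSAA[Met + Cys] = Met + Cys` and the methionine-equivalent form
`TSAA[Met] = Met + Cys·(MW_Met/MW_Cys)` with MW 149.21 and 121.16 g/mol
(defaults, configurable via `molecular_weights()`). All chained computations
carry full precision; rounding to one decimal happens only in reports. This
is not pedantry: the reference trial's digestible TSAA of 22.5 g/kg for the
21.5 g/kg diet only emerges from unrounded products (20.253 + 2.264);
chaining printed one-decimal values gives 22.4–22.6 depending on order.

### Dose-response families and analytic optima

Four families are fitted by least squares; each has a closed-form
stationary point, verified in the test suite against a brute-force numeric
optimiser (dense grid plus golden-section refinement) on 1,000 random valid
parameter draws per family at 1e−6 relative tolerance:

- **Power series** `Y = A·x^B + C·x^D`; `x* = (−DC/(BA))^(1/(B−D))`. The
  minus sign belongs inside the radicand — placing it outside, as some
  typesettings do, fails the `dY/dx = 0` check; the implementation asserts
  stationarity numerically after evaluating the formula.
- **Lognormal** `Y = (A/x)·exp(−0.5·(ln(x/gm)/ln(gsd))²)`; mode
  `x* = exp(ln gm − ln(gsd)²)`. The kernel is the standard lognormal-density
  shape consistent with that mode formula (typeset nestings that square the
  whole `ln(gsd)` denominator do not admit a finite interior mode and are
  treated as typographical).
- **Cubic** `Y = b0 + b1x + b2x² + b3x³`; stationary points
  `(−b2 ± √(b2² − 3b1b3))/(3b3)`. Requirement formulas quoted with shifted
  coefficient labels (B2/B3/B4) map onto b1/b2/b3; this mapping is what
  standard calculus gives and is verified by the numeric oracle. The root
  whose curvature matches the stated objective (maximise for SGR, minimise
  for FCR) inside the dose range is reported; both roots and a saddle flag
  are attached.
- **Segmented with gentle connection** — a bent-cable model: two lines
  joined, with the hinge replaced by a quadratic arc of width `blend_width`
  so the first derivative is continuous. The breakpoint is profiled over a
  101-point grid (the other coefficients are linear given the breakpoint)
  and refined with `optimize()`. Default blend width: 10% of the dose span —
  the exact smoothing used by commercial packages is undocumented, so the
  width is exposed as a parameter. A fit that does not improve on a straight
  line is flagged `breakpoint unidentifiable` and returned with equal
  slopes and an `NA` breakpoint rather than an arbitrary interior value.

### Fitting, screening and selection

Nonlinear families are fitted with **profiled linear coefficients** (for
fixed exponents/shape parameters the model is linear in the remaining
parameters), leaving a 2-parameter outer problem solved by Nelder–Mead plus
a BFGS polish from every point of a **deterministic multi-start grid**
(power: B ∈ {0.3, 1, 2, 3} × D ∈ {−2, −1, −0.3, 0.5, 1.5}; lognormal:
geo-mean at the dose quartiles × geo-SD ∈ {1.1, 1.5, 2.5}). No randomness
is involved, so fits are exactly reproducible; the `seed` argument is
recorded for interface stability and used by the bootstrap.

Goodness of fit: SSE, `R² = 1 − SSE/TSS`, `SE = √(SSE/(n−k))`, and for
selection `AIC = n·ln(SSE/n) + 2k` (the least-squares form; the originating
software's exact AIC formula is unpublished). `AICc` is reported as well
because n is 5–18 in these designs. Selection screens out non-converged
fits and fits whose optimum extrapolates beyond the observed dose range,
then takes minimum AIC, breaking ties by fewer parameters, then lower SSE.

Saturated fits (n = k) are permitted — an interpolating cubic on four points
has R² exactly 1 and AIC −∞ — because the exact-recovery tests rely on
them; the stated minimum of k distinct doses follows the family's parameter
count (segmented: 5).

The **taurine contrast diet is excluded by default** from methionine
dose-response fits: it is a taurine arm at replete SAA, not a sixth
methionine level. The rule is automatic (taurine content ≥ 2× the trial
minimum) and overridable via `exclude_diets`.

Bootstrap confidence intervals resample tanks within diets (the
experimental unit), 2,000 replicates by default, percentile interval,
seeded.

## What the synthetic generator emulates — and what it does not

`default_design()` states the reference trial's world: 6 diets (methionine
9.5, 11.6, 14.0, 17.9, 21.5 and the 18.6 g/kg taurine arm), cysteine 4.5
g/kg, marker 1.0 g/kg, 3 tanks × 14 fish, 38 days, initial weights
N(83.9, 8.4) g.

- **True SGR curve**: lognormal with its peak fixed at 15.8 g/kg and peak
  SGR 3.15 %/day. The geometric SD (3.12) was calibrated **once** so the
  curve spans the published diet-mean SGRs (2.83 at the lowest dose to 3.15
  at the peak) — growth responses near the requirement are shallow, and a
  narrow bell would make recovery unrealistically easy.
- **True FCR curve**: broken stick from 0.86 at 9.5 g/kg to a 0.80 plateau
  at 14.6 g/kg, matching the published FCR range and breakpoint.
- **Noise at tank level** (SD 0.09 %/day by default): the tank is the
  experimental unit. The true between-tank SD is unknown — only SEMs of
  pooled-fish means were published — so 0.09 was chosen to reproduce the
  printed SEM scale (~0.05 at n = 3) and is exposed in the design.
- Final weights are back-solved from the drawn SGR, feed intake from the
  true FCR curve, and feces from the prescribed ADCs via exact inversion of
  the marker formula; fish-level weights and livers are decorative draws for
  I/O testing only.
- All streams derive from one master seed by documented sub-seeding;
  identical designs generate byte-identical datasets.

Hence a green recovery test establishes that the pipeline finds the stated
peak under tank-level Gaussian noise of realistic size. It does **not**
establish robustness to intake-dependent noise, non-Gaussian tank effects,
mortality, or ADC measurement error — none of which the generator models.

## Numerical choices

- Optimiser tolerances: Nelder–Mead/BFGS `reltol 1e−14`; breakpoint and
  oracle refinements `optimize(tol = 1e−10..1e−12)`. Noiseless generating
  parameters are recovered to ≤ 1e−6.
- The power-series outer problem penalises |exponents| > 12 and
  `|B − D| < 1e−6` (exactly equal exponents make the inflection undefined).
- Results files are written with 17 significant digits so write/read
  round-trips are exact to double precision; all display rounding is
  report-side.
- ADC inversion (`feces_for_adc`) is algebraically exact; the round-trip
  property is tested to 1e−9 over the full [0, 100] range.

## Known limitations

- **The reference digestible table is internally inconsistent for the
  taurine arm.** Its printed digestible methionine (16.6 g/kg) cannot be
  derived from the composition table (18.6 g/kg) and the ADC table (94.7%),
  which give 17.61; the entire printed column is instead consistent with a
  dietary methionine of 17.6 g/kg. The package computes from the stated
  inputs, so three acceptance expectations covering those cells fail by
  design; every other cell of the digestible and TSAA tables is reproduced
  within ±0.1 g/kg.
- **Published FCR means are not reproducible from published diet means**
  under either intake basis; the per-tank raw data are unavailable. The
  package records the aggregation level rather than resolving this.
- The published breakpoints (15.8, 14.6, 18.9, 14.2 g/kg) and R² values
  (0.52–0.65) derive from unpublished tank/fish-level data. Fitting the six
  printed diet means is a demonstration — it lands at 15.79 g/kg for SGR —
  and the property-based oracle, round-trip and recovery tests substitute
  for exact reproduction.
- Across 100 simulated trials the mean recovered requirement sits ~0.4 g/kg
  below the true peak: AIC occasionally prefers the segmented family, whose
  breakpoint for a smooth unimodal response lies left of the mode — the
  same under-estimation long noted for broken-line analyses. The bias is
  within the stated ±0.5 g/kg recovery band, but users wanting a pure peak
  estimate should restrict `families` to the smooth ones.
- Colorimetry assumes sRGB inputs (IEC 61966-2-1 companding, D65/2°).
  Camera colour-checker calibration is upstream of this package; absolute
  colorimetric accuracy is not claimed, only internal comparability.

## Example

```{r example, eval = FALSE}
trial <- reference_trial()
est <- estimate_requirement(trial$diets, trial$tanks, adc = trial$adc,
                            response = "sgr",
                            basis = c("dietary", "digestible"),
                            fit_level = "diet")
est
```
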