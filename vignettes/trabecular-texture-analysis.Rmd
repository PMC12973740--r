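---
title: "Trabecular texture and radiomorphometric analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular texture and radiomorphometric analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandifrac)
```

# The problem

Trabecular bone in the mandible remodels under systemic influences, and
its radiographic texture — how completely the trabecular network fills
the plane, and how heterogeneous its marrow spaces are — can be
quantified on ordinary panoramic radiographs. This package implements a
complete replica of a three-group observational analysis of that idea:
patients stratified by total serum cholesterol (normal < 5.2 mmol/L,
borderline 5.2–6.2 mmol/L, high > 6.2 mmol/L) are compared on

* **fractal dimension (FD)** and **lacunarity** of 64 × 64 px trabecular
  regions of interest (anterior, premolar, molar mandible),
* **mandibular cortical width (MCW)** and the **panoramic mandibular
  index (PMI)** measured at the mental foramen,

using Kruskal–Wallis tests with Dunn–Bonferroni post-hoc comparisons,
rank effect sizes, and an ANOVA-approximation power analysis.

Because no patient images ship with the package, every claim the test
suite makes is established on synthetic phantoms and cohorts with known
ground truth. The synthetic-data module is therefore first-class code,
not a test convenience: its defaults *are* the study conditions.

# The preprocessing chain

A greyscale ROI is turned into a skeletonized binary trabecular pattern
by the classic duplicate–blur–subtract sequence:

1. **Background estimation**: Gaussian blur with σ = 35 px. On a 64-px
   patch this kernel is wider than the patch, so the blur captures the
   slowly varying brightness caused by soft-tissue and bone thickness
   while averaging out the trabecular texture itself.
2. **Subtraction + offset**: original − blurred + 128, rounded and
   clamped to [0, 255]. Flat regions land exactly at 128.
3. **Threshold at 128**: below → black, above → white.
4. **Opening**: one 3 × 3 binary erosion then dilation of the white
   phase, removing speckle noise.
5. **Inversion**: the analysed foreground becomes the originally-dark
   phase.
6. **Skeletonization**: Zhang–Suen-type 8-connected thinning to a
   one-pixel-wide pattern.

Stage tags on the binary container enforce this order; calling an
operation out of order fails deterministically rather than silently
producing a wrong pattern.

## Numerical choices in the chain

Several details of this chain are conventions that had to be fixed:

* **Threshold ties.** A pixel exactly at 128 is assigned white. After
  step 2, textureless background sits exactly at 128; either convention
  is defensible, but one must be fixed for the chain to be
  deterministic, and the white choice keeps flat background in the
  phase that inversion later removes from the analysed foreground.
* **Gaussian boundary handling.** Symmetric (reflective) padding. With
  σ = 35 on 64-px patches, zero padding would darken every border and
  leak a spurious gradient into the subtraction; under reflection a
  constant patch blurs exactly to itself and total mass is conserved.
  The kernel is truncated at 4σ.
* **Rounding.** Half-away-from-zero to integer grey, then clamping —
  8-bit pipeline fidelity rather than banker's rounding.
* **Morphology at the border.** For erosion, pixels outside the patch
  count as white; for dilation, as black. An all-white patch is then
  stable under opening, and the operator never invents foreground.
* **Thinning.** Zhang–Suen two-subiteration thinning, iterated to a
  fixed point, followed by a deterministic raster-order cleanup of any
  residual 2 × 2 foreground block (re-entering the thinning loop until
  stable). The result is idempotent, never adds pixels, and contains no
  2 × 2 block — the properties the tests assert.
* **Degeneracy.** A patch with no texture (all-white or all-black after
  thresholding or cleaning, or an empty skeleton) is flagged
  `degenerate = TRUE` and excluded downstream; it never yields a silent
  FD value. The foreground fraction after each stage is recorded so the
  phase being analysed can always be audited.

# Fractal dimension and lacunarity

For box side ε the patch is covered by a grid of boxes (partial edge
boxes included) and N(ε), the number of boxes containing foreground, is
counted. The box-counting dimension is the slope of the ordinary
least-squares regression of log N(ε) on log(1/ε). The nine standard box
sizes are 2, 3, 4, 6, 8, 12, 16, 32, 64 px; the regression uses all
configured sizes unweighted, with no automatic scale pruning.

**Grid origins.** Box counts depend on where the grid is anchored. Four
deterministic origins are scanned per size — (0,0), (⌊ε/2⌋,0),
(0,⌊ε/2⌋), (⌊ε/2⌋,⌊ε/2⌋) — and counts are averaged within each size
before the regression. `n_offsets = 1` reproduces the classic
single-origin method, which is what the closed-form fixtures (filled
square → FD 2, straight line → FD 1, Sierpinski carpet → log 8/log 3)
require to hold at machine precision. Offset averaging demonstrably
reduces the variance of FD across random translations of the same
pattern, which is its purpose.

**Lacunarity.** Per grid, λ(ε) = (σ/μ)² over the per-box foreground
masses, *empty boxes included*, with population (not sample) variance;
Λ(ε) averages λ over origins and the summary value averages Λ(ε) over
sizes. Hand-enumerable cases anchor the convention: a translation-
uniform full pattern gives exactly 0 at dividing sizes; a single pixel
among four ε = 32 boxes gives masses {1,0,0,0}, hence λ = 3; a 2 × 2
checkerboard at ε = 2 gives alternating masses {4,0}, hence λ = 1.
Lacunarity is phase-sensitive (a pattern and its complement differ),
which the suite documents. Because the aggregation convention (empty-box
treatment, summary statistic) is not standardized across tools,
absolute lacunarity values are comparable only within one convention;
the in-package closed forms, not external tool outputs, are the
equivalence surface.

FD estimates falling outside [0, 2] due to partial-box noise are
clamped with a warning, never silently.

# Radiomorphometry

MCW and PMI are computed from operator-supplied landmark coordinates
(automatic landmark detection is out of scope): an inferior-border
polyline, the lower edge of the mental foramen, and the endosteal
(inner cortical) margin. The measurement axis is the perpendicular to
the border through the foramen: the foramen is projected onto the
border polyline, the local tangent is fit by total least squares over
the k = 7 nearest border vertices (total rather than ordinary least
squares so the construction commutes with rotation), and the normal is
oriented toward the cortical margin. MCW is the distance along this
axis from the border to the inner margin; b is the foramen-to-border
distance along the same axis; PMI = MCW / b. Whether b should instead
be a point-to-curve minimum distance is not standardized; the
same-axis convention is adopted (they coincide for a locally straight
border) and the tangent neighbourhood is configurable.

All quantities are in pixels. MCW and b are isometry-invariant; PMI is
additionally invariant under uniform scaling — the point of the index,
since panoramic magnification varies between machines. Synthetic
fixtures constructed from chosen (a, b), arbitrarily rotated and
translated, are recovered to well below 0.5 px / 0.01.

# The statistical layer

Group comparisons use the tie-corrected Kruskal–Wallis H (via the base
distribution machinery) with a χ² reference on k − 1 df, and Dunn's
pairwise z tests on pooled mid-ranks with Bonferroni adjustment
(multiplier fixed at the 3 pairwise tests performed). A dataset in
which every observation is identical is defined to give H = 0: the
tie-correction denominator vanishes there, and a constant dataset
carries no group effect.

The effect-size chain is

* rank η² = H / (N − 1),
* Cohen's f = √(η² / (1 − η²)),
* achieved power of a fixed-effects one-way ANOVA with noncentrality
  λ = f²·N, df (k − 1, N − k), at α = 0.05.

**η² convention.** The small-sample-adjusted convention
η²_H = (H − k + 1)/(N − k) is also in common use and gives a visibly
different value at N = 92 (0.046 vs 0.067 for H = 6.104). The package
defaults to H/(N − 1), which is the convention consistent with the
published sensitivity analysis it replicates; the adjusted form is
available via the `convention` argument.

**Power rounding path.** Whether the published power was computed from
f rounded to two decimals or from the unrounded η² is not stated; both
paths are implemented, they agree to ≈0.01 (0.620 vs 0.613 at these
inputs), and the rounded-f path is the default reproduction route.

The age/sex confounding check is an OLS regression of regional FD on
age (years) and a male indicator; recoding sex flips the coefficient
sign but not its p-value, which the suite asserts.

# What the generators emulate — and what they do not

`make_ifs_fractal` produces binary patterns with known dimension: the
depth-4 Sierpinski carpet (FD = log 8/log 3 ≈ 1.8928, exactly 8⁴ cells
on its natural 81-px grid), filled squares, lines, points, strut
lattices and thresholded 1/f^β spectral surfaces. `make_grey_patch`
renders a pattern at two grey levels — the pattern phase dark, so that
after thresholding and inversion the chain's analysed foreground is the
generated pattern itself — then adds a linear illumination ramp
(emulating soft-tissue brightness bias; amplitude in grey levels,
peak-to-peak) and Gaussian pixel noise, clamped to [0, 255]. A
low-order (here linear) surface is the right bias model because the
σ = 35 blur removes exactly such slowly varying components; the suite
shows the estimated FD is unchanged to < 0.15 (in fact exactly, at zero
noise) under ramps up to 60 grey levels.

`make_cohort` draws per-patient regional FD/lacunarity and per-side
MCW/PMI from location-shift models around group medians. Defaults are
the published cohort's structure: sizes 35/33/24, the published group
medians for every variable, age means/SDs and sex ratios per group, and
cholesterol values consistent with the 5.2/6.2 mmol/L cuts. Spreads are
set so the simulated within-group ranges match the published ranges
(e.g. FD SD 0.10 against observed anterior range widths ≈ 0.5 at
n = 35).

**Distributional form.** No distributional form for within-group FD is
recoverable from summary statistics; the choice is a modelling
convention. The package uses the logistic distribution (location =
group median, scale parameterized by SD). The reason is coherence with
the analysis layer's own approximation: the replica's power chain
treats the rank test's power as that of the ANOVA F test. For logistic
errors the rank test's asymptotic efficiency relative to the F test is
π²/9 ≈ 1.10, which at these sample sizes offsets the rank test's
finite-sample power deficit, so a cohort constructed at population
Cohen's f = 0.27 yields an empirical Kruskal–Wallis rejection rate
(≈ 0.64–0.65 over 1000 cohorts) close to the analytic 0.62; under
normal errors the empirical rate is ≈ 0.56, i.e. the generator would
contradict the approximation the analysis itself relies on. Type-I
error is unaffected by this choice (the rank test is distribution-free
under the null).

What the phantoms do **not** emulate: projection geometry, focal-trough
blur, scatter, anatomical superimposition (teeth, cortical borders
inside the ROI), detector noise correlation, or operator variability
in ROI and landmark placement. Passing tests therefore show that the
implementation is faithful to the stated chain and statistics and
robust to the modelled degradations — not that FD on real radiographs
has any particular clinical property.

A note on magnitudes: the skeletonized patterns' FDs on these phantoms
fall in ≈ 1.3–1.6, squarely in the range reported for trabecular bone.
A skeleton is a thin line network, so its dimension is well below that
of the dense pattern it derives from (the 64-px carpet itself measures
≈ 1.73 under offset-averaged counting); comparisons in the suite are
therefore made chain-output against chain-output, never skeleton
against dense pattern.

# Problem sizes

The suite and the workflow scripts use: 64–81 px patches; 16 × 16
patterns for the exhaustive box-count oracle (all sizes and origins,
checked box by box); 2000 replicates for null calibration of the rank
tests (n = 30) and the permutation oracle; 1000 simulated 92-patient
cohorts for the power check; 50 translated copies for the
offset-averaging property; 200–500 replicates for regression
calibration. These sizes put Monte-Carlo error comfortably below the
tolerances asserted and keep a full run in well under a minute.

# Known limitations

* Absolute lacunarity values are convention-dependent (grid origins,
  empty-box handling, summary statistic); only relative comparisons
  within this implementation are meaningful.
* The box-size list mixes dividers and non-dividers of 64; partial edge
  boxes are included by definition here, and excluding them (possible
  via the series columns) changes third-decimal FD values.
* Landmark-based morphometry assumes reasonable polylines; wildly
  self-intersecting borders are not detected beyond the degenerate
  cases that raise errors.
* The cohort generator models variables independently within patients;
  real FD/MCW correlations across regions and sides are not emulated,
  which matters only for analyses that pool across variables (none
  here).
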