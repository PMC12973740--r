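# mandifrac

Trabecular texture and radiomorphometric analysis of panoramic
radiographs: box-counting fractal dimension and lacunarity of
skeletonized trabecular patterns, mandibular cortical width (MCW) and
panoramic mandibular index (PMI) from landmark geometry, and the
nonparametric three-group statistical layer used to compare them across
cholesterol-stratified patient groups.

## What it computes

**Who it is for.** Researchers quantifying mandibular trabecular bone
on ordinary panoramic radiographs — e.g. studying systemic conditions
(here, hypercholesterolaemia: groups split at total cholesterol 5.2 and
6.2 mmol/L) through their radiographic bone signature — and anyone who
needs a validated, scriptable replica of the classic ROI → texture →
group-test pipeline.

**Preprocessing** (`preprocess()`): a 64 × 64 px region of interest is
duplicated and Gaussian-blurred (σ = 35 px) to estimate the soft-tissue
brightness background; the blur is subtracted and 128 added; the result
is thresholded at 128, opened with a 3 × 3 element, inverted, and
thinned to a one-pixel-wide skeleton (Zhang–Suen).

**Fractal dimension** (`box_count()`, `fractal_dimension()`): the
skeleton is covered with grids of boxes of side ε ∈ {2, 3, 4, 6, 8, 12,
16, 32, 64}; FD is the OLS slope of log N(ε) against log(1/ε), with
counts averaged over four deterministic grid origins per size
(`n_offsets = 1` gives the classic single-origin count).

**Lacunarity** (`lacunarity()`): per grid, λ(ε) = (σ/μ)² over per-box
foreground masses (empty boxes included); the summary value averages
over origins and sizes.

**Morphometry** (`mcw()`, `pmi()`): on a line perpendicular to the
inferior mandibular border through the lower edge of the mental
foramen, MCW is the cortical thickness a and PMI = a/b, where b is the
foramen-to-border distance — a magnification-invariant ratio.

**Group statistics** (`kruskal_wallis()`, `dunn_bonferroni()`,
`eta_squared_from_h()`, `cohens_f()`, `anova_power()`,
`compare_all()`): tie-corrected Kruskal–Wallis H with χ²(k−1) p-values,
Dunn's pairwise z tests with Bonferroni adjustment, rank
η² = H/(N−1), Cohen's f = √(η²/(1−η²)), and achieved power of the
one-way ANOVA approximation with noncentrality λ = f²·N.

**Synthetic ground truth** (`make_ifs_fractal()`, `make_grey_patch()`,
`make_cohort()`, `make_landmark_fixture()`): Sierpinski-carpet and
other phantoms with closed-form dimension, radiograph-like renders with
illumination bias and noise, landmark fixtures with constructed MCW/PMI,
and 92-patient three-group cohorts with the published group structure.

## Worked example

```r
library(mandifrac)

# a fractal phantom rendered like a radiograph patch, with a 40-grey
# illumination ramp and pixel noise, then analysed through the chain
g <- make_grey_patch(synth_params(seed = 42, texture_model = "ifs_fractal",
                                  illumination_amplitude = 40, noise_sd = 5))
g
#> <grey_patch 64 x 64, grey range [61, 187]>
analyze_patch(g)
#> <fractal_result fd=1.4328 (R2=0.9935), lacunarity=0.8528>
```

The FD of 1.43 sits in the range typical of skeletonized trabecular
patterns (≈1.3–1.6); R² near 1 says the log–log relation is close to
linear over the nine scales; the lacunarity of 0.85 reflects the
carpet's hierarchical gaps. The estimate is unchanged if the ramp is
removed — the σ = 35 background subtraction absorbs it.

```r
# morphometry on a fixture constructed with a = 12, b = 40
fx <- make_landmark_fixture(seed = 1, a = 12, b = 40)
pmi(fx$landmarks)
#> <morphometry right: MCW=12.00 px, b=40.00 px, PMI=0.3000>

# the sensitivity-analysis chain from published summary inputs
eta2 <- eta_squared_from_h(6.104, 92)
c(eta2 = eta2, f = cohens_f(eta2), power = anova_power(0.27, 3, 92))
#>  eta2      f      power
#> 0.0671 0.2681  0.6198
```

A simulated cohort flows straight into the ten-variable comparison
table (FD and lacunarity × three regions, MCW and PMI × two sides):

```r
cmp <- compare_all(make_cohort(cohort_params(seed = 1)))
cmp[cmp$variable == "fd", c("variable","region_or_side","H","p","eta2","power")]
#>   variable region_or_side    H     p   eta2 power
#> 1       fd       anterior 3.01 0.222 0.0331 0.326
#> 3       fd       premolar 1.19 0.551 0.0131 0.149
#> 5       fd          molar 1.28 0.526 0.0141 0.157
```

## The analysis workflow

Numbered drivers under `analysis/` rebuild the whole study replica from
scratch and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | phantom images, ROI/landmark tables, 92-patient cohort |
| `02_fractal.R`  | closed-form FD fixtures + illumination-invariance table |
| `03_morphometry.R` | MCW/PMI on the landmark tables vs construction truth |
| `04_group_stats.R` | end-to-end `run_study()` + ten-variable comparison + age/sex regression |
| `05_power.R` | effect-size chain and its 1000-cohort simulation check |

Run them in order with `Rscript analysis/01_simulate.R` etc.

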