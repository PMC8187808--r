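---
title: "Measuring and modelling bilateral asymmetry in developing long bones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling bilateral asymmetry in developing long bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteofa)
```

## The scientific problem

Bilaterally symmetric organisms develop their left and right sides from the
same genome under (nominally) the same conditions, so left–right differences
in a paired trait carry information about how well development is buffered
against noise. Three canonical patterns are distinguished by the
distribution of the signed difference $D = R - L$ across a population:

* **Fluctuating asymmetry (FA)** — $D$ normal with mean zero: random
  developmental noise, the classical index of developmental instability.
* **Directional asymmetry (DA)** — $D$ normal with mean $\neq 0$: one side
  systematically larger.
* **Antisymmetry (AS)** — $D$ bimodal: asymmetry is the rule but the larger
  side is random.

`osteofa` implements this framework for paired long-bone measurements taken
from 3D surface models of left/right bones (here: prenatal humeri), with
two traits per specimen: **humeral length** (HL, bone elongation) and
**midshaft cortical thickness** (CT, periosteal diameter, a proxy for
cross-sectional bone deposition). Because elongation (endochondral
ossification at growth plates) and thickening (intramembranous periosteal
deposition) are driven by different morphogenetic pathways, comparing their
asymmetry trajectories across developmental stages tests whether the two
growth dimensions are developmentally decoupled.

## Measurement protocol

Given a closed triangulated surface per side (STL in/out is built in):

1. **Alignment** (`align_to_standard_position()`): the vertex cloud is
   centred and rotated onto its principal axes; the dominant axis (the long
   axis) goes to the third coordinate and the second axis — taken as the
   antero-posterior (AP) axis — to the first. Axis signs are fixed by
   requiring positive skewness of the vertex distribution along the axis,
   with a lexicographic fallback when skewness vanishes (e.g. idealised
   symmetric test cylinders); the remaining axis is the cross product, so
   the transform is always a proper rigid rotation (never a reflection,
   never a scaling). A mesh whose first-to-second eigenvalue ratio is below
   1.05 has no meaningful long axis and is rejected.
2. **Humeral length** (`humeral_length()`): the long edge of the
   axis-aligned bounding box of the aligned model — i.e. the vertex extent
   along the long axis.
3. **Midshaft section** (`extract_midshaft_section()`): intersection of the
   mesh with the plane perpendicular to the long axis at 50% of the
   bounding-box extent. Intersection segments are chained by exact mesh-edge
   identity (no coordinate tolerance is needed on a manifold surface). If
   the plane yields several closed loops, the largest-area loop — the
   diaphyseal outline — is kept and a warning is logged; an empty
   intersection is an error.
4. **Matching symmetry** (`reflect_for_matching_symmetry()`): left and
   right bones are mirror images, so right-side sections are mirrored
   across the AP axis (second in-plane coordinate negated) before
   landmarking; landmark correspondence between sides is then automatic.
5. **Equiangular landmarks** (`place_equiangular_landmarks()`): 16 rays
   from the polygon's *area* centroid (robust to uneven vertex density from
   slicing, unlike the vertex mean) at 22.5° spacing, ray 1 along +AP;
   landmark $i$ is the ray–contour intersection. Landmarks 1 and 9 span the
   AP axis. On a non-star-shaped contour a ray can cross the outline more
   than once; the farthest crossing (the outer, periosteal surface) is used
   and a warning is logged.
6. **Cortical thickness** (`cortical_thickness()`): the mean of the eight
   opposite-pair distances $\lVert p_i - p_{i+8}\rVert$ — the mean
   periosteal diameter.

All coordinates are millimetres; contours are counter-clockwise; angles are
measured counter-clockwise from +AP.

## Asymmetry statistics

For each specimen and trait, with $R$ and $L$ the side values:

$$D = R - L, \qquad a = \frac{R - L}{0.5\,(R + L)},$$

the latter the *size-corrected* signed asymmetry (dimensionless), which
separates instability from growth: a 2% asymmetry means the same thing in a
2 mm embryonic bone and a 9 mm fetal one. The population-level FA magnitude
is the **FA6 index**,

$$\mathrm{FA6} = \operatorname{var}(a),$$

computed with the $n-1$ sample variance (unbiasedness matters at the small
per-stage sample sizes typical of embryonic collections; the source
literature says only "variance").

**Sides ANOVA** (`sides_anova()`): raw trait values are decomposed by the
crossed two-way model `value ~ individual * side`. The individual factor
absorbs size differences; the side main effect tests DA; the
individual-by-side interaction carries FA. F ratios follow the mixed-model
convention, $F_{\mathrm{side}} = MS_{\mathrm{side}} / MS_{\mathrm{int}}$,
and with replicated measurements
$F_{\mathrm{int}} = MS_{\mathrm{int}} / MS_{\mathrm{res}}$. With one
automated measurement per side there is **no error term**: the default
refuses to fabricate one (the interaction row reports no F/p, and FA
magnitude is assessed via FA6 instead), while `paper_mode = TRUE`
duplicates each measurement into two identical replicates to reproduce the
table *structure* of published designs that list a residual line despite
zero measurement error. Only balanced designs are accepted.

**Type classification** (`classify_asymmetry()`), applied to the sample of
signed asymmetries, in order:

1. *Bimodality*: a two-component normal location mixture (shared SD, EM
   fit) against a single normal, compared by BIC. AS requires the mixture
   to win by at least 6 *and* the classical bimodality condition
   $|\mu_2 - \mu_1| > 2\sigma$ (a mixture of closer components is unimodal
   and must not be called AS).
2. *Mean*: one-sample two-sided t test at $\alpha = 0.05$; rejection → DA.
3. *Normality*: Shapiro–Wilk at $\alpha = 0.05$; a normal mean-zero sample
   → FA; a non-normal one → inconclusive.

The source literature names no tests (it argues from probability density
functions); Shapiro–Wilk, the t test and a BIC-compared location mixture
are standard, documented choices. No multiple-testing correction is
applied. Note an inherent property of this rule: under a true FA regime the
two independent $\alpha = 0.05$ gates pass jointly with probability
$0.95^2 \approx 90\%$, so per-class accuracy hovers at that level by
construction — a property of the stated decision rule, not of the
implementation.

## Developmental trajectories

* `per_stage_fa6()` / `stage_series()`: FA6 per ordinal stage, species
  pooled within stage (per-species stratification is available via
  `subset_reanalysis()` but off by default); stages with fewer than two
  specimens are flagged, not computed.
* `fa_stage_anova()`: one-way ANOVA of the *unsigned* $|a|$ on stage. Stage
  is an unordered factor by default; `stage_as = "numeric"` fits the
  single-df linear trend instead (published tables sometimes show stage
  with 1 df, implying the numeric fit, while describing stage as a factor —
  both are exposed, the discrepancy is recorded, not resolved).
* `decoupling_analysis()`: OLS of cross-sectional $|a|$ (CT) on
  longitudinal $|a|$ (HL) across specimens. A flat, non-significant slope
  is the signature of decoupled elongation/thickening pathways.
* `sampling_bias_check()`: OLS of per-stage average $|a|$ (switchable to
  FA6) on the number of specimens and number of species per stage — a
  guard against trajectories driven by uneven sampling. "Average FA" is
  the mean of $|a|$ by default, as the phrase suggests a mean, not a
  variance.

## The synthetic cohort: what it emulates and what it does not

No scan data ship with the package, so `simulate_measurement_table()`
generates cohorts with *known* asymmetry structure. The stated world:

* 10 ordinal prenatal stages, 6 specimens per stage by default (a ~60
  specimen cohort, matching the scale of real embryonic series), 11
  species labels cycled across specimens; uneven per-stage counts are a
  vector away.
* HL grows logistically from ~1 mm to ~9 mm across stages (rapid
  mid-prenatal elongation); CT grows linearly from ~0.17 mm to ~0.8 mm.
  The literature gives no growth equations; these are one-time realistic
  choices for small-bat embryos and both are overridable functions.
* Between-individual size: a shared lognormal multiplier with CV 0.1, so
  the individual term dominates the sides ANOVA as in real data.
* Asymmetry is injected on the **size-corrected scale**:
  $a \sim N(0, \sigma_a^2)$ (FA), $N(\mu_a, \sigma_a^2)$ (DA) or the
  equal-weight mixture at $\pm\mu_a$ (AS), independently per trait by
  default with an optional correlation `rho` (the decoupling test needs
  both regimes); under AS the random side sign is drawn once per specimen
  and shared by both traits. Sides are reconstructed as
  $R = T(1 + a/2)$, $L = T(1 - a/2)$, so recomputing $a$ from the table is
  exact to machine precision and FA6 recovery is exact in expectation.
  Draws with $|a| \ge 2$ (which would imply a non-positive side) are
  resampled with a warning. $\sigma_a$ may be a function of stage for
  stage-varying instability. Default $\sigma_a = 0.05$, i.e.
  $\mathrm{FA6} = 0.0025$.
* Replicates default to 1 with zero measurement error, mirroring automated
  measurement; `sigma_me > 0` adds Gaussian error per replicate for the
  full replicated design.
* Mesh fixtures (`make_bone_mesh()`) are capped star-shaped extrusions
  (circle/ellipse/Fourier sections, arbitrary axial taper, arbitrary rigid
  orientation, mirrored right sides), watertight by construction.

What the generator does **not** emulate: ossification geometry (flanges,
foramina, endosteal cavities), cartilage, segmentation noise, phylogenetic
covariance between species, or staging error. A green end-to-end test
therefore establishes that the measurement chain is geometrically exact on
clean bones, and that the statistics recover known parameters at realistic
n — not that the pipeline is robust to segmentation artefacts.

## Numerical choices and degenerate inputs

* Landmark rays use a $10^{-9}$ slack on the edge parameter so a ray
  through a shared polygon vertex cannot slip between adjacent edges under
  float32 round-off (STL stores single precision).
* If a mesh vertex lies exactly on the section plane, the plane is nudged
  by $10^{-9}$ of the bone length so every intersection is a clean edge
  crossing.
* Default extrusions use an odd number of axial segments so no vertex ring
  coincides with the midshaft plane.
* An all-equal-values ANOVA reports zero sums of squares and no tests; a
  constant regression response reports slope 0 and $R^2 = 0$ rather than
  NaN.
* The EM mixture fit bounds $\sigma \ge 10^{-8}$, caps iterations at 300,
  and canonicalises $\mu_1 \le \mu_2$; degenerate weights terminate early.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; the CLI requires `--seed` for simulation.

## Known limitations

* Only the periosteal (outer) boundary is measured; no endosteal boundary,
  second moments of area, or other cross-sectional properties.
* Only the FA6 index is provided (no FA1–FA5/FA8a, no multivariate
  Procrustes FA); no phylogenetic correction; no kurtosis-based AS test.
* Sides ANOVA accepts balanced designs only.
* The alignment convention (which anatomical direction maps to which axis)
  is a package decision, deterministic but not anatomically registered;
  for matched left/right comparisons this cancels, which is all the
  pipeline needs.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(asym_mode = "DA", mu_a = 0.05, sigma_a = 0.02,
                  replicates = 2, seed = 42)
sim <- simulate_measurement_table(cfg)
sides_anova(sim$table, "hl_mm")
classify_asymmetry(paired_from_table(sim$table, "hl_mm")$a)
stage_series(sim$table)
decoupling_analysis(sim$table)
```
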