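---
title: "sweetdot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweetdot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweetdot)
```

`sweetdot` models a surface-structuring experiment: thaumatin-loaded
cocoa-butter dots are inkjet-printed on chocolate plates in different
spatial arrangements at constant total tastant load, and a trained panel
rates sweetness at three consumption timepoints. This vignette documents
the models behind each stage, the tunable parameters with their units and
defaults, what the synthetic-data generators do and do not emulate, and
the choices made where the design was genuinely open.

## 1. Inks and the constant-load constraint

An ink is 90 %w/w seeded (pre-crystallized) cocoa butter plus 10 %w/w of a
water-in-oil emulsion whose aqueous phase carries the thaumatin. The
effective ink concentration is

$$C_\text{thaumatin} = f_\text{emulsion} \times
  f_\text{thaumatin-in-emulsion},$$

giving 0.09, 0.18, 0.36 and 0 %w/w for inks A–D
(`canonical_inks()`). Composition invariants (fractions in [0, 1], sums
to 1 within 1e−9) are enforced at construction with errors naming the
offending component.

The eight designs keep the deposited thaumatin mass identical by trading
dot count against ink concentration: with a 390 µg drop,
184 × 390 µg × 0.09 % = 92 × … × 0.18 % = 46 × … × 0.36 % = 64.584 µg.
`Bulk` instead disperses the same mass in the 2.34 g plate
(mass fraction 2.76 × 10⁻⁵), and `Layer` coats the full face with the
ink mass of 184 drops of ink A. `tastant_load()` verifies the ledger.

## 2. Canonical pattern layouts

The study reports dot counts and spacing classes, not coordinates, so the
layouts are declared conventions chosen to reproduce every printed
constraint simultaneously:

* **Micro lattice.** A 16 × 12 square lattice, pitch 2 mm, centered on the
  face (footprint 30 × 22 mm), minus the corner cell and its x-neighbor at
  each of the four corners: 184 cells. The checkerboard subset gives
  `SpacedHalf` (92) and the doubled-pitch sublattice `SpacedQuarter`
  (46), preserving the subset chain Quarter ⊂ Half ⊂ Full. With the
  nominal 1.5 mm dot diameter the largest nearest-neighbor edge gap is
  exactly 2.5 mm (`SpacedQuarter`), the printed micro threshold. This
  particular corner trim is the one that makes all three counts exact at
  once.
* **Meso clusters.** `Centered` places 92 ink-B dots in a central block
  and 92 ink-D dots in two bands at the short ends; `Periphery` is the
  inversion. 92 + 92 dots at the no-overlap spacing limit (1.5 mm) cannot
  leave an 8 mm *edge-to-edge* corridor on a 36 mm plate — the cluster
  strips alone occupy ≈ 17 mm of the ≤ 33 mm printable length — so the
  "> 8 mm gap between contrasting dots" is measured center-to-center
  along the long axis (`cluster_gap()`). Clusters are hexagonally packed
  at pitch 1.5 mm (17 rows, margin 1.5 mm) and trimmed to the most
  central cells, achieving an 8.625 mm gap.
* **Scale classification.** A pattern with contrasting clusters more than
  8 mm apart is `meso`; otherwise it is `micro` when the maximum
  nearest-neighbor edge gap over thaumatin-bearing dots is ≤ 2.5 mm;
  dot-free patterns are `none`.

Nominal dot diameter defaults to 1.5 mm, the midpoint of the measured
1.36–1.6 mm range; it only enters edge-gap metrics and overlap checks.

## 3. Rasterization and the print schedule

`render_bitmap()` maps a pattern to a binary bitmap over the full sample
face (white = print). The default pitch of 2 mm/px puts the micro lattice
exactly on pixel centers; meso patterns need a finer pitch (0.25 mm in the
tests) because hexagonal spacing (1.5 mm) is below the default pixel size.
`rasterize()` walks the bitmap line by line, top to bottom, inverting the
scan direction after every *printed* line (empty lines are skipped
without inversion, minimizing travel — the direction invariant is tested
on printed lines only) and firing one valve event per white pixel at the
pixel center.

A drop released from a head moving at $v$ drifts by
$v \cdot H / v_\text{drop}$ during its flight from piston height $H$;
`deflection_correction()` computes this offset (1 mm at the default
50 mm/s, 20 mm, 1000 mm/s) and the schedule stores the actuation position
advanced against the travel direction, so the simulated landing
(`simulate_deposition()`) coincides with the trigger position. The drop
free-flight speed is not a measured quantity; its default (1000 mm/s)
only scales this internally cancelling correction, which is why it is
round-trip-tested rather than value-tested. Valve peak-and-hold timings
(t_p, I_p, t_h, I_h) are carried through the schedule untouched as
placeholders for rig-specific values.

## 4. Dot geometry reconstruction

The image workflow mirrors the two camera views: the **top view** yields
per-dot equivalent-circle radii ($\sqrt{A/\pi} \times$ scale) of
connected components, excluding border-touching (partial) dots; the
**side view** yields the surface profile above a baseline estimated as
the most common per-column surface row (the flat face dominates the
silhouette), and `fit_parabola()` fits $z = c_2 x^2 + c_1 x + c_0$ by
OLS with classical 95% t-intervals (no bootstrap — matching a single
symmetric confidence band; with exactly 3 points the half-widths are
reported infinite). Radius from the top view and vertex height from the
side view is a declared split: it mirrors which quantity each view
measures well.

The dot surface is the paraboloid cap $z = h(1 - \rho^2/a^2)$ with
lateral area

$$S = \frac{\pi a}{6 h^2}\left[(a^2 + 4h^2)^{3/2} - a^3\right],
\qquad S \to \pi a^2 \text{ as } h \to 0.$$

Two numerical choices matter. First, the naive expression cancels
catastrophically for small $h$ (at $h = 10^{-8}$ it returns 3.49 instead
of $\pi$); `paraboloid_area()` therefore evaluates
$\pi a^4/(6h^2)\,\mathrm{expm1}(1.5\,\mathrm{log1p}(4h^2/a^2))$, which is
exact in the flat-disk limit and agrees with adaptive quadrature of
$2\pi\int \rho\sqrt{1+(dz/d\rho)^2}\,d\rho$ to better than 1e−8 across
$a \in [0.1, 2]$, $h \in [0, 1]$. Second, the *lateral* (curved) area is
used for A_pattern, excluding the base disk, because the base is fused to
the plate and only the exposed cap contacts the tongue; the measured
geometry extremes (a = 0.68, h = 0.54 and a = 0.80, h = 0.32 mm) then
give 2.154 and 2.304 mm², spanning the reported 2.15–2.3 mm² area range —
whether that range itself includes the base disk is not stated, and this
consistency is why the lateral-area reading is adopted.

`stimulus_size()` sums lateral area over thaumatin-bearing dots
(per ink for mixed meso patterns; the coated face area for `Layer`) and
multiplies by C_thaumatin. At shared per-dot geometry the product is
identical across all dotted designs — the geometric face of the
constant-load constraint.

## 5. Tongue surface and shear smearing

Papillae are modeled as paraboloid bumps. The shape template is
$z = h_\text{papilla}\,\max(0,\,1 - (x^2+y^2)/r^2)$: a paraboloid of
revolution inverted and scaled so the bump rises to the measured papilla
height at its apex and meets the base at its radius. (The bare
dimensionless bowl $z = x^2/r^2 + y^2/r^2$ cannot produce a bump of the
measured height; the inversion and scaling are this package's reading.)
Defaults: filiform r = 180 µm, h = 195 µm; fungiform h = 390 µm with
r = 400 µm — the fungiform radius is not reported alongside the heights
and 0.4 mm is a mid-literature value, configurable in `papilla_spec()`.

The theoretical filiform number density divides areal coverage fraction
by filiform radius and minimum papilla spacing
(`filiform_number_density()`); "area density" is read as the
dimensionless coverage fraction, which makes the quotient a count per
mm². `place_papillae()` does seeded dart-throwing with a hard minimum
distance (packing failures report the achieved fraction), and
`build_mesh()` samples the field on a regular grid — overlapping papillae
combine by pointwise maximum, not summed heights — with a Nyquist guard
(resolution ≤ half the smallest radius) and triangulated OBJ export.

Oral shearing is reduced to its geometric footprint: each dot's tastant
mass is spread uniformly over a box of full width $2 \times (A/2) =
10$ mm along the oscillation axis (`smear_exposure()`). The box is the
minimal kernel consistent with "spreading restricted by the amplitude";
the kernel site is isolated so triangular or Gaussian alternatives can be
swapped in. Shear velocity (10 mm/s) and normal force (1 N) parameterize
the physical rig and are carried as metadata only. The map extends A/2
beyond the face so mass is conserved to 1e−9. With A/2 → 0 the map
degenerates to the deposit map. The along-axis coefficient of variation
(`exposure_cv()`) operationalizes the blurring argument: the 10 mm band
exceeds every micro gap (≤ 2.5 mm), so `Homogeneous` and `SpacedQuarter`
produce near-identical profiles, while the `Centered` cluster stays
concentrated — CV ≈ 0.57 ≈ 0.62 ≪ 1.50. `region_split()` reports the
anterior/posterior mass fractions about a configurable boundary
(default: map mid-length; the anatomical plane is only approximately
placed), modeling the two tongue regions with distinct afferent nerves.

Dot melting is treated as instantaneous full release; melting kinetics,
lubrication and tongue deformation are out of scope.

## 6. Sensory statistics

`two_way_anova()` implements the mixed design as a linear model with
fixed sample, timepoint and interaction effects plus additive random
blocks for assessor and session, all terms tested against the residual
stratum. The original analysis names the factor roles but not the
error-stratum algebra, so this choice is validated by simulation rather
than matched to an unpublished configuration: under a null panel the
sample-effect type-I error is 0.05 ± 0.015 over 1000 replicates (an
acceptance criterion). Unbalanced tables trigger a warning and Type-II
sums of squares computed from nested-model residual differences.

Tukey HSD runs within each timepoint across samples (matching
per-timepoint figure bars), on the block-adjusted model. Significance
stars default to the four-level convention (p < 0.5 \*, < 0.1 \*\*,
< 0.01 \*\*\*, < 0.001 \*\*\*\*); the figure legends in the source
disagree between a three- and four-level convention (most likely a
typographical slip), so the thresholds are a configurable argument.

`amplification()` is the percent change of a sample mean versus the
reference mean, so "300% amplification" means 4× the reference. The
increase-reading is adopted (the alternative, 3×, is equally compatible
with the phrase "up to 300%"); because the generator fixtures encode the
same convention, the recovery tests are convention-consistent either way.
`fit_stimulus_response()` is plain OLS of mean maximum intensity on
stimulus size with a pointwise 95% confidence band, and
`predict_deviation()` returns standardized residuals to flag off-line
samples such as the hand-coated `Layer`.

## 7. What the synthetic generators emulate — and what they do not

`gen_ratings()` draws a full factorial assessor × sample × timepoint ×
session table: cell mean + Gaussian assessor effect + Gaussian session
effect + Gaussian residual, clipped to [0, 100]. The clipped fraction is
attached as an attribute so calibration runs can exclude saturated
configurations. Defaults: assessor sd 8, residual sd 10, session sd 0 on
the 0–100 scale — chosen once so a 14-assessor panel reaches the
qualitative significance pattern of the study; they are not fitted to
data.

The default cell means are **declared fixtures, not digitized figure
values** (the source reports effect ratios, not bar heights). Micro part
(14 assessors, 6 samples → 504 records): Bulk = (10, 12.5, 10) at
(t_start, t_max, t_end), the four dotted designs = (40, 50, 30) — 4×, 4×,
3× Bulk, encoding the printed 300/300/200% amplifications, anchored at a
dotted t_max of 50, the warm-up maximum-intensity anchor — and Layer =
(25, 32, 20), below the stimulus-size line. Meso part (17 assessors):
Periphery t_max 50, Centered t_max 38 = 0.76 × 50 (the printed 24%
deficit), with Bulk and Homogeneous as in the micro part.

One consequence is worth stating because it shapes the calibration
tests: clipping at 0 inflates the small Bulk reference mean by ≈ 1–3
intensity units, so single-panel amplification estimates center *below*
the nominal 300/200%. The recovery criterion is therefore a Monte-Carlo
interval check — the 95% interval of the estimator across replicate
panels (half-width ≈ ±50–100 percentage points at n = 14, dominated by
the noisy small denominator) must contain the nominal value — not a
point-estimate match. A green test establishes that the estimator is
consistent with the configured effect under the declared noise model; it
does not establish anything about real panel data, which this package
never sees.

`render_dot()` and `render_tongue()` produce two-level images with
optional Gaussian noise and (for dots) a linear illumination gradient,
plus exact ground truth. They emulate contrast and pixelation, not real
photographs: no specular highlights, shadows, staining variability,
out-of-plane tilt or occlusion. Round-trip accuracy criteria (a, h within
2% at ≤ 2% noise; exact papillae counts at zero noise) are claims about
this synthetic world only.

## 8. Numerical and degenerate-input conventions

* Paraboloid area: stable `expm1`/`log1p` form; h = 0 returns the disk.
* Connected components: vectorized iterative minimum-label propagation,
  4-connectivity; labels renumbered in raster order (deterministic).
* Otsu threshold on 256 bins; uniform images raise an error rather than
  return an arbitrary mask.
* Side-view baseline: modal top-row heuristic with the widest contiguous
  protrusion; profiles include one baseline column per side so endpoints
  sit near z = 0.
* Three-point parabola fits report infinite CI half-widths (0 df).
* Dart-throwing placement: deterministic per seed; candidate budget
  1000 × count by default; exhaustion raises a packing error with the
  achieved fraction.
* `dot_distances()` floors edge gaps at 0; patterns with < 2 dots return
  an empty vector, not an error.
* All RNG-consuming functions take an explicit seed and restore the
  caller's RNG state.

## 9. Known limitations

* The micro lattice and meso cluster layouts are conventions consistent
  with every printed count and spacing constraint, not reconstructions of
  the actual print files, which are not public.
* The meso cluster gap is center-to-center along the long axis (see §2);
  an edge-to-edge reading is geometrically unattainable at the stated
  dot counts and no-overlap spacing.
* The Homogeneous and SpacedFull designs are identical under the adopted
  ink assignment (the source is internally inconsistent about ink B vs A
  for SpacedFull; the constant-load reading is followed).
* The smear model is 1-D, mass-conserving and instantaneous; it makes no
  claim about melting kinetics or saliva transport.
* The stimulus-response line's reported R² in the source depends on
  unpublished point values and is deliberately not an acceptance target;
  only the fitting machinery (slope/band/coverage) is validated here.
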