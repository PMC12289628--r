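---
title: "Quantifying soil pore networks and xylem vessels from micro-CT: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying soil pore networks and xylem vessels from micro-CT: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmorph)
```

## The problem

X-ray micro-CT resolves, non-destructively, two water-bearing networks that
matter for shrub water relations in dry grasslands: the pore network of the
soil around the roots (where water is stored and pulled from) and the xylem
vessel network of the stem (where water is transported and where embolism —
gas-filling of a conduit — cuts conductance). `ctmorph` implements the full
desk side of that workflow: segmentation of the material phases in a
grayscale volume, morphometry of the labeled pore space and of its skeleton
graph, per-vessel hydraulic statistics, and the statistical comparisons
across experimental groups. Because raw CT volumes are rarely shipped with a
study, the package carries a synthetic phantom generator whose ground truth
makes every stage testable end to end.

The sections below record the model choices, the tunable parameters with
their defaults and units, and the places where a genuine design decision had
to be made — in enough detail that a maintainer can judge (and revisit) each
one.

## Containers and conventions

A `voxel_grid` is a 3D numeric array of intensities with an isotropic voxel
size in micrometers; **array axis 1 is the vertical (gravity) axis**, so a
"slice" is `v$data[i, , ]`. A `phase_mask` is a logical array of the same
shape naming one material phase. Throughout the package:

* voxels **strictly below** a threshold belong to the darker phase; a voxel
  exactly at the threshold goes to the brighter phase (stated once here,
  applied everywhere);
* connectivity is 26-neighbour for object phases (and 6-neighbour for
  background in topology tests), the common choice for pore networks;
* pores touching the volume border are kept by default
  (`label_components(drop_border = TRUE)` excludes them).

## Segmentation

**Histogram-parabola global threshold.** The intensity histogram of a soil
volume is multimodal: one mode per phase (air < water < root < solid, the
X-ray attenuation ordering). `parabola_threshold()` fits a least-squares
quadratic to the counts inside the inter-mode valley and returns the vertex
abscissa, clipped to the window. A concave fit (no valley curvature) falls
back to the minimum-count bin with a warning; a unimodal or flat histogram is
an error. When no window is given, it is auto-detected as the interval
between the two dominant modes, trimmed by 15% on each side so the fit sees
the valley and not the mode flanks. Mode detection itself runs on a
5-bin-smoothed histogram with a deliberately small prominence floor (0.1% of
the dominant peak): in a soil core of ~2% porosity the pore modes sit two
orders of magnitude below the solid peak. This window heuristic is a
documented choice, not a canonical procedure — per-volume window adjustment
in the original workstation workflow was manual.

**Region growing.** Roots and vessels extend through the slices, so they are
extracted by seeded growth: a FIFO flood through 26-neighbours whose
intensity lies within `tolerance` of the running region mean. The interactive
"magic wand plus repeated expansion/erosion" workflow is operationalized as
growth followed by one binary closing (`segment_by_growth()`); the result is
deterministic for fixed seeds.

**Phase arithmetic.** `and_not(a, b)` is voxelwise `a AND NOT b`; it removes
the pore/root intensity overlap from the pore mask, and implements the
drying logic for vessels: the fully dried stem exposes all lumina, the
natural-state scan exposes only the embolized ones, and
`extract_water_filled_vessels()` subtracts the latter from the former. The
natural mask must be contained in the dried mask up to a 2% tolerance —
beyond that the scans are probably mis-registered and the function stops
(the package performs no registration).

## Pore morphometry

Per 26-connected component, `label_components()` reports volume (voxel count
x voxel volume), a smoothed surface area, the equivalent spherical diameter
$(6V/\pi)^{1/3}$, and the shape factor

$$SF = \frac{S_p^3}{36\,\pi\,V_p^2},$$

which is 1 for an exact sphere. Size classes by equivalent diameter:
micropores $[5, 30)\ \mu m$, mesopores $[30, 80]\ \mu m$, macropores
$(80, \infty)\ \mu m$; below $5\ \mu m$ a pore is sub-resolution and excluded
from summaries. Shape classes: irregular $SF < 0.5$, near-spherical
$0.5 \le SF \le 1$, elongated $SF > 1$ (both boundary values to the middle
class).

**Surface estimator (a load-bearing choice).** By the isoperimetric
inequality no exact surface measure can give $SF < 1$, so the irregular
class ($SF < 0.5$) exists *only* because practical estimators smooth the
surface and under-measure small, rough objects. Voxel-face counting errs the
other way (a sphere's face count is ~1.5x its true surface, pushing every
pore past $SF \approx 3$ and making the sub-unity classes unreachable).
`ctmorph` uses the coarea-formula estimator: Gaussian-smooth the binary
indicator (sigma = 1 voxel, kernel truncated at 4 sigma) and sum the
central-difference gradient magnitude. On analytic solids this reproduces
the behaviour of a smoothed marching-cubes mesh at a fraction of the code: a
sphere of radius 10 voxels gives $SF = 0.97$, a 10:1 cylinder gives 2.80
against the closed-form 2.96, and few-voxel blobs drop below 0.5 — exactly
the regime in which real CT irregular pores live. The price is a known bias:
objects within ~2 voxels of the smoothing length are under-measured, so
`sigma` should stay at 1 voxel unless the application demands otherwise.

**Water.** With a water mask, each component gets its contained water volume
and a water-filled flag (majority of its voxels water). `pwp()` reports
proportions of water-filled pores per size or shape class, volume-weighted
($\sum V_w / \sum V_p$) or number-weighted (count ratio), as percent.

## Skeleton graph and network summary

`skeletonize()` thins a mask to a curve skeleton by sequential
topology-preserving deletion (simple points in the (26, 6) sense, six
directional subiterations, endpoints protected), then merges touching
junction voxels (3+ skeleton neighbours) into nodes and traces branches
between junctions and endpoints. Per branch: actual length $L_t$ as the sum
of voxel steps ($1, \sqrt2, \sqrt3$ x voxel size), chord length $L_i$, and
the chord's angle from vertical folded into $[0^\circ, 90^\circ]$.

Two behaviours are inherited from this algorithm family (the reference
implementations share them) and worth knowing:

* **End erosion.** The rounded ends of a solid tube are thinned away before
  the centerline stabilizes, shortening the skeleton by roughly one radius
  per end. Length-based metrics on stubby objects (aspect below ~10:1) are
  biased accordingly; the hydraulic-radius recovery tests use 20:1 tubes so
  the interior dominates.
* **Degenerate collapse.** A perfectly axis-aligned tube whose axis runs
  *between* voxel centers (even-width cross-section) has no unique medial
  line, and homotopic thinning can contract it almost entirely (scikit-image
  returns zero voxels on the same input). Tilted or noisy-walled structures
  — i.e. everything a scanner produces — are unaffected.

`network_summary()` assembles: number density $ND = N_m/V$, branch density
$BD = n_{branches}/V$, surface-area density $SD = \sum S_p / V$, node
density $NoD = N_n/V$ (nodes = junction clusters; a plain tube has 0), the
$L_t$-weighted mean angle $MA$, coordination number $CN$, hydraulic radius
$HR = \sqrt{V_t /(\pi L_t)}$ (recovering the radius of a cylinder), the
branch-mean tortuosity $L_t/L_i$, porosity, and a connectivity density.
Three printed-formula ambiguities are resolved as follows, each switchable
or documented:

* $CN$ is implemented as branches per node ($n_{branches}/N_n$) — the
  standard meaning of a coordination number; the printed product form
  (branch density x node count) is dimensionally a density times a count
  and is available via `cn_form = "product"` for comparability.
* $MA$ weights branch angles by actual length $L_t$ (the numerator symbol),
  since the printed denominator symbol conflicts with the chord-length
  definition.
* $BD$ counts branches per volume, following the prose definition.
* Connectivity has no formula in the source workflow tables; the package
  defines it as the Euler-based connectivity density
  $(1 - \chi)/V$ with $\chi$ computed on the cubical complex of the voxel
  set. A ball gives 0; each independent loop adds $1/V$.

`root_metrics()` reports the root-phase volume density, surface-area
density, branch/node densities, mean angle, and a mean radius. Branch
volumes are apportioned proportional to branch length, under which each
branch's hydraulic radius equals the network value — so the mean radius is
$\sqrt{V_{root}/(\pi L_t^{total})}$; it recovers a constructed cylinder's
radius within 5%.

## Vessel hydraulics

From a lumen mask, vessels are 26-connected components; the cross-section
area is taken on the mid-slice (mean per-slice area when a component misses
it), $D = \sqrt{4A/\pi}$, and status comes from majority overlap with the
embolized mask. Components spanning under 3 slices or under 10 voxels are
speckle, not vessels, and are dropped with a message.

* **Hydraulic diameter** $D_h = (\sum D^4 / n)^{1/4}$: the uniform diameter
  with the same per-vessel Poiseuille conductance.
* **$D_{95\%}$**: sort descending, accumulate $D^4$ until the running sum
  *first reaches at least* 95% of the total, report the mean of the included
  diameters. The "at least" reading is the implementable version of
  "until it equalled", which is unattainable for generic reals. Note that
  $D_h \le D_{95\%}$ is *not* a theorem (with $D = \{20, 10\}$ both vessels
  are needed for 95%, so $D_{95\%} = 15 < D_h = 17.07$); the provable bounds
  are $\bar{D} \le D_{95\%} \le \max D$, and removing the largest vessel
  never increases it.
* **Conductivity** $K = \sum \pi d_i^4 / (128 \eta)$ with
  $\eta = 1.002 \times 10^{-9}$ MPa s (water, 20 °C) and diameters converted
  to meters internally; the printed equation is followed verbatim (it omits
  the fluid-density factor of the mass-flow form, which cancels in every
  ratio the pipeline reports). $K_s$ sums the embolized subset, $K_n$ the
  water-filled subset, and $K_m = K_s + K_n$ — computed in that order so the
  partition identity is exact in floating point as well.
* `vessel_summary()` adds vessel density (per mm^2 of stem cross-section),
  lumen fraction, the number-based embolism rate (percent of vessels
  gas-filled), and counts per diameter class (default breakpoints 10, 20,
  30, 50 micrometers).

## The synthetic stated world

The phantom generator emulates the two specimen types at their scan
resolutions, and its defaults are fixed once:

| parameter | default | why |
|---|---|---|
| soil voxel size | 6 um | resolution of the soil-core scans emulated |
| stem voxel size | 3 um | resolution of the stem scans emulated |
| phase means (air, water, root, solid) | 30, 90, 120, 180 | attenuation ordering; valleys wide enough for global thresholding, the workflow's own assumption |
| noise sd | 10 | ~4.5 sigma between adjacent modes: visible noise, negligible phase confusion |
| elongated pores | tubes, lognormal radii (median 12 um, sdlog 0.35, clipped 5-40 um), spanning 35-60% of the core, tilted up to 40 degrees from vertical | biopore-like: near-vertical, diameters 10-80 um, the dominant porosity carriers |
| near-spherical pores | spheres, 40-80 um diameter | mesopore class, comfortably above the estimator's smoothing length |
| irregular pores | rough blobs, 12-24 um diameter, irregularity 0.7 | micropores near the resolution floor — the only scale at which SF < 0.5 arises (see surface estimator) |
| saturation | 0.4 | intermediate water condition; varied by the study design |
| vessels | vertical tubes, lognormal diameters (median 22 um, sdlog 0.35, clipped 8-60 um) | concentrates diameters in 10-50 um, the dominant class of shrub stems |
| embolism rate | 0.25 | a mid-range natural-state value; varied by design |

Water is assigned per primitive (a pore is wholly water or wholly air),
smallest diameter first — the capillary ordering: narrow conduits hold water
at lower potential — filling greedily until the next primitive would
overshoot the target water volume. Primitives are placed by rejection
sampling with a clearance gap, so ground-truth components match labeled
components one to one.

What the phantoms deliberately do **not** model: partial voxel filling and
menisci, beam hardening and ring artifacts, root growth geometry, and any
unsaturated-flow physics. A green phantom test therefore establishes that
the measurement chain is correct on crisp-boundary, Gaussian-noise volumes —
not that segmentation is robust to scanner artifacts.

## Statistics layer

Group comparisons follow the classical small-sample design (3 groups x 3
replicates): Shapiro-Wilk normality screening; one-way ANOVA with Fisher's
*protected* LSD — pairwise t tests on the pooled MSE are only interpreted
when the omnibus F is significant at alpha = 0.05, otherwise all groups
share one letter. Letters come from a deterministic insert-and-absorb
compact letter display, assigned from the highest group mean downwards with
ties broken by label order. Pearson correlation matrices carry per-cell
two-sided p values with **no** multiple-testing correction, matching the
per-cell-stars reporting convention of the emulated tables (a documented
choice, not a recommendation). When normality is rejected the pipeline logs
it and proceeds with ANOVA, as the emulated analysis did; a rank-based
fallback can be added by the user at the `anova_lsd()` call site.

`run_study_pipeline()` wires everything together over a factorial design of
water-condition groups, derives one seed per cell from the base seed, logs
every threshold and seed, skips (and reports) failing cells, and writes
byte-reproducible CSV tables.

## Known limitations

* Surface areas (hence SF and SD) carry the smoothing bias described above;
  comparisons across studies should use the same estimator.
* Skeleton lengths on stubby, low-aspect objects are biased short.
* The vessel cross-section is taken per component on one slice; vessels
  merging or splitting along the segment are counted once.
* The TIFF reader covers the uncompressed little-endian grayscale subset
  only.
* No image registration: the natural/dried stem pair must be voxel-aligned.
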