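---
title: "Building and comparing retinal defocus pattern maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing retinal defocus pattern maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retdefocus)
library(dplyr)
```

## The problem

Optical treatments for myopia control — multifocal contact lenses among them
— work by changing the sign and amount of defocus reaching the peripheral
retina. Whether the imposed defocus is *meaningful* for a given wearer
depends on three things at once: the dioptric structure of the environment
being viewed, the wearer's own peripheral refraction, and the lens's in-situ
power profile. `retdefocus` merges these three ingredients into
per-condition retinal defocus maps for a right eye and asks, region by
region, where the conditions actually differ.

The defocus value at a retinal location is modelled as the sum of three
dioptric maps over the central 40° × 40° of field:

* an **environment dioptric-defocus map**: at each field angle, the vergence
  mismatch `1/gaze_distance − 1/object_distance` between the accommodative
  plane and the scene object imaged there;
* the **eye power map**: the negated peripheral-refraction surface,
  interpolated from five measured horizontal meridians;
* the **lens power map**: the lens's effective in-situ profile obtained by
  over-refraction subtraction (a blank, all-zero map for the naked eye).

All maps are 400 × 400 matrices sampled every 0.1°, and all analysis happens
in the retinal frame of a right eye (+x nasal retina, +y superior retina);
visual-field maps are flipped upside down and left-right before stacking.
Positive combined values denote relatively myopic defocus (focal plane in
front of the retina). The inputs never state a sign convention for "defocus",
so this choice is fixed here once and written into every map file's metadata
sidecar.

## Input data and the synthetic generator

Real inputs are repeated-scan tables (spherical equivalent M versus field
angle, five elevations at 0°, ±10°, ±20°, 81 azimuths spanning ±40°, nominally
four scans per fixation — 324 Hartmann-Shack images per fixation) plus scene
maps from an RGB-D/eye-tracking recording. Neither is publicly available, so
the package ships generators for all three input classes:

* `make_scene()` rasterises archetypal indoor scenes (office, corridor,
  living room) as object-distance patches against a background, converts to
  dioptric defocus, smooths at a spatial scale (default 1.5°), and adds
  Gaussian pixel noise. The presets emulate qualitative structure only — a
  near desk plane in the inferior field for the office, a far low-variance
  corridor, mixed patches for the living room; no quantitative claim about
  any real recording is intended or possible.
* `make_shell()` draws repeated scans around a parametric
  spherical-equivalent surface: a central value, a quadratic
  relative-periphery term, a one-sided half-cosine edge ramp over the outer
  20° of the skewed side (reaching `skew_amplitude` at 40°), and a quadratic
  elevation term. The half-cosine shape is a modelling choice; no functional
  form for skewed profiles is prescribed by the data this emulates. Per-scan
  noise defaults to 0.26 D, i.i.d. Gaussian per point — real between-scan
  variability is likely correlated along a scan, which this deliberately
  ignores.
* `make_lens_scans()` adds an analytic lens profile to each naked-eye scan:
  near-centre `c + add·exp(−r²/T²)` and distance-centre
  `c + add·(1 − exp(−r²/T²))` with centre power −0.25 D and high adds
  (2.25 D / 2.50 D), optional decentration, an optional nasal-temporal tilt
  (`asymmetry_amplitude`, reaching its value at ±40° azimuth) emulating the
  systematic asymmetries seen in on-eye profiles, and optional extra
  measurement noise. Because the lens term is added to each naked scan,
  over-refraction subtraction cancels the shared noise exactly — convenient
  for round-trip testing, slightly optimistic about real over-refraction.

Because generated scans carry their class label, classifier recovery, lens
round-trips and the end-to-end analysis are all testable without any
external data. What passing tests show is that the *pipeline* is faithful to
its stated rules; they cannot show that real eyes or rooms look like the
generator.

## Scan filtering and profile classification

`average_scans()` averages the repeats per field angle and flags a point
missing when the sample SD of its repeats exceeds 1 D (`sd_threshold`); a
meridian more than half missing is a quality error. Missing points are
explicit (`NA` + flag), never zero. Before surface fitting they are filled
by linear interpolation along their own meridian only — never across
meridians, since elevations are sparse (five nodes) while azimuths are dense.

`classify_profile()` works on the averaged equator. With `N`, `T`, `C` the
mean refractions over the nasal edge zone (azimuth +20…+40°), temporal edge
zone (−40…−20°) and central zone (±10°), and τ = 0.25 D (one clinical
refraction step — the comparison zones are prescribed but no numeric
criterion for "more positive" is, so τ is this package's choice):

* RPH if `N − C ≥ τ` and `T − C ≥ τ` (both edges relatively hyperopic);
* RPM if `C − N ≥ τ` and `C − T ≥ τ`;
* NPS if `N − C ≥ τ` and `N − T ≥ τ` (nasal edge positively skewed);
* TPS if `T − C ≥ τ` and `T − N ≥ τ`;
* otherwise INDETERMINATE.

Rules are evaluated in that order, so a profile with both edges elevated is
RPH even though it also satisfies the NPS inequalities. Zone *means* are
used rather than single edge points: the edge wording is ambiguous, and
means are robust to the scan filter removing individual angles.

## Surface interpolation

`fit_surface()` builds the 400 × 400 map from the five averaged meridians as
a tensor-product cubic-spline interpolant: a cubic spline along each
meridian's azimuth nodes (cropped to the central ±20°; the outer 20° zones
feed only the classifier), then a cubic spline through the five meridian
values at each output abscissa. The grid is regular, so scattered-data
fitting is unnecessary; the testable contract is exact node reproduction
(< 1e-6 D), i.e. the surface interpolates, it does not smooth. Scan tables
use visual-field angles (nasal/superior positive); the fitted map is in the
retinal frame, so azimuth and elevation are negated on the way in. Pixel
centres sit at half-offsets (±0.05°, …, ±19.95°), strictly inside the ±20°
node span, so the interpolant is never extrapolated.

## Segmentation

`make_region_masks()` partitions the 20° analysis disc into four 5° rings
(half-open at the inner edge, `5(k−1) < d ≤ 5k`, measured at pixel centres)
crossed with four quadrant sectors bounded by the ±45° diagonals and centred
on the superior, inferior, nasal and temporal half-axes — the
corneal-topography convention. Sector bounds are half-open angular intervals
(each sector includes its clockwise diagonal boundary), so each diagonal
pixel belongs to exactly one sector and the four quadrant counts in every
ring are identical by the grid's 4-fold rotational symmetry. Matrix corners
beyond 20° stay in the files but enter no statistic.

Under this frozen convention the innermost regions hold 1965 pixels each and
the outermost 13747 — within 0.21% and 0.08% of the reference averages
(1961, 13737) this rasterization is calibrated against. The counts are
convention-sensitive at the ~2% level (excluding diagonal pixels outright,
for example, drops the inner-ring average to 1930), which is why the
convention is frozen and the counts are asserted in the test suite rather
than left implicit.

## Statistics

Two tracks, both nonparametric because pixel-value distributions are
arbitrary mixtures:

* **Per-meridian point-wise comparisons** (`compare_scan_profiles()`):
  Mann-Whitney U between two conditions' repeats at every field angle,
  with Benjamini-Hochberg FDR within each meridian defining that meridian's
  critical p-value. The U test uses exact enumeration when
  `min(n) ≤ 8` and there are no ties — exactness is cheap there — and the
  tie-corrected normal approximation otherwise (no continuity correction, so
  z is a smooth monotone function of U).
* **Region-wise condition comparisons** (`region_condition_analysis()`):
  for each ring × quadrant region and each combination of the two held-fixed
  factors, a tie-corrected Kruskal-Wallis test across the varying factor's
  levels, then Dunn-type pairwise z statistics on mean-rank differences with
  pooled tie-corrected variance. Familywise control defaults to the
  studentized-range (Tukey-Kramer-on-ranks) criterion — the default
  multiple-comparison convention of the numerical environment this analysis
  style comes from — with Holm and Benjamini-Hochberg as alternatives. The
  effective corrected critical raw p-value is an *output* of the procedure
  (reported per table), never an input.

`benjamini_hochberg()` implements the step-up rule explicitly because its
contract here includes the critical value `(i/m)q`, not just adjusted
p-values; `kruskal.test()` supplies H and p inside `kruskal_wallis()`, with
mean ranks and the tie term computed alongside for the post hoc.

One caveat is reproduced deliberately rather than fixed: pixels are treated
as independent observations (n ≈ 1965–13747 per region), although
neighbouring pixels of an interpolated, smoothed map are strongly dependent.
This pseudo-replication makes the tests anticonservative in absolute terms;
the analysis is meaningful as a *relative* screen across conditions, which
is how its results should be read. A spatial-dependence-aware alternative
(e.g. effective sample sizes or block resampling) is out of scope.

## Numerical and design notes

* Degenerate inputs: all-identical values give H = 0, p = 1 (the tie
  correction would otherwise be 0/0); a zero-variance pairwise SE gives
  z = 0; an empty group, an empty classification zone, or a fully missing
  meridian are errors, not warnings.
* `symmetrize()` mirror-averages each meridian about azimuth 0
  (`s(θ) = (f(θ) + f(−θ))/2`): idempotent, exactly symmetric, preserves each
  meridian's mean. Meridian-wise mirroring (rather than radial averaging)
  keeps the five measured elevations independent; elevation is not
  symmetrized because the asymmetries of interest are nasal-temporal.
* Map algebra is exact: addition is commutative/associative with the blank
  map as identity, the flip is an involution, and interpolation is linear in
  the node values (so the lens map of a sum of profiles is the sum of maps).
* File I/O (headerless matrix CSV + JSON metadata sidecar) round-trips
  values to < 1e-9 D; there is no established interchange format for
  dioptric field maps, hence plain text.
* Only right eyes are modelled; left-eye mirroring, astigmatic (J0/J45)
  component maps and raw wavefront processing are out of scope.

## Problem sizes used in the test suite

The suite regenerates everything from code: classifier recovery uses 100
random shells per class (amplitudes ≥ 2τ, noise ≤ 0.15 D, ≥ 95% recovery
required per class); the rank-test oracles use 500 random small instances
plus 1000 random p-vectors; the familywise-error simulation uses 2000
triples of n = 50 null groups (observed FWER must stay ≤ 0.07 at α = 0.05);
and the end-to-end analysis runs one synthetic subject (office scene, NPS
profile, three optics). The stress configuration for the non-significance
smoke check — asymmetry tilt 3 D, scene noise 1.2 D, lens measurement noise
0.3 D — is deliberately extreme: it makes the asymmetric near-centre lens's
regional mean power cross zero in the nasal mid-periphery, so the naked and
lens conditions genuinely overlap there, while constant-add designs separate
every region.

## Known limitations

The generator's scenes are archetypes, not recordings; per-scan noise is
i.i.d.; on-eye scans share the naked eye's noise realisation; pixel
pseudo-replication is reproduced as-is; and the rasterized region counts are
tied to the documented boundary convention. Conclusions about real lenses or
real eyes require real scan tables, which the reading functions accept in
the same tidy format the generators emit.
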