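---
title: "Mapping the functional organization of a nerve cross-section"
author: "vagusmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the functional organization of a nerve cross-section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagusmap)
```

## The problem

The cervical vagus nerve carries laryngeal, pulmonary and cardiac fibers
in anatomically distinct fascicles.  Spatially selective vagus nerve
stimulation (sVNS) drives current through one of 14 circumferential
electrode pairs of a cuff (2.7 mm inner diameter) and thereby activates
only a sector of the nerve.  Two independent data streams describe where
each functional group sits in the cross-section:

* **tracing arm ("microct")** — fascicle centroids and equivalent radii
  traced from micro-computed tomography, labelled by the organ their
  fibers innervate and by fiber class (afferent / efferent / mixed);
* **stimulation arm ("ephys")** — percent changes of heart rate (HR),
  breathing rate (BR), end-tidal CO2 (EtCO2) and laryngeal EMG RMS
  elicited by each of the 14 pairs.

`vagusmap` turns both streams into maps over one normalized circular
cross-section, aligns them across animals, averages them into atlases,
and quantifies the angular organization — in particular the separation
between the cardiac efferent region (purely cardiac fascicles, the
bradycardia pathway) and the cardiac afferent region (cardiopulmonary
fascicles, the reflex pathway).

## Coordinate conventions

Angles are degrees, measured clockwise from the 12 o'clock direction
with the section viewed from the cranial aspect; a point at angle
$\theta$ and radius $r$ sits at $(x,y) = r(\sin\theta, \cos\theta)$.
Maps are square rasters whose pixel centers tile $[-1,1]^2$ (row 1 at
the top); the nerve occupies the inscribed unit disk, and a pixel
belongs to the disk iff its center does.  Electrode pair 1 is at the
top (0°), pairs increase clockwise at spacing $360/14 \approx 25.7°$.

## The two map constructions

**Fascicle co-registration.**  For a fascicle with centroid $c$ the
nearest pad distance is $d = \min_j \lVert c - p_j \rVert$ (pads $p_j$
on the cuff circle of radius $R_c = 1.35$ mm, nerve centered).  The
projected radial coordinate preserves that distance,

$$ r_{\mathrm{norm}} = \mathrm{clamp}\!\left(\frac{R_c - d}{R_c},\, 0,\, 1\right), $$

while the angular coordinate keeps the fascicle's own angle about the
nerve centroid.  The cross-section is not exactly circular in reality
and the nerve is not exactly centered in the cuff; this projection is
precisely the circularization that anchors every animal to the
electrode geometry.  Keeping the fascicle's own angle (rather than
snapping to the nearest pad's angle, available via `angle = "pad"`)
preserves the circumferential ordering that the sector back-projection
assumes.  Each projected fascicle is rasterized as a filled disk of its
normalized equivalent radius; the group map is the union (binary, 0/1).

**Response back-projection.**  The disk is divided into 14 equal
sectors centered on the pad angles (half-open intervals
$[\alpha_k - w/2, \alpha_k + w/2)$, $w = 360/14$), and pair $k$'s
percent change is written onto every pixel of sector $k$.  Percent
changes come either from monitor-exported tables or from raw traces:
the baseline is the full off-period preceding each on-window; HR, BR
and EtCO2 use window means, EMG uses window RMS.

## Alignment and atlases

The cuff's rotational placement differs between animals and is unknown.
Each animal's four maps are therefore rotated by the negation of the
center-of-mass (CoM) angle of its cardiac efferent map, pinning that
reference at 0°.  Binary maps are rotated nearest-neighbor and
re-thresholded; response maps bilinearly.  The CoM is the
$|$value$|$-weighted centroid of pixel centers, reported in polar form;
absolute values make bradycardic (negative) and tachycardic (positive)
responses reinforce rather than cancel.

Atlases average the aligned maps of a group across animals.  For binary
sources the pixel-wise mean is already the fraction of animals with
that group at that location (0 = none, 1 = all), so no rescaling is
applied; response atlases average magnitudes and are divided by their
maximum so the peak is 1.  Thresholding an atlas (`atlas_support()`,
default $\tau = 0$ for binary sources and $\tau = 0.5$ for response
sources) yields the binary regions used for area fractions (% of disk)
and pairwise overlaps (% of each region's own area).

## Angular statistics

**Separation.**  For two groups, each animal contributes the signed
circular difference of its two CoM angles, wrapped to $(-180, 180]$.
The reported `mean_deg` is the circular mean direction of those signed
differences (its absolute angular value, in $[0,180]$), and `sd_deg` is
the circular SD about it.  A linear mean of *folded* differences in
$[0, 180]$ would be biased downward near a true separation of 180° by
roughly $0.8\,\sigma$; the circular mean is unbiased in direction.  Any
magnitude estimator still loses $O(\mathrm{SE})$ exactly at the 180°
boundary (the absolute value folds the sampling jitter of the *mean*),
which is why noiseless checks give exactly 180 while noisy cohorts
recover it to within a few standard errors.

**ANOVA.**  CoM angles of the four groups are compared by one-way
fixed-effects ANOVA with Tukey–Kramer pairwise comparisons.  Angles are
first unwrapped: within each group, deviations are taken about the
group's circular mean; the group means themselves are then placed on
the branch of the pooled circular mean.  The second step matters —
unwrapping each group in isolation can put two groups on branches 360°
apart when the pooled mean sits near the 0/360 boundary, inflating the
type-I error from the nominal 0.05 to above 0.1.  With branch
anchoring the simulated null rejection rate is ≈ 0.044 (see the test
suite).  A Watson–Williams circular test (omnibus and Holm-adjusted
pairwise) is available via `method = "watson_williams"` as a
sensitivity check.  Note one caveat inherited from the alignment step:
pinning the cardiac efferent CoM at 0° deflates that group's
between-animal variance, so its pairwise comparisons are
anticonservative; results are reported as-is and flagged in the
summary documentation.

**Selectivity.**  A stimulation setting is selective when the target
response is observed on fewer than half of the 14 pairs.  "Fewer than
half" is read strictly (at most 6); the inclusive reading (at most 7)
is available via `max_pairs`.  An "observed" response is a percent
change of at least 5% in magnitude with the physiologically expected
sign (negative for efferent HR, BR and EtCO2; positive for EMG; either
sign for the post-vagotomy HR reflex).  The titration loop multiplies
the amplitude by $1 \pm$ 25% — down while too many pairs respond, up
while none does — and stops at the first amplitude that is selective
with at least one responsive pair.

## The synthetic cohort generator

The generator provides ground-truthed cohorts with the statistical
structure the analysis assumes, so that the full pipeline can be tested
for parameter recovery.  Per nerve it draws:

* per-group fascicle counts from rounded normals floored at 0, with
  means/SDs 1.2±0.5 (cardiac), 10.2±1.8 (recurrent laryngeal),
  10.4±1.9 (pulmonary), 1.4±0.6 (cardiopulmonary), 6±2
  (laryngopulmonary) — 29.2 fascicles per nerve in expectation;
* angular positions from wrapped normals about planted group centers
  (cardiac at 0°, laryngeal at 45°, pulmonary at 180° before rotation;
  cardiopulmonary and laryngopulmonary fascicles are placed about the
  pulmonary center, making the planted cardiac afferent–efferent
  separation 180°), plus one uniform, unknown cuff rotation per animal;
* radial positions uniform in an annulus (0.15–0.9 of the nerve
  radius), with rejection sampling against fascicle-disk overlap.  The
  angle is drawn **once** per fascicle and kept through rejections —
  resampling it would let crowded neighbouring clusters tilt the
  angular distribution and bias the planted separation (we measured
  ≈ 28° of bias with naive resampling).  Clashes are resolved by
  redrawing the radius, then shrinking the fascicle;
* equivalent radii log-normal with median 0.07 mm (sdlog 0.3, cap
  0.15 mm), about 20% total fascicle-to-nerve area — larger medians
  are not packable once ~17 fascicles cluster into the pulmonary
  sector;
* fiber classes from the per-group compositions (purely cardiac
  fascicles are always efferent; cardiopulmonary fascicles
  afferent-dominated);
* a per-animal afferent reflex direction — tachycardia with
  probability 0.6, bradycardia otherwise.  Tachycardia persists after
  double vagotomy (sympathetic arc); bradycardia is abolished
  (left-vagal efferent arc cut).

**Recruitment.**  Fascicle $f$ is activated by pair $j$ iff
$A \ge T \exp(d_{fj}/\lambda)$, with amplitude $A$ (mA), base threshold
$T$ at zero distance (1 mA cardiac efferent, 5 mA cardiac afferent,
0.2 mA laryngeal, 0.8 mA pulmonary), centroid-to-pad distance $d_{fj}$
and decay length $\lambda = 0.4$ mm.  The decay length was set once
from the cuff geometry: the pad-to-nerve-rim gap is ≈ 0.43 mm and
neighbouring pads are ≈ 0.66 mm apart, so $\lambda = 0.4$ mm makes
titration from the protocol's starting amplitudes land on one to three
responsive pairs.  Responses saturate: pair $j$'s noise-free response
is the animal's full-recruitment effect magnitude scaled by the
activated fraction of the target group's total fascicle area.  Effect
magnitudes are drawn once per animal from the observed distributions
(−7.8±3.4% HR efferent; +10.2±5.3% or −5.0±3.1% HR reflex by
direction; −73±21% BR), truncated below at 6.5% so that every animal's
full response clears the 5% observation threshold by at least three
noise SDs — in the emulated protocol a response was identifiable in
every animal, and a frozen sub-threshold draw would otherwise make the
titration loop non-terminating.  Gaussian measurement noise is added
per pair (SD 0.5% for HR — window-averaged heart rate is precise — and
5 / 2 / 5% for BR / EtCO2 / EMG).

**Angular spreads.**  The default placement spreads are per-group:
5° for cardiac, 15° for cardiopulmonary, 25° for the three large
groups.  The tight cardiac cluster reflects that the one or two purely
cardiac fascicles merge from the same branches and appear as a single
compact spot, consistent with the ~0% cardiac afferent–efferent region
overlap; it is also what makes the responsive sectors of a titrated
stimulation contain the planted cardiac angle in ≳ 90% of animals,
given that a 14-pad cuff quantizes angle to ±12.9°.  Recovery tests
that stress the estimator use a single 30° spread for all groups,
passed explicitly.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: non-circular nerve outlines and tissue
deformation between in-vivo and ex-vivo states; fascicle merging and
branching along the nerve; correlated placement beyond the planted
group structure; electrode impedance variation and field spread beyond
the exponential-distance abstraction; beat-to-beat physiological
dynamics (traces are piecewise-constant plateaus with an onset delay).
Recovery of a planted separation therefore validates the estimation
chain, not the anatomy.

## Numerical choices and degenerate inputs

* Default raster 128×128 for cohort fits (256 available; recovery
  simulations use 64, where per-sector pixel counts still match
  $1/14$ of the disk within 1%).
* Rotation resamples nearest-neighbor + re-threshold for binary maps,
  bilinear for response maps; out-of-disk samples read 0.  A rotation
  can wipe a map whose group occupies only a pixel or two; cohort
  pipelines skip such animals rather than propagate an undefined CoM.
* Nearest-pad ties (exact center) break to the lowest pair index,
  with a 1 nm tolerance absorbing floating-point noise of the pad
  coordinates.
* A fascicle nominally outside the cuff clamps to the rim
  ($r_{\mathrm{norm}} \le 1$); a fascicle at the exact center takes
  angle 0°.
* All-zero maps: group maps warn and return zeros; the CoM and the
  alignment reference error out; animals without a cardiac efferent
  reference are excluded from their arm (and reported in the fit).
* Empty regions report their own overlap percentage as `NA`, never 0.
* Cohorts are pure functions of `(config, seed)`.

## Problem sizes in the test suite

The recovery property runs 200 replicate cohorts of 10 animals at grid
64 for each arm; ANOVA calibration uses 2000 simulated null cohorts and
400 power draws; the protocol check titrates 200 animals; oracle
comparisons run on 64-grids with up to 5 fascicles.  These sizes give
standard errors comfortably below the tolerances they are tested
against while keeping the default suite around two minutes.

## Known limitations

Animal is the unit of analysis; no hierarchical modelling of
within-animal correlation across groups is attempted.  The area and
overlap statistics depend on the support threshold $\tau$ for
response-sourced atlases (0.5 by default; the choice is exposed).  The
alignment-induced variance deflation of the reference group is
reported, not corrected.  The package consumes tracing output tables;
it does not read proprietary tracing formats or imaging volumes.
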