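---
title: "Ring-unit morphometry of coronary resistance-artery networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-unit morphometry of coronary resistance-artery networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronet)
```

## The measurement model

The object of study is the network of coronary resistance arteries — the
intramural tree arising at the left anterior descending (LAD) orifice —
exposed in situ, pressure-perfused, and traced from video-microscopic
collages down to roughly 80 µm outer diameter. The tracing yields, for
every numbered vessel segment, an ordered planar centerline with outer
and inner (lumen) diameter at each point. `coronet` treats this traced
tree as its input; image capture, collage stitching and manual tracing
are upstream of the package.

Conventions fixed throughout: all lengths in micrometres; the analysis
plane is the collage plane; the orifice is the coordinate origin, the
X-axis points from the orifice toward the apex and positive Y toward the
left ventricle. Networks are validated on construction: a single root,
acyclic parent links, strictly positive diameters with lumen < outer,
children attached within 5 µm of a parent centerline point (manual
tracing noise allowance), and no traced point under the preparation
cutoff (80 µm by default).

For SWC import the single radius column is read as the *outer* radius and
the lumen is derived from a linear wall model
`inner = outer − 2(a + b·outer)`. This is a package convention, not a
measurement: SWC morphologies carry no wall information, so wall-based
quantities from SWC input inherit whatever wall model the user supplies.
SWC `z` is dropped with a warning, consistent with the planar analysis.

## Ring units

Each segment is divided independently, from its proximal end, into
consecutive ring units of fixed arc length (50 µm). Ring `k` spans arc
`[(k−1)L, kL]`; the trailing remainder shorter than `L` is discarded
(the floor rule — fixed-length units are the point of the construction,
and the discarded length is below `n_segments · L` per network). Rings
are not carried across bifurcations, matching per-segment bookkeeping of
a numbered network.

Each ring's radii are sampled at the ring *centre* by linear
interpolation between the two bracketing traced points. Averaging the
radii over the 50-µm span is a defensible alternative; centre sampling
was chosen as the simplest estimator that is exact under linear taper,
and at 50 µm the two differ only at second order in the taper. The ring
axis is the centerline secant over the ring span, folded to [0°, 180°)
because a ring axis is undirected. Two distances are attached to every
ring: the direct (Euclidean) distance of its centre from the orifice and
the flow distance, i.e. the path length along the unique tree path from
the orifice to the ring centre. Flow distance is always at least the
direct distance, and increases strictly along any root-to-leaf path —
both properties are enforced by tests on generated networks.

## Bifurcation geometry

Every attachment of children to a parent yields one branching record: the
mother lumen radius just proximal to the junction, up to two daughter
lumen radii (the parent's distal continuation counts as a daughter, read
at the next traced point past the junction), and the daughter–mother
axis angles. Axes are centerline secants over a 100-µm window proximal
(mother) and distal (daughters) of the junction; the window, about two
ring lengths, is a smoothing choice against tracing jitter and is not a
measured quantity. The reported angle is
`180° − arccos(u_m · u_d)`: 180° for a daughter continuing the mother's
course, 90° for a perpendicular take-off. A single child joining the
parent's tip is a continuation of the same vessel and is skipped; rare
junctions with more than two daughters are reduced to the two largest,
with a warning.

Murray's law — daughter lumen radii cubed summing to the mother radius
cubed, the shear-equalising optimum — is assessed two ways:

* per junction, the signed log-scale residual
  `log₁₀(r_d1^γ + r_d2^γ) − γ log₁₀ r_m` (zero at exact compliance,
  invariant under uniform rescaling of the radii);
* per network or group, a fitted branching exponent `γ̂`, the minimiser
  over `γ ∈ [1, 6]` (1-D search, tolerance 1e-6) of the *weighted* sum of
  squared residuals with weights `1/(γ²(1 + w₁² + w₂²))`, where
  `w_j = r_dj^γ / (r_d1^γ + r_d2^γ)`.

The weight deserves a comment. Multiplicative (log-normal) measurement
noise on the three radii propagates to the log residual with variance
approximately proportional to `γ²(1 + w₁² + w₂²)`. The unweighted
least-squares exponent therefore prefers smaller `γ` — noise is damped
there — and is biased low by an amount quadratic in the noise scale
(about −0.3 at 5 % radius noise, essentially independent of sample
size). Normalising each squared residual by its noise variance removes
the leading-order bias while leaving the noise-free estimator exact: on
data constructed with any exponent in [2, 4] and no noise, `γ̂` equals
the generating exponent to three decimals, and under 5 % log-normal
radius noise with 200 junctions it is unbiased to within ~0.02 (SD
~0.07). Degenerate inputs — all junctions sharing one asymmetry ratio —
leave the exponent weakly identified and raise a warning.

The angle analysis pairs each daughter's angle with the radius ratio
`r_m/r_d` and reports the Pearson correlation with its two-sided p-value;
zero variance in either variable is an error, not a silent `NA`.

## Spectra and their comparison

Ring-frequency spectra count rings per outer-diameter class. The default
binning has 13 classes centred 100, 150, …, 700 µm, each spanning
`[centre − 25, centre + 25)`; a two-group comparison on fully occupied
spectra then has 12 degrees of freedom. Rings under 75 µm (just below
the preparation cutoff) are dropped with a logged count; rings at or
above 725 µm are pooled into the top class. Boundaries are half-open
upward, so a 325-µm ring belongs to the 350-class.

Group spectra are pooled over animals by summation before the two-sample
χ² homogeneity test (no continuity correction; classes empty in both
groups dropped first). Pooling treats the ring, not the animal, as the
sampling unit: with several hundred rings per heart the test is very
powerful and its p-values cannot be read as animal-level inference. This
pseudo-replication caveat is documented deliberately rather than
"corrected", because the pooled spectrum itself is the quantity of
interest; a mixed-model per-animal comparison is out of scope. The χ²
statistic grows roughly linearly when both groups' counts are scaled by
a common factor — large pooled samples produce large statistics — which
the suite verifies empirically, along with the test's empirical size
(null rejection rate at α = 0.05 within [0.035, 0.065] over 2000
two-multinomial replicates of 700 rings each).

Bidimensional histograms cross the 13 diameter classes with 1-mm
half-open flow-distance bins up to a 25-mm ceiling (network paths rarely
exceed ~20 mm; rings beyond the ceiling are dropped with a logged
count). Marginalising over distance reproduces the diameter spectrum of
the in-range rings exactly.

## Wall-thickness profiles

Wall thickness `(outer − inner)/2` is profiled against the diameter
classes (per-class mean, SEM — undefined for singleton classes — and the
overall wall-versus-diameter Pearson correlation). Group comparison is a
two-way ANOVA of ring wall thickness on group and diameter class with
interaction, followed by per-class Tukey HSD contrasts. Sums of squares
are type II: pooled ring tables are unavoidably unbalanced, there is no
natural factor entry order, and type II is the standard choice in that
setting; on balanced designs it coincides with the textbook
decomposition, which the suite checks against an independent from-scratch
sums-of-squares oracle at 1e-6 relative accuracy. The ring is again the
unit of analysis, with the same pseudo-replication caveat as the
spectra. Classes not occupied in every group are excluded with a
message.

## Echocardiographic formulas

Linear LV dimensions enter in cm, masses leave in g, the mass index in
g/kg body weight: `LV mass = [[(LVEDD + AWTd + PWTd)³ − LVEDD³]·1.04]·0.8
+ 0.14`, fractional shortening `(LVEDD − LVESD)/LVEDD·100`, Teichholz
volume `V = 7.0/(2.4 + D)·D³` (ml), and the ejection fraction from the
Teichholz volumes of LVEDD and LVESD. The additive 0.14 is taken to be in
grams — the standard reading of the cube-formula correction, though unit
annotations for it are customarily omitted; with both wall thicknesses
zero the formula returns exactly 0.14 g for any cavity size, which is
also the package's cheapest end-to-end sanity check. Under these
formulas EF ≥ FS on the whole physiological grid, verified numerically.

## The synthetic generator

`generate_network()` grows planar trees from the orifice along +X:
log-normal segment lengths (median 900 µm, σ_log 0.4), 50-µm centerline
steps with a 3°/step direction random walk, 5 % linear per-segment lumen
taper, and at every segment end a bifurcation whose daughter lumen radii
satisfy `r_d1^γ + r_d2^γ = r_m^γ` exactly (default γ = 3) at an
asymmetry ratio drawn uniformly from [0.4, 1]. Daughter take-off angles
follow `180° − c(r_m/r_d − 1) + N(0, σ_θ)` (c = 25, σ_θ = 10°), clamped
to (60°, 180°], which produces the negative angle–ratio correlation seen
in real networks. Walls follow `w = 8 + 0.06·outer + N(0, 3 µm)`.
Branches end below 80 µm outer diameter or beyond 20 mm flow distance;
trailing sub-cutoff points are pruned so every output passes validation.
The root stem starts at 550 µm outer diameter (500 µm in the female
presets).

Two mechanisms matter beyond these laws:

* **Tracing noise.** The wall-noise scale σ_w is interpreted as the
  contour-reading error of the tracing and applied independently to the
  outer and inner contour of every traced point. The *construction* is
  exactly Murray-compliant; the *recorded* lumina scatter around it, so
  extracted residuals have realistic spread in every group (log-scale SD
  ≈ 0.15–0.19 at defaults) and vanish identically when σ_w = 0.
* **Planar capture loss.** Real in situ video microscopy follows
  branches running near the surface plane; daughters diving into the
  wall are lost to the tracing. The generator omits the smaller daughter
  of each bifurcation with probability `side_loss = 0.62`. This is the
  one calibrated parameter: without it trees carry ~3500–4300 rings,
  with it the median is ~750 rings per network (roughly 300–1600 across
  seeds), the order observed in real preparations. It was fixed once and
  is not adjusted per analysis.

Group presets encode the qualitative remodelling contrasts of a
sex-by-training design. `MEx` raises the wall slope by +0.02 in the
200–500-µm outer-diameter range and enriches 400-µm-class side branches
within 5 mm of the orifice and 200-µm-class branches at 8–13 mm; `FEx`
lowers the wall slope of the largest vessels and inserts a 200–250-µm
population at 5–8 mm; `FSed` carries a far (10–15 mm) small-vessel
cluster. Enrichment twigs are inserted as genuine bifurcations — the
host lumen is stepped down so the branching-exponent relation holds at
twig junctions too — so preset groups remain Murray-compliant and differ
only where they are meant to differ (spectra, wall profiles, spatial
pattern). All randomness flows from one integer seed; cohort seeds are
derived deterministically from a base seed.

What the generator does **not** emulate: hemodynamics and shear-driven
adaptation (Murray compliance is imposed, not emergent), vessel
self-avoidance and tissue boundaries, curvature of the heart surface,
per-animal covariance structure (each network is an independent draw),
collage stitching artifacts, and absolute agreement with any real
cohort's counts. Passing tests therefore demonstrate that the
*measurement pipeline* is correct and well-calibrated on trees whose
ground truth is known — not that any biological claim about real
networks is reproduced.

## Numerical choices and degenerate inputs

* Linear interpolation everywhere a quantity is read at an arc position;
  exact for linear taper.
* Diameter classes and flow bins are half-open upward; ties go to the
  upper bin.
* Exponent search: `stats::optimize` on [1, 6], tolerance 1e-6.
* Zero-variance inputs to correlations raise errors; identical spectra
  give χ² = 0 with p = 1; expected counts below 1 warn but still return
  the statistic; singleton classes report missing SEM; segments shorter
  than one ring length contribute zero rings with a message.
* Attachment tolerance 5 µm; the nearest parent point defines the
  attachment arc position.

Simulation sizes used by the test suite were chosen to make the checks
sharp yet quick: 100 generator seeds for the conservation and ordering
invariants, 2000 replicates for the empirical size of the χ² test and
the Tukey family-wise error rate, 10,000 rings for recovery of an
imposed diameter × distance density (total variation < 0.05), cohorts of
10 networks per group for the preset contrasts, and 200 junctions for
exponent recovery. The whole suite runs in well under a minute.

## Known limitations

* Planar geometry only; genuinely three-dimensional networks are
  projected (SWC `z` is discarded).
* The χ² and ANOVA group comparisons inherit ring-level
  pseudo-replication; treat their p-values as descriptive of the pooled
  material.
* The SWC wall model is a convention, and wall-based results from SWC
  input are only as good as that model.
* Per-junction exponents are not estimated; the fitted γ̂ is a
  population summary and assumes a common exponent across junctions.
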