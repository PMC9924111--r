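---
title: "Field-in-field planning for whole-brain radiotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-in-field planning for whole-brain radiotherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fifplan)
```

## The planning problem

Whole-brain radiotherapy (WBRT) is classically delivered with two parallel
opposed lateral 6 MV fields (gantry 90° and 270°) prescribed 30 Gy in 10
fractions. Because lateral ray paths through the superior and peripheral head
are much shorter than through the midline, normalizing such a plan to brain
coverage leaves *hotspots* — connected regions, mostly in the skull and
scalp, that receive well above the prescription (Rx). Field-in-field (FIF)
forward planning shaves these off: small MLC-blocked subfields are added
inside the main fields, beam weights are re-optimized, and the plan is
renormalized, iterating until the hotspot level reaches an acceptance target.

`fifplan` implements this loop as a self-contained planner. Since clinical CT
data cannot ship with a package, a synthetic head phantom and an analytic
raycast dose engine supply the substrate; both are explicit stand-ins whose
purpose is to reproduce the *qualitative* situation the algorithm faces —
peripheral supra-107% hotspots on a coverage-normalized opposed-lateral plan
— at desk scale.

## The FIF loop

A hotspot is any disconnected volume larger than 1 cm³ receiving at least
107% of Rx (connected components of the supra-threshold body voxels;
26-neighbour connectivity by default so scattered shell fragments merge
realistically). Each iteration:

1. normalize the plan so 99.9% of the brain volume receives 100% of Rx;
2. measure the maximum hotspot percentage $h$ (peak dose of any qualifying
   component, as % of Rx); stop if $h \le 107$;
3. select the block threshold $b = \max(h - 3,\; 107)$ — a fixed decrement of
   3 percentage points of Rx, floored at the target so the last block never
   overshoots into cold spots (a 116% plan blocks the 113% iso-dose volume,
   a 108.5% plan blocks 107%);
4. build one *opposed subfield pair*: the block region (union of all body
   voxels at or above $b$) is projected into the beam's-eye-view (BEV); each
   subfield aperture is the main aperture minus that projection, and the
   opposed member is its left–right mirror, so plans always carry an even
   number of fields;
5. compute the subfield doses from the cached beam transports;
6. re-optimize all beam weights (bounded quasi-Newton, below);
7. renormalize, and accept the iteration only if the hotspot volume (total
   supra-107% body volume, cm³) did not increase — otherwise the pair is
   reverted and the loop stops.

The loop also stops when six subfields have been added (the configured
maximum), and — a case the source procedure does not cover — when a block
region projects entirely outside the aperture (a no-op iteration, reported
with its own stop reason). Every setting (hotspot level, minimum component
volume, decrement, subfield cap, MU floor, coverage, prescription) is
configuration, not code.

Two readings of "the hotspot got bigger" are defensible: total supra-threshold
volume or peak percentage. We treat the volume as authoritative for the
accept/revert decision and log both; in every phantom scenario we exercise,
the peak also decreases monotonically across accepted iterations, and the
test suite asserts both.

## Synthetic head phantom

The phantom is an ellipsoidal soft-tissue body (default semi-axes
80 × 100 × 85 mm) wrapped in a higher-density bone shell (6 mm, 1.6 g/cm³),
enclosing an ellipsoidal brain offset slightly posterior–superior so the
anterior–inferior quadrant has room for two eye spheres with anterior lens
caps, as in a real head. Densities are representative values (air 0, soft
tissue 1.0, bone 1.6 g/cm³), not calibration claims. A low-amplitude seeded
sinusoidal jitter of the body/bone surface (default 2 mm) makes hotspot
components irregular so the connected-component logic is exercised by
realistic shapes; generation is pure — identical spec and seed give identical
voxel output. Masks satisfy, by construction: brain ⊆ body, bone ⊆ body,
lenses ⊆ eyes ⊆ body, eyes ∩ brain = ∅.

Three presets define the study conditions used in the tests:

* **default** — a realistically eccentric adult head; its initial normalized
  opposed-lateral plan carries a substantial peripheral hotspot volume and
  the loop runs to the subfield cap while strictly reducing it.
* **mild** — a small head (66 × 82 × 110 mm) with a thin shell and a brain
  placed well below the skull vertex, so no open ray chord is short enough
  to run very hot; the loop reaches the 107% target within the budget.
* **stress** — a wide head (84 × 102 × 82 mm) with an 8 mm shell; a large
  hotspot volume persists past the subfield cap, exercising that stopping
  rule.

The default grid is 2 mm isotropic — coarser than clinical CT (~1 × 1 × 3 mm)
but fine enough that structure volumes converge to their analytic values
within a percent; the unit-test phantoms use 4 mm for speed. These problem
sizes are the package's own choice of desk scale.

What the phantom deliberately does *not* emulate: real anatomy (gyri,
ventricles, C1/C2, mandible), HU-to-density calibration, CT artefacts, or
couch/immobilization hardware. Passing tests therefore demonstrate the
algorithmic behaviour of the planner — stopping rules, monotone improvement,
coverage preservation, MU and parity contracts — not clinical dosimetric
accuracy on patients.

## Dose engine

Per voxel and field, dose per unit beam weight is

$$D(v) \;=\; O \cdot T(u_v, w_v)\cdot \Big(\tfrac{\mathrm{SAD}}{r_v}\Big)^2 \cdot B(d_v),$$

where $T$ is the aperture transmission at the voxel's divergent BEV
projection (binary, optionally Gaussian-blurred for a soft penumbra;
default off so subset invariants are exact), $r_v$ the distance to the point
source (SAD 1000 mm), and $B$ a depth factor of the *radiological depth*
$d_v$ — the line integral of density along the ray from the source, computed
by a midpoint-rule raycast with trilinear density sampling (1 mm step,
compiled). The depth curve is

$$B(d) = \begin{cases}
\dfrac{1 - e^{-k d / d_{max}}}{1 - e^{-k}} & d < d_{max}\\[4pt]
e^{-\mu (d - d_{max})} & d \ge d_{max}
\end{cases}$$

with build-up depth $d_{max} = 1.5$ cm and steepness $k = 3$, continuous at
$d_{max}$. The saturating build-up matters: a linear ramp would place brain
voxels 10–12 mm under a locally thin surface at ~70% of peak where a real
6 MV beam is already near 96%, manufacturing an artificial cold tail that
the coverage normalization then amplifies into grossly exaggerated hotspots.

The attenuation coefficient defaults to $\mu = 0.028\ \mathrm{cm^{-1}}$.
Because the engine applies inverse-square separately and has no scatter
model, $\mu$ plays the role of the *broad-field tissue-maximum-ratio slope*
of a 6 MV beam (measured TMR tables give ≈ 0.025–0.032 cm⁻¹); the
narrow-beam primary coefficient (≈ 0.046 cm⁻¹) would double-count what
scatter build-up compensates in reality and steepen the opposed-pair profile
far beyond the clinical regime the 3-point decrement schedule is designed
for. Both numbers are engine parameters, not physics claims; the slab tests
exercise the closed form at explicitly chosen $\mu$.

Field doses are cached per aperture and beam transport (depth, inverse
square, projection) per beam geometry, so weight optimization and subfield
addition never re-raytrace. Plan dose is the exact weighted superposition
$D(w) = \sum_i w_i D_i$.

Out of scope by design: Monte Carlo or convolution/superposition transport,
lateral scatter, leaf transmission and interleaf leakage, machine output
factors, wedges.

## Apertures and the MLC

The BEV raster is a 2 mm pixel grid on the isocenter plane, symmetric about
the beam axis. Projection carries each mask voxel center along its source ray
with similar-triangle magnification and sets the nearest pixel; it is
monotone in the mask. The main aperture is the brain projection dilated by a
7 mm flash margin, minus the eye/lens projections — with the rule that target
pixels are never sacrificed to a blocked structure (coverage has priority in
the main field, as in clinical practice) — conformed to an MLC with 5 mm
leaves travelling along the BEV u axis. Conformance is per leaf row by the
over-cover (min–max extent) rule, so the region is always contained in the
realized open area. The opposed beam's aperture is the left–right mirror.

A leaf pair realizes a *single* open interval. When a block projection is
subtracted for a subfield, a row whose interior is hit cannot open on both
sides of the block; the larger remaining segment is kept (tie → left), and
rows covered entirely are closed. This standard MLC constraint is also how
the per-row test oracle is defined.

## Beam-weight optimization and normalization

Weights are optimized with L-BFGS-B (`stats::optim`) under box constraints,
starting from the current plan, with the analytic gradient, minimizing

$$C(w) = \alpha \sum_{v \in \mathrm{brain}} (D_v(w) - Rx)_+^2
       + \beta \sum_{v \in \mathrm{brain}} (Rx - D_v(w))_+^2
       + \gamma \sum_{v \in \mathrm{body\setminus brain}} (D_v(w) - 1.07\,Rx)_+^2 .$$

The defaults are $\alpha = 1$, $\beta = 10$, $\gamma = 1$. Two choices here
were genuinely open and deserve their rationale:

* **The body hotspot term ($\gamma$).** WBRT hotspots live mostly *outside*
  the brain, in scalp and skull. A target-only cost is flat in the
  subfield-weight direction whenever the blocked region does not overlap the
  brain projection, so the solver would never transfer weight into the
  subfields and the loop would be inert. A one-sided penalty above the
  hotspot level over the non-target body — the normal-tissue objective every
  clinical optimizer carries — restores the gradient.
* **Coverage dominance ($\beta = 10$).** With a weak underdose penalty the
  solver happily trades a little coverage for hotspot relief; the subsequent
  renormalization then scales the plan back up and warms the 107–113% band,
  which the volume-acceptance rule correctly rejects. A coverage-dominant
  penalty keeps the renormalization scalar near unity so accepted iterations
  shrink the hotspot monotonically.

The solver never worsens a plan: if it fails or ends above the starting
cost, the starting weights are kept with a warning. Solver settings:
`factr = 1e7`, 200 iterations maximum.

Normalization multiplies all weights by one exact scalar — the target dose
level divided by the coverage quantile of the brain voxel doses (an order
statistic, not an iterative search, so the DVH inverse agrees to within one
0.01 Gy bin). Monitor units follow the linear stand-in
$\mathrm{MU}_i = 100\, w_i$; the optimizer's lower weight bound is the 5 MU
floor divided by that reference. Because a pure global rescale could push a
bound-sitting weight below the floor, normalization projects: violating
weights are pinned at the floor and the remaining free weights are re-solved
(1-D root find) for the same coverage. Renormalization to a lower dose level
(e.g. 99.5% of Rx, within the clinically used band) is the same operation
with a different level.

## Evaluation

Cumulative DVHs use 0.01 Gy bins; $D_x$ and $V_d$ lookups interpolate
linearly between bins and are mutually consistent within one bin. The plan
report carries brain D99%/D95%/D1%, mean eye doses, maximum lens doses
(single hottest voxel by default; a dose-to-small-volume alternative,
e.g. D0.03cc, is a parameter since the maximum-dose convention is not
standardized), the maximum body dose as % of Rx, and V107% both in cm³ and
as a percentage of the brain structure — the brain volume is the reporting
denominator even though detection runs over the body. Maximum *plan* dose
and maximum *hotspot* percentage are reported as separate quantities.

## Numerical and design notes

* Everything is deterministic: the only random element is the phantom
  surface jitter, driven by the seed in `phantom_spec()`; the loop itself
  has none.
* Voxel indices are 1-based (R convention); world coordinates refer to voxel
  centers; grids and masks persist as single-file NIfTI with the affine in
  the sform.
* Degenerate inputs fail loudly and early: empty masks, non-positive
  spacing/SAD/μ, sources inside the mask bounding box, apertures whose open
  area disappears, plans with zero brain dose, config keys that are unknown
  or out of range (validated before any computation). "Normalize by point"
  is exposed in the config schema but deliberately not implemented.
* Ties and floors: block threshold floored at the target level; subfield
  row subtraction keeps the left segment on ties; component labels are
  assigned in raster order so labelling is reproducible.
* The `max_iterations` cap (default `max_subfields / 2`) is exposed
  separately from the subfield cap since the two limits are conceptually
  distinct.

## Known limitations

The dose model has no scatter, no penumbra by default, no leaf transmission,
and an idealized MU chain, so absolute OAR doses (eyes, lenses) are
optimistic compared to a TPS; the phantom is an ellipsoid, so hotspot
*locations* are stylized even though their topology (peripheral
superior/lateral shell fragments) is right. The landmark-based clinical
aperture method is replaced by the dilate-and-block construction above.
Results on the phantoms validate the planner's control logic and contracts,
not patient-level dosimetry.
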