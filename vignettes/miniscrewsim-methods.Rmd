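---
title: "Methods: simulated miniscrew placement and miniscrew-root distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated miniscrew placement and miniscrew-root distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Buccal interradicular miniscrews anchor molar distalization, but the
distalizing root can collide with the screw. The clearance that matters is
not the plain interradicular width: it depends on the screw's insertion
angle, on how deep the screw penetrates buccolingually, and on how the
interradicular corridor changes shape with depth. `miniscrewsim` implements,
as a fully synthetic and testable pipeline, the virtual experiment in which
a tapered 1.5 mm x 6 mm miniscrew is placed 4 mm apical to the
cementoenamel junction (CEJ) at the mesiodistal midpoint of four posterior
interradicular sites (Mx 5-6, Mx 6-7, Mn 5-6, Mn 6-7), tipped vertically at
0, 30, 45 and 60 degrees, and the shortest screw-to-root distance available
for distalization is read off 0.1-mm axial slices.

Patient images for this design are not publicly available, so the package
generates parametric anatomy with the geometric and statistical structure
the analysis assumes, and the whole measurement and statistics chain is
validated against closed forms, an independent sampling oracle, and a
voxel-domain counterpart.

# Coordinate frame and reference line

All computation happens in a standardized occlusal frame: x transverse
(buccal positive in a segment's local frame), y mesiodistal (mesial
positive), z vertical with the occlusal-to-apical direction +z in the
maxilla and -z in the mandible. `build_occlusal_frame()` recovers this
frame from landmarks (an occlusal point set and the mesiobuccal cusps of
the maxillary first molars), mirroring the protocol of aligning the
occlusal plane and the inter-molar line with the scanner axes; recovery is
exact under rigid motions and the measurement is pose-invariant (tested to
1e-6 mm).

All distances are measured parallel to the *posterior reference line*
through the buccal cusps of the first and second molars of the measured
side - the direction along which molars distalize. When a segment only
models teeth 5 and 6, the second-molar cusp landmark is synthesized one
molar width distally; the generator always emits both landmarks.

# Anatomy generator

Each root is a tapered elliptical cone: the cross-section at normalized
depth $t =$ depth/length is an axis-aligned ellipse with semi-axes
$a(t) = a_0 (1 - \tau t)$ and a mesiodistal centerline displacement
$b \cdot 4t(1-t)$ (a quadratic bow peaking at mid-root). Root axes are
vertical in the standardized frame; curvature is expressed through the bow
only. The buccal cortical sheet is a vertical plane (optionally tilted with
depth) at a configurable *ridge offset* buccal to the widest root surface;
total ridge thickness, not a cortical/cancellous split, is what drives the
geometry. Bone extends from the alveolar crest (1.5 mm apical to the CEJ)
past the apices, and far lingually.

No numeric root dimensions or ridge thicknesses are reported for the
original cohort, so the shipped site defaults are plausible literature-scale
values, chosen once so that the *stated qualitative contracts* hold, and
then frozen:

* interradicular width increases with depth at Mx 5-6, Mn 5-6 and Mn 6-7
  (tapered premolar roots, diverging molar roots);
* at Mx 6-7 the corridor is narrowest near mid-root, not at the CEJ or
  apex: nearly cylindrical facing surfaces ($\tau = 0.03$) with strong
  opposing bows ($\pm 1.2$ mm) produce the non-monotone profile. Because
  the quadratic bow accumulates mostly cervically, a gentle taper cannot
  produce a mid-root minimum below the 4-mm insertion level; the
  near-cylinder + bow combination can, at the cost of a wide CEJ-level gap
  (4.4 mm) that narrows to about 2.1 mm mid-root - consistent with the
  clinical picture of a sub-3-mm corridor at this site.

**Facial types.** Subjects are hyper-, normo- or hypodivergent.
`classify_facial_type()` implements the two-rule assignment (S-N/Go-Me
27/37 degrees; S-Go/N-Me 61%/69%; boundaries are normodivergent; discordant
pairs are excluded) and the cohort generator redraws covariates until the
rules agree, mirroring the exclusion rule. Two geometric knobs carry the
facial-type effect, in the mandible only:

* `mandibular_ridge_scale` (0.8 / 1.0 / 1.2): multiplies the Mn buccal
  ridge offset, so hypodivergent screws sit further buccally. This drives
  the angle-dependent part of the facial effect and the noncontact rates at
  60 degrees.
* `mandibular_gap_delta` (-0.18 / 0 / +0.18 mm on the Mn interradicular
  gap). This is a deliberate extension of the parameter set: a screw
  inserted perpendicular to the cortex crosses the whole corridor, so ridge
  thickness alone moves the 0-degree distance only through the screw's
  taper slope (0.075 mm per mm of ridge) - an order of magnitude too weak
  to carry the mandibular ordering that the cohort statistics must recover
  at every angle. Mandibular bone morphology differs globally across
  vertical facial types (the masticatory-muscle argument), not just in
  cortex thickness, and the small gap offset represents that.

Maxillary parameters are identical across facial types, so any maxillary
"effect" in a simulated cohort is sampling noise - which is exactly the
pattern the interaction analysis should flag.

**Variability.** Between-subject anatomy varies per site: interradicular
gap (SD 0.22 mm), ridge offset (SD 0.25 mm), root taper (8% multiplier SD)
and bows (SD 0.10 mm). Left/right segments of a subject share this anatomy
up to a small seeded side jitter (scale 0.06 mm), so paired left/right
analyses are null by construction. These SDs were chosen once to give cell
SDs in the 0.1-0.5 mm range that grow with insertion angle; they are
generator configuration, not estimates. Everything derives deterministically
from one master seed.

What the generator does *not* emulate: real root surface texture,
multi-root furcations (a single facing root per tooth by default), the
maxillary sinus, soft tissue, oblique root axes, and scanner artifacts. A
green trend test therefore establishes that the measurement chain responds
correctly to the modeled geometry - not that the shipped absolute distances
match any clinical population.

# Screw placement

`build_screw()` models the screw as a solid of revolution with a linear
radius profile, 1.5 mm neck diameter, 6 mm length and a 0.6 mm default tip
diameter (taper is not quantified in the protocol; a cylinder mode exists).
Threads are not modeled; the "threaded portion" is the whole shank.
`initial_placement()` puts the head on the cortical sheet 4 mm apical to
the mean CEJ of the two adjacent teeth, at the mesiodistal midpoint between
the facing root surfaces, axis horizontal and pointing lingually.
`angulate()` rotates the axis vertically (tip apically) about the insertion
point, keeping the mesiodistal coordinate unchanged, and re-seats the neck
on the sheet; with a flat vertical sheet the insertion point itself is the
pivot. `check_in_bone()` samples the shank and fails placements that leave
the modeled bone; the unavoidable entry wedge where a tilted shank meets
the flat cortical surface at the head is exempted, since the head is
defined to sit on the surface.

# The measurement

In each axial slice between the apex and the neck (0.1 mm spacing, both
ends included), the screw cross-section and the anterior root cross-section
are compared along the direction $u$ of the posterior reference line
projected into the slice. For each perpendicular offset $v$ (the
buccolingual position within the distalization corridor), both sections cut
the line into intervals; the gap is the distance from the screw's mesial
boundary to the root's distal boundary, and the slice value is the minimum
gap over offsets covered by both sections. The overall distance is the
minimum over slices; ties report the most cervical slice.

Outcomes: `contact` if the screw solid touches either adjacent root
(minimum 3D clearance <= 1e-6 mm, evaluated on a dense grid with local
refinement); `noncontact` if no slice shows any buccolingual overlap with
the anterior root's corridor (the screw is buccally outside the
distalization path and cannot obstruct it); otherwise `measurable` with the
minimum gap in mm.

**Numerics.** The screw is a frustum, so each slice cross-section is a
conic region clipped to an axial slab, and a root section is an ellipse;
both intersect any in-plane line in an interval obtained from a quadratic.
The per-slice minimization over $v$ runs on a 0.05 mm grid followed by a
golden-section search (the gap is convex in $v$: a lower boundary of a
convex region minus an upper boundary of a convex region), which also
resolves the square-root-shaped minima at corridor edges. An earlier design
based on polygonal section approximations at fixed angular resolution was
dropped in favor of this exact interval algebra; the configurable
resolution knob is the offset step `v_step`.

**Verification.** Three independent routes guard the implementation:

* closed forms: parallel-cylinder scenes (exact planar gap in every slice),
  penetration depth $6\cos\theta$, the collinear-circles slice example;
* `brute_force_distance()`: per slice, points on the section boundary are
  generated from the *surface parametrization* (nested low-discrepancy plus
  seeded random angular samples, cap chords included with their rim
  endpoints) and rays are cast toward the root; the minimum converges to
  the measured value from above and never increases when `n_samples`
  doubles. Agreement within 1e-3 mm on 100 seeded random scenes is an
  acceptance criterion;
* `voxel_measure()`: the scene is rasterized (0.1 mm voxels, the scanner's
  resolution scale), the screw is stamped into the volume, and rows of
  voxels parallel to the reference direction are scanned per layer;
  agreement within two voxel diagonals on 20 scenes is an acceptance
  criterion.

# Statistics

Left/right outcomes are averaged per subject x jaw x site x angle: both
measurable -> mean; same non-measurable outcome -> that outcome; one side
measurable -> the measurable value, flagged discordant (undefined in the
original protocol; a contact/noncontact discordance resolves to contact,
flagged). The paired left/right t-test first averages differences within
subject, because one subject's 16 conditions share anatomy and are not
independent units.

Averaged records are coded 0-6: contact 0; (0, 0.5], (0.5, 1], (1, 1.5],
(1.5, 2] and > 2 mm as 1-5 with inclusive upper edges; noncontact 6. Cell
summaries (means/SDs of measurable values, rates above 2 mm, contact and
noncontact rates) mirror the study's output tables; percentages are
rounded half-up to one decimal in the written tables.

`fit_ordinal_gee()` fits the marginal cumulative-logit model
$\mathrm{logit}\, P(Y \le j \mid x) = \theta_j - x'\beta$ by maximum
likelihood (verified against `MASS::polr`) and computes cluster-robust
sandwich covariances with subjects as clusters - generalized estimating
equations with an *independence* working correlation. An exchangeable
working structure was considered and rejected: no ordinal-GEE estimation
routine is available in the target environment, and imposing an
exchangeable correlation on expanded cumulative indicators (which are
deterministically ordered within an observation) models the association
wrongly; independence estimating equations with a robust sandwich remain
consistent and give valid inference. Small-sample behavior is handled a
priori: a CR1 factor $K/(K-1)$ on the meat, t references with $K-1$ degrees
of freedom for coefficients, and F references with $(q, K-q)$ degrees of
freedom for q-degree-of-freedom term tests. Unobserved categories are
collapsed before fitting and recorded; singular information (separation,
empty cells) is reported, never silently dropped. The default model has the
four main effects (facial type, jaw, site, angle - angle and site nominal),
all six two-way interactions, and the sex, mandibular-plane-angle and
facial-height-index covariates; the covariates nearly determine facial type
by construction, so their terms mainly absorb within-group gradients, and
reduced models can be passed as a formula (the type-I simulation uses main
effects only). Direction summaries order the marginal means of the fitted
linear predictor (larger = larger ordinal category).

# What the acceptance suite establishes

1. The 0-6 coding reproduces the printed bins exactly.
2. Measurement and sampling oracle agree to 1e-3 mm on 100 scenes.
3. Closed-form scenes are exact.
4. A default 60-subject cohort shows: distance non-decreasing in angle at
   Mx 5-6, Mn 5-6, Mn 6-7; the 30-degree dip and 45/60-degree rise at
   Mx 6-7; mandibular means ordered hypo > normo > hyper in every cell;
   no consistent maxillary ordering.
5. The ordinal model flags the angle, site and facial-type x jaw effects
   that are built into the geometry, and its facial-type test holds its
   nominal size (within 3 Monte-Carlo SEs at 200 replicates) on reduced
   null cohorts with all facial-type geometry removed.
6. Voxel and analytic measurements agree to two voxel diagonals.
7. The default pipeline yields exactly 60 x 16 = 960 averaged records
   whose category counts are conserved.

# Known limitations

* Absolute distance levels are generator choices; only orderings, trends
  and rates-of-change are meaningful claims.
* Contact events are rare under the default jitter (the corridor must close
  to under the local screw diameter); cohorts tuned for thin Mx 6-7
  corridors exercise the contact path.
* The noncontact/measurable boundary at 60 degrees is knife-edge by nature;
  measurable-only cell means near that boundary are upward-biased
  (survivors sit close to the corridor edge), as in the original design.
* Root axes are vertical; tilted or dilacerated roots are out of scope.
* Only the independence working correlation is implemented.
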