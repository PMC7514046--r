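# miniscrewsim

Simulated interradicular miniscrew placement and measurement of the
miniscrew–root distance available for molar distalization.

## What it is for

Orthodontic molar distalization anchored on buccal interradicular
miniscrews fails when the distalizing root runs into the screw. The usable
clearance depends on the screw's vertical insertion angle, the buccal
ridge thickness, and how the interradicular corridor changes shape with
depth — not just on the two-dimensional interradicular width. This package
implements that virtual experiment end to end for researchers studying
placement strategy:

* a seeded generator of parametric 3D posterior dental segments (two
  adjacent teeth with tapered, optionally bowed root surfaces, a buccal
  cortical sheet, cusp landmarks) and of whole bilateral cohorts stratified
  by vertical facial type (hyper-/normo-/hypodivergent, classified from the
  S-N/Go-Me angle with 27°/37° cutoffs and the S-Go/N-Me index with
  61%/69% cutoffs);
* protocol placement of a tapered 1.5 mm x 6 mm miniscrew: head on the
  cortical bone, 4 mm apical to the CEJ, at the mesiodistal midpoint
  between the roots, angulated 0/30/45/60° to the transverse occlusal
  plane, all of the shank in bone;
* the slice-based measurement: on 0.1-mm axial slices between the screw
  apex and neck, the shortest distance from the mesial screw surface to the
  distal surface of the anterior root **measured parallel to the posterior
  reference line** (the line through the buccal cusps of the first and
  second molars — the distalization direction), minimized over slices.
  Outcomes are a distance in mm, `contact` (screw touches a root), or
  `noncontact` (screw buccally outside the distalization corridor);
* the statistics layer: bilateral averaging, the ordinal 0–6 coding
  (contact = 0; 0–0.5/0.5–1/1–1.5/1.5–2/>2 mm = 1–5 with inclusive upper
  edges; noncontact = 6), summary tables, and a marginal cumulative-logit
  model with subject-clustered (GEE-style, independence working
  correlation) robust inference:
  `logit P(Y <= j | x) = theta_j - x'beta`.

Verification is built in: closed-form scenes, an independent
surface-sampling ray-cast oracle (`brute_force_distance()`), and a
voxel-domain counterpart (`voxelize_segment()` + `voxel_measure()`).

## Worked example

```r
library(miniscrewsim)

## one hypodivergent mandibular 5-6 segment, screw at 0 and 60 degrees
seg <- make_segment("Mn", "5-6", facial_type = "hypodivergent")
for (a in c(0, 30, 45, 60)) print(measure_placement(seg, place_screw(seg, a)))
```

```
<measurement_record> Mn 5-6 right @0 deg: 1.240 mm
<measurement_record> Mn 5-6 right @30 deg: 1.518 mm
<measurement_record> Mn 5-6 right @45 deg: 1.857 mm
<measurement_record> Mn 5-6 right @60 deg: 3.137 mm
```

The clearance grows with the insertion angle: the tip points into the
apically widening corridor and the screw penetrates less deeply through the
thick hypodivergent ridge. (With the subject-level jitter of a full cohort,
a fraction of hypodivergent 60° placements tip past the corridor entirely
and come out `noncontact`.)

```r
## a full 60-subject cohort (20 per facial group), bilateral, 4 sites x
## 4 angles; tables and the ordinal model
res <- run_all(default_config(seed = 20260911), out_dir = "out")
print(res$analysis$gee)
```

```
Ordinal cumulative-logit model, independence working correlation
960 observations in 60 subject clusters; categories: 1 2 3 4 5 6
              term df   wald        p
       facial_type  2  14.14 1.79e-03
               jaw  1  13.07 6.22e-04
              site  1  57.65 2.68e-10
             angle  3 217.10 1.99e-19
               sex  1   0.15 7.04e-01
          mp_angle  1   0.04 8.39e-01
               fhi  1   0.92 3.41e-01
   facial_type:jaw  2  34.10 1.50e-06
  facial_type:site  2   0.80 6.71e-01
 facial_type:angle  6  12.15 7.80e-02
          jaw:site  1 130.49 1.39e-16
         jaw:angle  3  39.73 1.14e-06
        site:angle  3  23.84 1.63e-04
directions:
  facial_type_Mx: normodivergent > hyperdivergent > hypodivergent
  facial_type_Mn: hypodivergent > normodivergent > hyperdivergent
  jaw: Mn > Mx
  site: 5-6 > 6-7
  angle: 60 > 45 > 30 > 0
```

Reading it: distance categories increase with insertion angle
(60 > 45 > 30 > 0) and are larger at the 5–6 than the 6–7 site and in the
mandible; the facial-type effect interacts with jaw — mandibular distances
order hypodivergent > normodivergent > hyperdivergent while the maxilla
shows no consistent ordering (maxillary anatomy does not differ across
facial types in the generator); the cephalometric covariates add nothing
once facial type is in the model. `out/` contains `records.csv`,
`records_bilateral.csv`, `tables/t2.csv` … `t5.csv` (category counts, cell
means ± SD of measurable distances, % > 2 mm, contact/noncontact rates),
`gee.json`, the serialized cohort and a manifest with config, seed and
file digests. A command-line entry point covers the same pipeline:
`inst/exec/miniscrewsim run-all --seed 1 --out-dir out`.

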