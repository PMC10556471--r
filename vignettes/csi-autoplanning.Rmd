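---
title: "Automated craniospinal irradiation planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated craniospinal irradiation planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(csiplan)
```

# The technique being automated

Craniospinal irradiation delivers a uniform prescription (here 23.4 Gy in 13
fractions) to the whole brain and the full spinal axis. The classical
3D-conformal photon technique — still the prevalent approach where IMRT and
protons are unavailable — uses two opposed lateral brain fields matched to
one or more posterior-anterior (PA) spine fields. Three geometric problems
dominate:

* **Junction divergence.** Abutting field edges diverge, so naive matching
  produces hot or cold stripes at the match plane. The brain fields use a
  *half-beam block*: the inferior jaw closes at the central axis, so their
  junction-side edge does not diverge, and the brain isocenter is placed on
  the junction plane. The residual divergence of the spine field's superior
  edge is absorbed by rotating the brain-field collimator by
  $\theta = \arctan(L_{sup}/\mathrm{SSD}_{spine})$, which makes the two edge
  planes coincide along the junction line at the canal depth.
* **Junction error smearing.** Whatever mismatch remains is feathered: the
  plan is delivered as three sub-plans whose junctions sit at
  $\{z_0, z_0+s, z_0+2s\}$, weighted 5, 5 and 3 fractions. Any local junction
  error is diluted by the convex combination — the composite deviation from
  the prescription is provably bounded by the worst sub-plan deviation, an
  invariant the test suite asserts on every generated plan.
* **Field-length limits.** A spinal canal longer than one field allows must
  be split (two matched PA fields with a calculated skin gap) or treated at
  extended SSD, where geometric magnification lengthens the field on the
  patient.

The package automates the pipeline end to end: anatomical pre-checks, field
and MLC construction, spine subfield weighting, feathering, coverage
normalization, and plan evaluation, with a synthetic phantom generator
supplying test anatomy.

# Pre-check rules and their rationale

`runPrecheck()` reduces the anatomy to three measurements and applies fixed
rules:

| Measurement | Rule | Default outcome |
|---|---|---|
| feathering space $g$ (mandible inferior edge to shoulder superior edge) | $g \ge 2$ cm → 1 cm junction spacing; $1 \le g < 2$ → 0.5 cm; $g < 1$ → reject | the three junction shifts span $2s$, so spacing $s$ needs $2s$ of room |
| brain-to-mandible distance | reject strictly above 20 cm | the whole brain must fit one half field; a chin tuck raises the mandible and shortens the distance |
| canal length $L$ | $L \le$ 36 cm → SINGLE; $\le 36 \cdot \mathrm{SSD}/\mathrm{SAD} = 43.2$ → EXTENDED; else MULTIPLE | 36 cm leaves junction margin inside a 40 cm aperture; the extended cap scales with magnification |

Boundary conventions follow the strict inequalities of the flag definitions:
exactly 1 cm of feathering space selects the 0.5 cm junction, and exactly
20 cm passes the half-beam check. The single-field cap and the machine
geometry (SAD 100 cm, extended SSD 120 cm, 0.5 cm leaves) live in
`machineLimits()` and are configurable; the 36 cm default is this package's
declared choice, not a universal constant.

On the head-tilt sign convention: a *larger* chin tuck raises the mandible's
inferior edge and therefore *shortens* the brain-to-mandible distance. The
phantom generator implements exactly that monotonicity
(`head_tilt_deg` up ⇒ distance non-increasing), and the half-beam rejection
consequently catches patients with *insufficient* tilt.

# Field construction details

**Junction placement.** The cranio-spinal junction defaults to the midpoint
of the feather interval minus one junction spacing, which is the unique
placement keeping all three shifts $\{0, +s, +2s\}$ inside the measured
space. Feathered sub-plans are rebuilt at each shifted junction (the brain
isocenter rides the junction plane), so half-beam abutment is exact in every
sub-plan rather than approximated by jaw edits.

**Aperture targets.** Spine MLCs conform to the 1 cm *lateral* expansion of
the canal (leaves travel left-right for a PA field at collimator 0). Brain
MLCs conform to the 1 cm uniform brain expansion *unioned with the
laterally-expanded canal segment superior to the junction*: the cervical
canal between the junction and the skull base belongs to the lateral fields
in this technique, and omitting it would leave a cold gap no normalization
could repair. This union is a deliberate design extension of the bare
"1 cm brain expansion" rule and is isolated in `buildFields()`.

**Two-field matching.** For MULTIPLE configurations the spine-spine match
point is placed 0.5 cm anterior to the canal's anterior surface at the split
plane. Each field's jaw edge is set so its edge *ray* passes through the
match point; the skin gap that opens follows the similar-triangle formula
$G = (d/2)(L_1/\mathrm{SSD}_1 + L_2/\mathrm{SSD}_2)$, which
`computeFieldGap()` exposes and the dose-level tests verify by locating the
50% edge crossings.

**Extended SSD.** Extended fields keep their jaw and MLC definitions at the
isocenter plane but move the source so that the source-surface distance on
the central axis equals the setup SSD; magnification and the inverse-square
output reduction then emerge from the geometry rather than being applied as
corrections.

# The dose model

`beamDose()` evaluates, per voxel,

$$D = w \left(\frac{\mathrm{SAD} + d_{max}}{r}\right)^2 \cdot
      \mathrm{PDD}(d_{\mathrm{eff}}) \cdot F(u, v)$$

* $r$: source-voxel distance; one weight unit delivers 1 Gy at $d_{max}$ on
  the central axis at SSD 100.
* $d_{\mathrm{eff}}$: radiological depth, the density line integral along
  the source ray, ray-marched with a step of half the minimum voxel
  dimension (bounded discretization error; the PDD closed forms reproduce to
  ~0.2% in the tests).
* $\mathrm{PDD}$: linear build-up to 1 at $d_{max} = 1.5$ cm, then
  $\exp(-\mu (d - d_{max}))$ with $\mu = 0.05\ \mathrm{cm}^{-1}$ — plausible
  6 MV values, configurable via `beamModel()`.
* $F$: aperture fluence. Without an MLC it is the product of four
  error-function jaw edges of width $\sigma = 0.3$ cm; with an MLC it is the
  Gaussian-smoothed indicator of the jaw-clipped aperture, computed as a sum
  over leaf tracks of (smoothed track $v$-interval) × ($u$ edge factors).
  The per-track indicators telescope across contiguous tracks, so a leaf
  edge coinciding with a jaw edge is counted once — this matters at the
  half-beam junction, where double-counting would dig a systematic cold
  trough that no feathering could hide. Outside the opening, 2% leaf
  transmission remains.

The model deliberately omits scatter kernels, heterogeneity corrections
beyond the radiological depth, and interface effects: the package's subject
is planning logic, and the model preserves the properties that logic depends
on (divergence, depth falloff, penumbra, transmission), each pinned by a
closed-form test.

# Subfields, weighting, normalization

The canal midline (per-slice canal centroid) is the homogeneity yardstick.
Subfields copy their parent spine beam with leaves closed over the
longitudinal segments whose parent-field midline dose exceeds the in-field
median (first subfield) or lower quartile (second subfield, MULTIPLE
configurations only — nested apertures). `optimizeSpineWeights()` then
minimizes the midline spread (max − min) over subfield weights by bounded
coordinate descent on a 0.01-step grid, at most 50 sweeps, converging when
the spread improves by under 0.1% of the mean parent midline dose; the
optimizer is deterministic, never accepts a worsening step, and matches an
exhaustive grid search on toy midlines.

Normalization proceeds per sub-plan with two scalars: the brain-field scalar
is the smallest value putting *every* brain voxel at or above 95% of the
prescription (so brain V95 is exactly 100% by construction), and the
spine-group scalar the smallest achieving canal V95 ≥ 95%; both are found by
monotone bisection (tolerance $10^{-4}$, two coupling sweeps because each
field group spills a little dose into the other target). Because the three
sub-plans' cold sets differ slightly, the composite canal coverage can dip
below the rule even when every sub-plan meets it; a final common spine
factor, found by the same bisection on the composite, restores it. Brain
coverage needs no such correction: a pointwise guarantee survives convex
combination unchanged.

This "normalize each sub-plan, then composite, then trim" order is a design
choice; normalizing only the composite would also satisfy the rules but
would let individual sub-plans drift from deliverable per-fraction doses.

# The synthetic phantom

`generatePhantom()` assembles stylized geometric primitives — ellipsoids,
boxes and tubes on an LPS grid, head-first supine, superior = increasing
slice — into a body with 18 structures and a density volume (water 1.0,
lung 0.26, bone 1.6 g/cc, optional kidney contrast offset). The planner
consumes only masks and densities, so image texture is out of scope.

The spec parameters are honoured by construction: the canal's occupied-slice
extent equals `canal_length_cm` within one slice, the mandible-shoulder
clearance equals `mandible_shoulder_gap_cm` within one voxel (the
measurement-critical faces are snapped to voxel centres so slice-based
measurements recover them without systematic bias), and head tilt moves the
mandible monotonically. Cohort sampling (`sampleCohort()`) defaults to canal
lengths 25–60 cm, tilts 0–20°, gaps 0.5–4 cm, heights 100–150 cm and slice
thicknesses 1–3 mm — the anatomical spread of a pediatric CSI population;
the pediatric size distribution itself is a package choice, since no public
reference cohort accompanies the technique.

What passing tests on these phantoms shows — and does not show: they
exercise every geometric and dosimetric rule of the pipeline under
controlled anatomy, but they cannot stand in for real patients. Real CT
anatomy brings curved spines (which shift multi-field match points), air
cavities, setup variation and contouring noise that the phantoms do not
emulate.

# Numerical choices and degenerate inputs

* Expansions include voxels tied at exactly the margin distance
  (deterministic and grid-robust). On a voxel lattice the semigroup identity
  `expand(a+b) = expand(expand(a), b)` holds only up to corner voxels that
  cannot be decomposed into two lattice steps; the tests assert containment
  and exact per-axis extents instead.
* BEV footprints rasterize projected voxel *sub-samples* (quarter-voxel
  offsets), so coarse grids still paint every 0.5 cm leaf track; apertures
  pad half a footprint pixel so every projected point is covered.
* Measurements use occupied-slice indices: length = span × slice thickness;
  overlapping mandible/shoulders clamp the feathering space to 0; empty or
  missing masks raise errors naming the structure.
* Structure-name lookup is case-insensitive with a synonym table
  ("SpinalCanal", "cord", singular organ names).
* Junction shifts that would leave the measured feather interval raise an
  error (the pre-check rule makes this unreachable in the pipeline).
* Dmax is the maximum voxel dose; no small-volume convention is applied.
  V95 uses an inclusive threshold, which makes the normalization target
  exactly attainable.

Problem sizes: the tests run most scenarios on 5–6 mm phantom grids, where a
full plan takes a few seconds, and the end-to-end coverage checks on the
default 3 mm grid (~1.4M voxels, ~30 s including three sub-plans and
subfield optimization). These sizes were chosen as the coarsest grids on
which every geometric feature (0.5 cm leaves, 1 cm margins, penumbra) is
still resolved.

# Known limitations

* The dose model's lack of scatter makes heterogeneity ratios and hotspot
  magnitudes unrealistic: normalizing to the coldest brain voxel (partly in
  the build-up region of each lateral field) yields maximum doses well above
  the ~107–110% a clinical system reports. Relative, geometry-driven
  quantities — coverage, junction behaviour, edge positions — are the
  model's reliable outputs.
* Brain subfields (to shrink the hotspot) and physician-preference MLC edits
  (cribriform coverage versus lens sparing) are intentionally absent.
* The multi-field technique assumes a straight canal when propagating the
  match point across feathered sub-plans.
* No DICOM-RT import/export; volumes travel as NIfTI, plans as JSON.
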