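# csiplan

Automated 3D-conformal treatment planning for pediatric craniospinal
irradiation (CSI), as an R package.

CSI treats the whole brain and the full spinal axis with abutting photon
fields, and is among the most demanding plans to produce by hand: two opposed
lateral brain fields must be matched without couch rotations to one or more
posterior-anterior (PA) spine fields, the match line must be *feathered*
(shifted between fractions) to smear out junction dose errors, and spine
subfields must be weighted to flatten the dose along the canal. `csiplan`
automates that workflow end to end for the classical 6 MV technique, and is
aimed at medical-physics research and teaching: every stage — anatomy checks,
field construction, dose, feathering, normalization, evaluation — is an
exported, testable function, exercised on synthetic pediatric phantoms so no
patient data is ever needed.

## The planning model

Given a labeled structure set (binary masks on a regular LPS voxel grid) and
a co-registered density volume, the pipeline is:

1. **Anatomical pre-check.** The spinal-canal longitudinal extent *L* selects
   the spine configuration: one isocentric PA field (*L* ≤ 36 cm), one
   extended-SSD field at 120 cm source-surface distance (*L* ≤ 36 · SSD/SAD
   = 43.2 cm), or two matched PA fields. The mandible-shoulder clearance *g*
   sets the junction spacing *s* (*g* ≥ 2 cm → *s* = 1 cm; 1 ≤ *g* < 2 cm →
   *s* = 0.5 cm; *g* < 1 cm → rejected), since the three feathered junction
   positions {z₀, z₀+s, z₀+2s} span 2*s*. A brain-to-mandible distance over
   20 cm rejects the patient: the brain no longer fits a half-beam block.
2. **Fields.** Lateral brain beams (gantry 90°/270°) with the inferior jaw
   closed at the central axis (half-beam block, so the junction edge does not
   diverge) and the collimator rotated by θ = atan(L_sup/SSD_spine) to
   parallel the spine field's diverging superior edge. MLC apertures conform
   to the 1 cm uniform brain expansion (plus the laterally-expanded cervical
   canal above the junction) and to the 1 cm lateral canal expansion, fit
   per 0.5 cm leaf track in the beam's eye view. For two spine fields, the
   match point is placed just anterior to the canal and the fields open a
   skin gap G = (d/2)(L₁/SSD₁ + L₂/SSD₂) so their edges abut at depth *d*.
3. **Dose.** A simplified analytic broad-beam model (Rcpp kernel):
   `D = w ((SAD+d_max)/r)² · PDD(d_eff) · F`, with ray-marched radiological
   depth, linear build-up to d_max = 1.5 cm then exp(−μ(d−d_max)) with
   μ = 0.05 cm⁻¹, and a Gaussian-penumbra aperture fluence with 2% leaf
   transmission. It stands in for a clinical dose engine while preserving
   what the planning logic depends on: divergence, depth falloff, penumbra,
   transmission.
4. **Subfields and feathering.** Each spine field gets reduced-aperture
   subfields shielding the above-median canal-midline segments, weighted by
   bounded coordinate descent to minimize the midline spread. The plan is
   feathered into three sub-plans with junctions at {z₀, z₀+s, z₀+2s},
   delivered over 5, 5, and 3 of the 13 fractions.
5. **Normalization and evaluation.** Each sub-plan is scaled (monotone
   bisection) so 95% of the 23.4 Gy prescription covers 100% of the brain
   and 95% of the spinal canal, then composited with weights 5/13, 5/13,
   3/13; a final composite-level factor re-establishes the canal rule after
   compositing. `evaluatePlan()` reports V95 for the targets, max dose for
   serial organs, mean dose for parallel organs and the 107% hotspot volume.

## Worked example

```r
library(csiplan)

spec <- phantomSpec(canal_length_cm = 28, voxel_spacing_mm = c(5, 5, 5),
                    slice_thickness_mm = 5, seed = 2)
phantom <- generatePhantom(spec)

runPrecheck(phantom)
#> CSI compatibility pre-check
#>   canal length     : 28.0 cm -> SINGLE configuration
#>   feather space    : 2.5 cm -> 1.0 cm junction spacing
#>   brain-to-mandible: 15.0 cm -> half-beam ok
#>   verdict: accepted

plan <- generatePlan(phantom)
plan
#> CompositePlan (SINGLE): 23.4 Gy / 13 fx, feather fractions 5-5-3
#>   normalization scalars (brain, spine) per sub-plan: (19.518, 25.365) (19.597, 25.181) (19.660, 25.214)
#> VoxelVolume 62 x 40 x 104, spacing 5 x 5 x 5 mm, range [0, 37.8]

evaluatePlan(plan, structureSet(phantom))
#> | Structure | Metric | Gy | % Rx | V95 (%) |
#> |---|---|---|---|---|
#> | brain | V95 | - | - | 100.0 |
#> | spinal_canal | V95 | - | - | 95.5 |
#> | cribriform_plate | V95 | - | - | 100.0 |
#> | brain | Dmax | 37.21 | 159.0 | - |
#> ...
#> | kidneys | Dmean | 0.94 | 4.0 | - |
#> | body | hotspot V107 | - | - | 2025.00 cc |
```

The pre-check accepted the phantom with a single spine field and a 1 cm
junction. The composite plan delivers at least 95% of 23.4 Gy to the whole
brain (V95 = 100%, the normalization target) and to 95.5% of the spinal
canal; out-of-field organs such as the kidneys receive a few percent of the
prescription through leaf transmission and exit dose. The maximum doses are
high relative to a clinical plan because the analytic model normalizes to
the coldest brain voxel and has no scatter smoothing — the methods vignette
discusses this limitation.

The same pipeline runs from a shell:

```sh
csiplan phantom  --out ph/ --seed 2
csiplan precheck --structures ph/manifest.json --out precheck.json
csiplan plan     --structures ph/manifest.json --out plan/
csiplan evaluate --plan plan/ --structures ph/manifest.json --out eval/
```

`plan` exits nonzero, echoing the reasons, when the pre-check rejects the
anatomy (for example, under 1 cm of feathering space).

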