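---
title: "Organ-of-Corti morphometry: models, conventions and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-of-Corti morphometry: models, conventions and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortimorph)
```

`cortimorph` measures the cytoarchitecture of the cochlear amplifier — the
three-row lattice of Y-shaped outer hair cell (OHC) / Deiters cell (DC)
complexes — and the afferent/efferent innervation of the OHCs, from
skeletonized volume-EM annotations. This vignette records the measurement
model, the conventions behind every tunable parameter, and the design of the
synthetic generator that stands in for an EM volume in all tests.

## Measurement model

**Reference frame.** All heights and angles are measured against a frame
built from the annotation itself. The basilar-membrane (BM) plane is the
total-least-squares plane through the `DC_root` landmarks of all rows pooled:
the normal is the singular vector of the centred root cloud with the smallest
singular value, oriented toward the mean OHC cuticular plate (the
reticular-lamina side), so heights above the BM are positive. Each DC row
additionally gets a fitted line (first principal axis of that row's roots),
oriented toward the cochlear base by a user-supplied `basal_hint`; the hint is
required because a skeleton annotation carries no anatomical compass. The
mid-cochlear segment is treated as locally straight — no spiral unrolling —
which is adequate over the few-hundred-micron extents this package targets.

**Y-shape geometry.** For each complex the three limbs are delimited by
landmarks: `L_OHC` from `basal_pole` to `cuticular_plate`, `L_DC` from
`DC_root` to `PhP_branch_point` (the cup), and `L_PhP` from the branch point
to `PhP_apical_insertion`; lengths are summed edge lengths along the unique
tree path. Limb axes are whole-path SVD principal directions (not local
tangents at the junction), signed from the BM end toward the RL end. The
intersection angle α is the plain arccos of the dot product of the
co-oriented OHC and PhP axes, so a straight continuation reads 0° and the
Y-shape opening angles land in the observed 30–50° range. Longitudinal angles
β are measured against the structure's own row line (OPCs use row 1, the row
they abut). Whether α and β are full 3D angles or longitudinal-plane
projections is genuinely open; both are computed (`beta3d` and `beta_proj`,
and α has an implicit projected analogue through the axes), with the 3D
variant as the headline value.

**Mosaic span.** The reticular-lamina lattice is the set of OHC
cuticular-plate landmarks; within each row, apices are ranked by their
projection onto the row line ("columns"). A PhP's span is the inclusive
column count between its own complex's OHC apex and the RL column nearest its
apical insertion, with near-ties broken toward the base and flagged. The
reference census predicts spans of exactly 4, 3, 2 for rows 1, 2, 3.
The "own column" is anchored at the complex's own OHC apex rather than its DC
root: ranks are defined on apices, and anchoring at the root would make the
span depend on the trunk tilt rather than on the RL mosaic it describes.

**Type-2 fibers.** The basal turn is the main-path node with the largest
direction change between windowed tangents (default window 5 µm, minimum
accepted angle 45°); the search is restricted to the radial band of the
outer-pillar zone when OPCs are landmarked, because fibers weaving between DC
rows can produce bends of similar magnitude further out. Profiles sample
every main-path node past the turn: longitudinal position (projection on row
1's direction), height above the BM, and the nearest supporting trunk within
the attachment radius (default 2 µm — about half the inter-row spacing, so
attachments are unambiguous). The compartment model is deliberately not a
free change-point fit: the breakpoint *is* the first OHC-innervating
collateral, because the compartments are defined by the presence of
collaterals; a fiber with no collateral keeps its climbing fit and reports an
undefined contact slope. Both compartments are ordinary least squares of
height on longitudinal position; slopes are dimensionless, with per-DC
variants scaled by a configurable DC pitch (default 6.8 µm, the ratio of the
reported per-DC and dimensionless slopes).

**MOC classification.** The tunnel-crossing zone is a slab between two
parallel planes supplied as a `tc_zone`. Crossings are counted as tree edges
transversal to the slab's mid-plane — a definition that is invariant to
subdividing edges and counts one crossing per clean traversal. Subtype is
`branched` for two or more crossings ("multiple tunnel-crossing fibers"),
`unbranched` for exactly one; a fiber that never reaches the slab is flagged
as anatomically not an MOC fiber.

**Statistics.** `compare_groups()` wraps the classical tests used in this
literature — equal-variance two-sample t (Welch by flag), paired t, one-way
ANOVA — and attaches the significance bands n.s. (p > .05), `*` (p < .05),
`**` (p < .01), `***` (p < .001). No multiple-testing correction is applied:
pairwise p-values are reported raw alongside the ANOVA, matching the
convention of the reports this package mirrors.

## The synthetic generator

`generate_organ_of_corti()` produces a full annotation set — OHC/DC/OPC
skeletons, type-2 and MOC fibers, a contact table — plus a ground-truth
ledger of every sampled parameter. The presets `cba1` and `cba2` encode two
study conditions: per-row means and SDs of lengths and angles, the 4/3/2 span
rule, fiber trajectory parameters, innervation counts and fractions, and the
MOC mixture (96 OHCs / 96 DCs / 32 OPCs / 40 type-2 fibers / 70 MOC fibers
for `cba1`; the smaller sampled census at coarser voxels for `cba2`, which
reuses `cba1` values for fields its source does not report, such as the OHC
longitudinal angle and the MOC synapse distributions).

**Geometry is realized exactly, not approximately.** Per-complex draws
(truncated Gaussians, ±4 SD) of `L_OHC`, `L_PhP`, `L_DC`, α, β_DC and β_OHC
are realized by construction: the DC trunk and OHC axes are planar with their
sampled longitudinal angles, and the PhP direction is solved on the α-cone
around the OHC axis subject to a fixed longitudinal run, taking an
out-of-plane (radial) component as needed. The printed per-row values of α,
β_OHC, β_PhP, the lengths and the span rule jointly over-determine the
geometry — no uniform column pitch satisfies them all simultaneously — so one
quantity has to be emergent. Because the analysis contracts require recovery
of α, β_DC, β_OHC and the lengths, the generator makes **β_PhP** the emergent
quantity; its per-row means come out steeper than the reported ones (roughly
70°/79°/91° versus 61°/67°/75°), which is reported, not forced. A related
consequence: the RL mosaic of OHC apices is kept on a regular grid (that
regularity is the biological observation the span rule expresses) and the DC
roots absorb the per-complex variation, so the root "honeycomb" is slightly
irregular and PhP insertions land exactly `span − 1` columns basal of their
own apex. Basal-edge DCs whose insertion would leave the volume lose their
insertion landmark, which yields the 29/30/29 intact-complex census.

**Annotation noise** is modelled as a smooth quadratic bow per limb
(amplitude 150 nm per perpendicular axis) plus 30 nm node-level tracing
noise, with all coordinates quantized to the voxel grid (11 × 11 × 40 nm for
`cba1`). A symmetric bow neither inflates arc length appreciably nor rotates
the SVD axis, so sampled lengths and angles survive measurement to well
within 0.1 µm / 0.1°; independent per-node jitter of the same amplitude would
inflate path lengths by several percent and was rejected for that reason.
DC roots get 200 nm out-of-plane noise; the fitted BM plane and row lines
recover the true frame to well under 1°.

**Fibers.** Each type-2 fiber approaches radially, turns at the outer-pillar
row (turn height drawn from the observed OPC contact heights, 21.4 ± 3.1 µm),
runs basally with an exactly biphasic height profile — the sampled climbing
slope (0.23 ± 0.07) up to its first collateral, the sampled contact slope
(0.02 ± 0.09) after — and weaves among the DC rows according to a per-column
lane scheduler that realizes the configured per-DC fiber abundances
(20.4/13.6/7.6 of 40 fibers). Three realities shape the scheduler. First,
the abundances sum to 41.6 > 40, so they cannot all hold at one column; row 1
is filled first (exactly), rows 2–3 take the remaining supply,
most-height-constrained first. Second, a fiber can only ride a trunk whose
top it can reach, so the contact-phase riding band is anchored at 26 µm over
the census columns, below essentially all trunk tops; fibers with the
steepest contact slopes take the basal-most breakpoints so the anchoring
offset stays small. Third, with a strictly monotone biphasic profile the
observed drop from OPC contact heights (21.4 µm) to DC1 heights (17.8 µm)
cannot be reproduced; per-support climbing heights are therefore emergent and
tested against the ledger, not the preset. Collateral contacts are drawn per
OHC from the configured per-row count distributions; bouton classes are
Bernoulli draws from the per-row ribbon fractions; the number of row-mixing
fibers is a fixed count (`round(0.125 × 40) = 5`), the seeded draw deciding
which fibers mix and each mixing fiber realizing contacts on both of its
rows.

**MOC fibers** are split into a fixed count of branched fibers
(`round(0.243 × 70) = 17`); branched fibers bifurcate before the tunnel slab
into 2–3 crossing branches, unbranched fibers cross once. Synapse counts are
integers from a discretized Gaussian over the printed range (3–11 branched,
1–4 unbranched) whose latent location is solved once with `uniroot()` so the
discrete mean equals the printed mean (naive truncation would bias the
branched mean from 5.18 up to ≈ 5.7). Branched fibers concentrate 75% of
their synapses in a modal row; unbranched fibers draw rows independently from
their near-uniform distribution.

**Determinism.** One seed drives everything through R's RNG; identical
config + seed gives byte-identical annotations and ledgers, and the caller's
RNG state is restored.

## What the generator does and does not emulate

Passing recovery tests on this generator shows that the *measurement chain*
(frame fitting, SVD vectorization, path metrics, span ranking, compartment
fits, classifiers) is unbiased and correctly scaled under realistic noise,
lattice irregularity, voxel anisotropy and boundary truncation. It does not
exercise: curved (spiral) geometry; tracing errors that change topology
(missed branches, mergers); non-Gaussian biological variation; fibers whose
compartments are not cleanly biphasic; or realistic per-support height
profiles (see above). Real annotations will also carry landmark placement
error, which enters lengths directly and is not modelled beyond node noise.

## Numerical choices and degenerate inputs

- Plane/line fits refuse < 3 points, collinear or coincident inputs with a
  `cortimorph_degenerate` error; axes of coincident path nodes likewise.
- Non-unit axis inputs within 10% of unit norm are renormalized with a
  warning; anything worse is an error.
- Span near-ties (within 50 nm of equidistant) break toward the base and set
  a flag; negative heights are counted in the QC block, not dropped.
- The geometric consistency check `|(β_OHC − β_PhP) − α| ≤ 5°` flags
  complexes (it only holds when both limbs lie near the longitudinal plane;
  out-of-plane PhPs violate it benignly).
- Problem sizes in the test suite — 40 lattice replicates for geometry
  recovery, 15 full-census replicates for fiber statistics, 5 for the MOC
  mixture — were chosen so each per-seed check (±2 SEM) aggregates into a
  one-sided binomial test of a ≥ 95% pass rate at α = 0.001.

## Known limitations

- The emergent β_PhP (and the projected-angle variants) should not be
  compared quantitatively against reported longitudinal PhP angles.
- Realized per-DC abundances for rows 2–3 fall below their configured means
  (the 40-fiber supply cap); the ledger records what was realized.
- Per-OHC efferent counts are emergent from the synapse-share census; the
  reported per-OHC means are internally inconsistent with that census and
  were not targeted.
- The tonotopic place-frequency axis is out of scope, as is any mechanical
  modelling of BM motion.
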