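# cortimorph

Quantitative morphometry and innervation analysis of the organ of Corti from
skeletonized volume-electron-microscopy annotations.

The cochlear amplifier rests on a three-row lattice of Y-shaped structural
units, each formed by an electromotile outer hair cell (OHC) and the
phalangeal process (PhP) of a supporting Deiters cell (DC) tilted the opposite
way between the basilar membrane (BM) and the reticular lamina (RL). Two fiber
systems innervate the OHCs: thin type-2 spiral ganglion neuron (SGN) afferents
that turn ~90° at the outer pillar cells and climb along DC rows before making
ribbon-associated or ribbon-less contacts, and medial olivocochlear (MOC)
efferents that cross the tunnel of Corti with one or several branches.
`cortimorph` turns skeleton annotations of such a volume (webKNOSSOS-style NML
or SWC, plus a synapse table) into the standard quantitative readouts:

- **Reference frame** — total-least-squares BM plane from DC root landmarks
  (normal = smallest principal component of the centred roots), per-row fitted
  lines, and heights above the BM.
- **Y-shape geometry** — per complex: path lengths `L_OHC`, `L_PhP`, `L_DC`;
  SVD principal axes; the intersection angle `α = arccos(u_OHC · u_PhP)` of
  the co-oriented OHC and PhP axes; longitudinal angles `β` against the fitted
  row direction (full 3D and longitudinal-plane projections); and the RL
  mosaic span (the 4/3/2-column rule).
- **Type-2 SGN analysis** — turn detection, height/longitudinal profiles,
  the biphasic compartment fit (OLS height-vs-run slope in the collateral-free
  climbing region and in the OHC-contact region, split at the first
  collateral), per-support contact heights, per-DC fiber abundance, per-OHC
  afferent counts, ribbon fractions and row-specificity.
- **MOC classification** — branched vs unbranched by the number of distinct
  tunnel-slab crossings (mid-plane transversals; `branched` ⇔ ≥ 2), with
  per-subtype synapse statistics and row distributions.
- **Synthetic generator** — a seeded parametric organ-of-Corti model
  (`generate_organ_of_corti()`) with presets `cba1`/`cba2` that emulates the
  lattice, fibers and synapse tables together with a ground-truth ledger, so
  every analysis stage is testable without an EM volume.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()`/`plot_*()` for figures.

## Worked example

```r
library(cortimorph)
library(dplyr)

sim <- generate_organ_of_corti(oc_config("cba1"), seed = 1)
sim
#> <oc_synthesis> preset cba1, seed 1
#> <oc_annotation>
#>   pitch: 11 x 11 x 40 nm
#>   trees: 334 ( DC=96, MOC=70, OHC=96, OPC=32, T2SGN=40 )
#>   contacts: 413

report <- oc_run_pipeline(sim)
report$yshape_summary |> filter(metric %in% c("alpha", "span"))
#>     row metric  mean    sd     n
#>   1   1  alpha 46.1   2.15   29
#>   2   2  alpha 35.3   3.03   30
#>   3   3  alpha 30.3   2.30   29
#>   4   1   span  4     0      29
#>   5   2   span  3     0      30
#>   6   3   span  2     0      29
```

The 88 intact complexes split 29/30/29 across rows; the recovered mean
intersection angles (46.1°, 35.3°, 30.3°) sit within sampling error of the
preset values (45.58°, 36.09°, 30.22°), and every PhP spans exactly 4, 3 or 2
OHC columns depending on its row — the mosaic rule. Fiber-side readouts live
in the same report:

```r
bind_rows(lapply(report$fibers$fits, tidy)) |>
  group_by(compartment) |> summarise(mean = mean(slope, na.rm = TRUE))
#>   compartment   mean
#>   climbing    0.228      # um height per um longitudinal run
#>   contact     0.012

report$specificity$exclusive_fraction   # fraction of row-exclusive fibers
report$moc |> count(subtype)            # 17 branched / 53 unbranched
```

`report_to_json(report, "summary.json")` writes all headline statistics under
stable figure-style keys; `plot_yshape_summary()`, `plot_fiber_profiles()` and
`plot_innervation()` give quick-look figures.

For real annotations, read them instead of generating:

```r
ann <- read_nml("volume.nml", voxel_pitch(11, 11, 40))
ann <- read_contacts("contacts.csv", ann)
report <- oc_run_pipeline(ann, basal_hint = c(1, 0, 0),
                          zone = tc_zone(c(0, -14000, 0), c(0, 1, 0), 4))
```

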