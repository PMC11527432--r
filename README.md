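# synapseQuant

Quantification of secretory polarization and cortical actin remodeling
at the immune synapse, for labs that score T-cell/APC conjugates from
multichannel fluorescence z-stacks and time-lapse movies.

When a T cell recognises antigen on an antigen-presenting cell (APC),
its microtubule-organizing centre (MTOC) and CD63+ multivesicular
bodies (MVB) move to the contact and the central cortical F-actin mesh
clears to allow polarized (exosomal) secretion. synapseQuant implements
the field's standard readouts of this process as tested R functions:

* **Polarization index (PI).** With the cell geometric centre
  `Cell^C`, the synapse contact point, and an organelle centre of mass
  `Org^C`, the PI is the signed projection of `Org^C` onto the
  `Cell^C → synapse` axis divided by the `Cell^C`–synapse distance:
  +1 fully polarized, −1 fully anti-polarized, independent of cell size
  and shape. Computed on the maximum intensity projection by default
  (`MIP-2D`), or volumetrically (`full-3D`).
* **F-actin clearance ratio.** The z-stack is resampled *en face*
  (orthogonal to the contact axis), the synapse interface is outlined
  as the filled convex region of supra-threshold F-actin, and the ratio
  `F-actin-low area / IS area` of the largest interior sub-threshold
  component is reported — a size-independent measure of central actin
  clearance.
* **Colocalization.** Pearson (unthresholded) and Manders M1/M2 with
  Otsu/Costes/manual thresholds, interface colocalization overlays, and
  band-averaged MFI line profiles.
* **Time-lapse kinetics.** Floating-ROI MFI series and the duration of
  reporter accumulation at the synapse (longest run of IS/cell MFI
  enrichment above 1.5× baseline, timed between boundary-frame
  midpoints).
* **Group statistics.** Per-synapse one-way ANOVA with Tukey HSD and
  the exosome fold-induction normalization
  `(exo_stim/cell_stim)/(exo_unstim/cell_unstim)`.
* **A ground-truth simulator.** `simulateConjugate()` renders two-cell
  conjugate stacks (truncated-sphere geometry, Gaussian PSF, Poisson +
  read noise) with exact known PIs, synapse point, and clearance
  fraction; `simulateTimelapse()` renders accumulation movies. Every
  measurement above is validated against this forward model in the
  test suite.

## Worked example

```r
library(synapseQuant)

# a polarized conjugate with known ground truth (true MTOC PI = 0.7,
# 40% of the contact disc F-actin-depleted), on a 0.25 um test grid
params <- sceneAtPI(0.7, seed = 3, mvbJitter = 0.4,
                    voxelSize = c(0.25, 0.25, 0.35))
sim <- simulateConjugate(params)
sim$truth
#> GroundTruth: PI(MTOC) = 0.700, PI(MVB) = 0.474, clearance = 0.40
#>   synapse point (um): 10.45, 7, 7

seg <- segmentConjugate(sim$stack)
pol <- polarityFromStack(sim$stack, mode = "MIP-2D")
pol$mtoc
#> PolarityResult [MTOC, MIP-2D]: PI = 0.723 (A/B = 3.31 um, C = 4.58 um)
pol$mvb
#> PolarityResult [MVB, MIP-2D]: PI = 0.481 (A/B = 2.20 um, C = 4.58 um)

interfaceQuantify(sim$stack, seg = seg)
#> InterfaceResult: IS area 15.06 um^2, F-actin-low 6.56 um^2, ratio 0.436 (midlevel threshold 151)
```

The measured MIP PI (0.723) recovers the programmed 0.700 within the
voxel/noise tolerance; the MVB PI (0.481) recovers its own ground truth
(0.474), which differs from the MTOC target because the rendered MVB
puncta scatter about a jittered centre; and the measured clearance
ratio (0.436) recovers the programmed 0.40. Group-level workflows
aggregate one row per synapse and feed `anovaTukey()`:

```r
set.seed(99)
batch <- data.frame(
  pi = c(rnorm(30, 0.7, 0.15), rnorm(30, 0.0, 0.2)),
  group = rep(c("stimulated", "unstimulated"), each = 30))
res <- anovaTukey(batch$pi, batch$group)
res$table[, c("pair", "diff", "p_adj")]
#>                      pair       diff        p_adj
#> 1 unstimulated-stimulated -0.7548581 1.490319e-11
```

A thin command-line front end over the same functions is installed at
`inst/scripts/synapseq.R` (subcommands `simulate`, `segment`,
`quantify-polarity`, `quantify-interface`, `coloc`, `report`).

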