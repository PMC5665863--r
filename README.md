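# germaquant

Quantitative 3D analysis of follicle precursor cell fates in the
*Drosophila* germarium.

During early oogenesis, follicle stem cell progeny in germarium regions
2b–3 read graded niche signals and diverge into main body
(Eya<sup>high</sup> Cas<sup>low</sup>), polar/stalk (Eya<sup>low</sup>
Cas<sup>high</sup>), or still-uncommitted (double-low / double-positive)
states. Resolving these decisions requires measuring marker and reporter
levels in *every* somatic nucleus of a 3D confocal stack, positioning each
cell along the anterior–posterior (AP) axis, and comparing genetically
marked mosaic clones against the internal control cells of the same
sample. `germaquant` implements that workflow end to end for researchers
doing quantitative confocal microscopy of germarium-scale epithelia, and
ships a synthetic phantom generator so every stage can be validated
against known ground truth without any external image data.

## What it computes

* **Two-pass nuclear detection** — scale-matched Laplacian-of-Gaussian
  blob detection at the nominal nucleus diameter (2.5 µm), refined to
  1.75 µm quantification cores at the masked intensity centroid, plus
  robust-outlier flags for dividing/dying/damaged nuclei.
* **Canonical orientation** — least-squares mid-sagittal plane, rotation
  of the plane normal onto the stack Z axis, anterior to the left; each
  cell gets an AP coordinate (µm) and a region label (R1 … S2plus).
* **Intensity processing** — per-core channel means, background
  subtraction from 8–12 small spheres in cell-free tissue across two Z
  planes, and a top/middle/bottom depth-bias QC for the laser-power
  correction.
* **Normalization** — per-sample maximum
  (`v / max(v)`), internal-control mean (`v / mean(v_control)`, the
  mosaic fold-change readout), or the one-phase decay
  `y(x) = P + (y0 − P)·e^(−Kx)` fitted on internal-control cells
  (gradient-aware normalization for reporters such as fz3-RFP).
* **Statistics** — the variance-gated decision tree: F-test-gated
  unpaired *t* vs Mann–Whitney for two groups; Brown–Forsythe-gated
  ANOVA + Tukey HSD vs Kruskal–Wallis + Dunn (Bonferroni, tie-corrected)
  for multiple groups, with compact letter displays; exact
  probability-mass Fisher test on 2×2 clone-composition tables; Tukey
  box-plot statistics; fold-change CIs.

## Worked example

```r
library(germaquant)

# a 50-cell germarium phantom at SNR 10, with full ground truth
ph  <- generate_phantom(phantom_params(n_cells = 50, snr = 10, seed = 42))
res <- run_pipeline(ph$stack, run_config(), truth = ph$truth)
cells <- res$cells

match_to_truth(cells[, c("z_um", "y_um", "x_um")], ph$truth)
#> recall 1.00  precision 1.00  mean localization error 0.064 um

table(cells$region)
#>     R1    R2a  R2b_A  R2b_P  R3_S1 S2plus
#>     13     13      7      6      8      3

# Eya rises from region 2a to region 3/stage 1
compare_two_groups(cells$eya_norm[cells$region == "R3_S1"],
                   cells$eya_norm[cells$region == "R2a"])
#> <test_result> mann_whitney  statistic = 104  p = 0.0001917
#>   gate: F p = 0.0002369 -> different variance

# four-region comparison with compact letters
g <- split(cells$eya_norm, cells$region)[c("R2a", "R2b_A", "R2b_P", "R3_S1")]
compare_multi_groups(g)$letters
#>   R2a R2b_A R2b_P R3_S1
#>   "a"   "a"   "b"   "b"

# anterior-high Wnt-reporter gradient, fitted on all cells
fit_one_phase_decay(cells$ap_um, cells$wnt_reporter_bgsub)
#> <decay_fit> y = 17.69 + (486.7 - 17.69) exp(-0.0768 x);  R^2 = 0.8072 (n = 50)

# polar/stalk unit composition: 0/75 fully-mutant vs 6/82 in controls
fisher_exact_2x2(matrix(c(0, 6, 75, 76), 2, 2))
#> [1] 0.02920674
```

The detection metrics say all 50 phantom nuclei were found with no false
positives and sub-voxel localization; the letter display groups regions
that are statistically indistinguishable in Eya (anterior "a" vs
posterior "b"); the decay fit recovers the generating rate constant
(K = 0.08 µm⁻¹) from the rendered, noisy stack; and the Fisher p-value
prints as 0.03 at two decimals.

A command-line wrapper is provided in `exec/germaquant`
(`phantom | detect | run | stats` subcommands, YAML config).

## Limitations

The phantom renders spherical Gaussian nuclei on a smooth ellipsoidal
monolayer shell; it does not emulate germline cyst morphology, muscle
sheath artefacts, photobleaching, or anisotropic PSF tails. Region
boundaries on real samples are user-supplied landmarks, and anterior
orientation comes from a config hint rather than automatic landmark
detection. See the methods vignette (`vignettes/germaquant-methods.Rmd`)
for the full model description and design rationale.
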