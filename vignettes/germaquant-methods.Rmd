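---
title: "germaquant: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germaquant: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`germaquant` quantifies cell-fate markers and signalling reporters per
nucleus in 3D confocal stacks of germarium-like tissue. This vignette
documents the models the package implements, the parameters that matter
(with units and defaults), the synthetic phantom that backs the test
suite, and the design decisions taken where the method left genuine
choices open.

## 1. The measurement model

A sample is a multi-channel stack `[z, y, x, channel]` with anisotropic
voxels — by default 0.43 µm axial steps and 0.14 µm lateral pixels, the
regime of a high-NA confocal imaging a whole germarium. All geometry is
done in physical micrometres; voxel indices are only touched at the
conversion boundary, because at this anisotropy (3:1) index-space
distances are badly wrong.

**Detection** is a two-pass spot workflow. The coarse pass runs a
scale-normalized Laplacian-of-Gaussian operator (sigma =
diameter / (2√3) µm, converted per axis to voxels) on the nuclear-stain
channel, takes local maxima of the negated response above
`sensitivity × max(response)`, and greedily suppresses maxima closer
than 0.7 × diameter (ties: higher raw intensity, then lexicographic
(z, y, x)). Accepted centres are refined to the raw-intensity centroid
within the spot radius, giving sub-voxel localization. The refinement
pass then masks the channel to each coarse sphere and places one
1.75 µm core at the masked intensity centroid, so that only the bright,
even centre of each nucleus is quantified — the same logic as shrinking
a detected 2.5 µm spot onto the chromatin core. Dividing, dying, or
damaged nuclei are flagged (not removed) by a robust z-score
(median/MAD, cutoff 3.5) on the core's nuclear-stain mean and
coefficient of variation.

Defaults: coarse 2.5 µm (germarium nuclei; a ~3.46 µm coarse pass for
egg chambers is a parameter, not separately validated), core 1.75 µm
(2.0 µm allowed), sensitivity 0.3. The sensitivity default was
calibrated once on the reference phantom so that recall stays above
0.95 at SNR 10; it lives in `run_config()`, not in the algorithm.

**Orientation** reproduces the two-step manual rotation used for
sagittally mounted samples. Step 1 fits the mid-sagittal plane by least
squares (normal = smallest principal component of the centred
covariance of nuclear centres, sign toward +z) and rotates it flat.
Step 2 turns the in-plane component of an anterior hint onto −x
("anterior to the left") and zeroes x at the anterior-most cell. The AP
coordinate is then simply x. Whether a curved-midline arc length would
be more faithful than straight-line x is debatable; for the
near-straight germarium the difference is negligible, and straight-line
x is what the canonical rotation delivers, so that is what the package
uses. The anterior hint is user input (or phantom truth): anterior is
identified visually on real samples, and no automatic landmark
detection is attempted.

Region labels partition the AP axis into half-open intervals
`[b_i, b_{i+1})` so boundary cells are assigned deterministically. With
k boundaries the first k + 1 of (R1, R2a, R2b_A, R2b_P, R3_S1, S2plus)
are used in order; anything past the sixth label is S2plus. The package
default (10, 15, 20, 25, 30) µm is the phantom's reference geometry —
on real data the boundaries are user landmarks read from germline cyst
morphology, which is out of scope here.

**Intensity processing.** Core means are taken over voxels whose
centres fall inside the core sphere; cores clipped by the stack edge
are averaged over the in-bounds subset and flagged. Background is
estimated from 8–12 core-sized spheres placed in signal-free tissue
across exactly two z planes (auto-placement samples low-nuclear-signal
voxels away from all detected nuclei; manual centres override, and a
manual centre overlapping a nucleus is an error). Subtraction floors at
zero. The fit of the decay model (below) and all normalizations run on
background-subtracted values — consistent with processing order
"background subtraction, then normalization"; whether raw values were
ever used instead is not documented for the original workflow, and
bg-subtracted is the defensible choice.

The depth-bias QC guards the acquisition-time laser-power ramp: control
cells are split into top/middle/bottom z terciles and the sample passes
if the maximum pairwise band-mean ratio is ≤ 1 + tolerance (default
0.15, i.e. a 15% allowed imbalance). A residual attenuation of
0.01 µm⁻¹ over a 40 µm stack produces a ratio of e^0.4 ≈ 1.49 and
fails.

## 2. Normalization modes

* `max` — divide by the per-sample maximum over non-excluded cells;
  values land in [0, 1] with the brightest cell exactly 1. Idempotent,
  scale-invariant, per-sample independent.
* `control_mean` — divide by the mean of in-scope internal-control
  cells (≥ 3 required); a clone cell's value is its fold change versus
  the controls of the same sample/region.
* `decay` — divide by the prediction of a one-phase decay fitted on the
  internal-control cells. This is the right normalization for
  anterior-high reporter gradients, where a clone cell at AP position x
  must be compared to what a control cell *at that position* would
  show, not to a global mean.

The decay model is `y(x) = P + (y0 − P)·e^(−Kx)` in the
plateau / Y0 / rate-constant parameterization (the convention of the
curve-fitting software this field uses, so fitted parameters are
directly comparable). Fitting is constrained Levenberg–Marquardt
(`minpack.lm`), K ≥ 0 and P ≥ 0, initialized at P = min y, y0 = max y,
and K from a log-linear fit of y − P; on failure a fixed ladder of five
alternative starts is tried before the fit is reported unconverged
(with the best parameters found — downstream normalization then
requires explicit opt-in). R² is 1 − SS_res/SS_tot about the mean; the
all-constant degenerate case (SS_tot = 0) is defined as R² = 0 with
P = y0 = const and K = 0. Where the fitted curve approaches zero
posteriorly the divisor is clamped at `floor_eps` (default 5% of the
fitted y0) and the affected cells are flagged rather than silently
dropped.

## 3. Fate classification and statistics

A cell is "high" for a marker iff its normalized value is at or above
that marker's threshold (≥, so boundary cells are double-positive);
the four quadrants map to precursor (low/low), main body (high/low),
polar/stalk (low/high), and double-positive states. No numeric cutoff
for "high" is canonical, so thresholds are data-driven by default:
at late stages each marker is bimodal, and `auto_thresholds()` places
the cutoff at the density valley between the two main KDE modes
(modes below 10% of the peak are ignored; a valley shallower than 75%
of the smaller mode means the distribution is effectively unimodal and
the threshold falls back to 0.5 with a warning). A config override is
always available.

The statistical decision tree is gated on variance homogeneity, with
the gate recorded in every result. Two groups: F-test at alpha (default
0.05, configurable separately from the comparison alpha); similar
variance → two-tailed unpaired t, different → two-tailed Mann–Whitney.
Multiple groups: Brown–Forsythe (Levene with median centring, via
`car::leveneTest`); similar → ANOVA + Tukey HSD, different →
Kruskal–Wallis + Dunn. Dunn's pairwise z uses tie-corrected pooled mean
ranks with Bonferroni adjustment over all pairs; commercial packages do
not document their internal multiplicity correction, so Bonferroni is
declared explicitly and recorded in the report rather than assumed to
match any particular program to all digits. Compact letter displays are
derived by insert-and-absorb on the non-significance graph. Degenerate
inputs have defined conventions: both groups zero-variance with equal
means → p = 1; all values identical across groups → all pairwise p = 1,
one letter.

Fisher's exact test on 2×2 clone-composition tables uses the
probability-mass two-sided definition: the sum of probabilities of all
tables (margins fixed) whose probability does not exceed the observed
table's, with a 1e-7 relative tolerance for floating-point ties. On the
0/75-vs-6/82 polar/stalk composition table this yields p = 0.0292,
printing as 0.03 at two decimals; the doubled-one-sided alternative
gives a different second decimal and was rejected. A zero margin means
the table is determined by its margins: p = 1 by convention. Tukey
box-plot statistics use R's default type-7 (linear interpolation)
quartiles — quartile conventions differ across software and none is
canonical, so one is fixed and documented — with whiskers at the most
extreme data within 1.5 IQR of the quartiles.

## 4. The synthetic phantom

The phantom generator is first-class, tested code: it defines the
reference study conditions under which the pipeline's accuracy claims
are made.

**Geometry.** `n_cells` (default 50) nuclei of diameter 2.5 ± 0.15 µm
are rejection-sampled onto an ellipsoidal shell — semi-axes x = 16,
y = 9, z = 2.5 µm, thickness 1 µm — with minimum centre separation
0.8 × diameter. This emulates the sagittally mounted half-germarium as
actually imaged: a curved epithelial monolayer a few micrometres deep,
roughly 30 µm long and 18 µm tall. The AP coordinate runs 0–32 µm from
the anterior tip. A random mounting tilt (uniform axis, up to 10°) is
drawn per phantom and recorded in the truth, so axis recovery is
genuinely exercised.

**Expression.** Each channel has an AP profile: nuclear stain constant;
Eya a logistic rise centred at 16 µm (inside region 2b_A) with
steepness 1 µm⁻¹ — a steep, switch-like rise; Cas a gradual linear rise
(slope 0.035 µm⁻¹) across 2b; and a Wnt-reporter one-phase decay with
plateau 0.1, y0 1, K 0.08 µm⁻¹. The logistic/linear forms are this
package's modelling choice: the biological rises are documented only as
data, steep versus gradual, and no validation depends on the specific
functional form. Cell-to-cell variability is multiplicative mean-1
lognormal (sd 0.25 for markers, 0.1 for the stain): fluorescence
intensities are strictly positive and right-skewed, which additive
Gaussian noise would violate. Clone cells (20% by default, independent
draws with an exact count, or one contiguous patch) have their true
expression multiplied by per-channel effect sizes; the clone-marker
channel is rendered for clone cells (positive polarity, MARCM-style
GFP gain) or for non-clone cells (negative polarity, ubi-marker loss).

**Imaging.** Nuclei render as spherical Gaussian blobs (sigma =
diameter/4) at `gain` (1000) counts per unit expression — spheres are a
deliberate simplification that suffices to exercise the 2.5/1.75 µm
two-pass logic, not a model of chromatin texture. Depth attenuation
`exp(−0.015 z)` is either cancelled exactly (laser-corrected mode, the
default, emulating a calibrated acquisition ramp) or left in as the
residual bias the depth QC must catch. Then: isotropic Gaussian PSF
(0.3 µm), additive background (50 counts), Gaussian read noise of
`gain/snr` counts (so `snr` is blob peak over noise sd; default 10),
optional Poisson shot noise, and quantization to 16-bit integer counts.
Quantized stacks round-trip bitwise through the TIFF writer, which is
what makes seed determinism testable end to end.

**What passing tests do and do not show.** On phantoms the pipeline
achieves recall/precision 1.0, sub-voxel localization, AP-axis error
well under 2°, and truth rank correlations above 0.95. Real germaria
add everything the phantom omits: germline cyst nuclei in the same
stain channel, curved and crowded epithelia, mounting compression,
anisotropic PSF tails, photobleaching, and autofluorescence. Phantom
results validate the algorithmic chain, not performance on arbitrary
real data; the manual-edit hooks (add/remove spot lists in config) and
QC flags exist precisely because real data needs human checking.

## 5. Numerical choices and problem sizes

Plane fitting refuses collinear clouds (second eigenvalue < 1e-10 of
the largest); rigid frames are validated orthonormal to 1e-8; the
blob operator handles plateau ties through its deterministic ordering;
`normalize_max` of an all-zero channel returns zeros with a warning
rather than NaN; background spot placement fails loudly when the
candidate region cannot hold the requested non-overlapping spheres.
Rendering refuses stacks beyond a configurable voxel budget (5e7)
before allocating.

The validation suite uses a 12-cell phantom for most unit tests and the
full 50-cell reference phantom for end-to-end checks; simulation-based
checks use 50 seeds (clone-effect power and CI coverage), 100 rotations
(axis recovery), and 1000 null seeds (type-I calibration of the gated
test, expected 5% ± 1.5%). The Fisher implementation is verified by
exhaustive enumeration of every 2×2 table with total ≤ 60 against an
independent factorial-formula oracle. These sizes were chosen to give
stable pass/fail behaviour at sub-minute runtimes per file.

## 6. Known limitations

* Straight-line AP coordinate; strongly curved ovarioles would need
  non-rigid straightening, which is out of scope.
* The clone-label threshold on the clone-marker channel (half of the
  per-sample maximum) assumes a clean on/off marker; weak or variegated
  markers should use truth tables or manual labels.
* Dunn's adjustment is Bonferroni; other software may adjust
  differently, so adjusted p-values can differ in the last digits even
  when conclusions agree.
* The phantom's imaging model has no flat-field error, spectral
  bleed-through, or per-voxel attenuation correction; the
  laser-corrected mode stands in for the microscope's ramp.
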