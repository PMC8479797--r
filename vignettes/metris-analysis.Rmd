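---
title: "Rolling-parameter analysis of mechanically transduced binding assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rolling-parameter analysis of mechanically transduced binding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metris)
```

## The measurement

A mechanically transduced immunosorbent assay measures a protein-protein
interaction through friction rather than mass action.  A ~10 µm
streptavidin-coated ferromagnetic bead (a *roller*) carries one binding
partner; the glass surface beneath it carries the other.  An external
magnetic field rotating at frequency $\omega$ spins the bead; whatever
rotation is converted into translation is set by the effective friction
between bead and surface, which in turn scales with the strength and density
of the binding interaction.  A bead on a non-binding surface spins almost in
place; a bead held by biotin–streptavidin bonds rolls nearly without slip.

The field is applied in windows: clockwise for $\tau$ seconds, off for a
settling period, counter-clockwise for $\tau$, off again, repeated 18 times —
36 actuation windows per bead under the standard schedule ($\omega = 1$ Hz,
$\tau = 5$ s, 5 s off).  For each window the displacement $\Delta x$ from the
pre-actuation to the post-actuation position is normalised by the maximum
theoretical displacement of a sphere rolling without slip:

$$\mathrm{RP} = \frac{\Delta x}{\pi D \tau \omega}$$

with $D$ the bead diameter.  The rolling parameter is dimensionless: 0 means
no effective friction, 1 a perfect single-hinge roll through one
circumference per rotation.  With ~10 beads per condition and 36 rolls per
bead, a condition yields ~360 measurements, which is what gives the assay its
statistical power: condition means are typically resolved with percent errors
(100·SEM/mean) below 5%.

The magnetic torque itself ($\vec\tau = \vec m \times \vec B$, ~10 mT fields
against ~10⁻¹¹ A·m² moments) is orders of magnitude stronger than any
noncovalent interaction, so bead rotation is locked to the field frequency.
That hardware physics is outside this package: the analysis starts from
trajectories.

## From trajectory to rolling parameter

`segment_actuations()` cuts each trajectory into the $2 n_\mathrm{cycles}$
field-on windows of the protocol.  Two deterministic conventions are fixed
here rather than left to chance:

* **Window boundaries** are evaluated at the nearest frame *at or before* the
  boundary time.  Only pre/post-actuation positions are defined by the
  experiment; frame quantisation has to be resolved somehow, and "at or
  before" guarantees a segment never includes field-off motion.
* **Displacement mode.** The displacement is "calculated as a vector"; the
  default here is the Euclidean magnitude of the 2-D displacement
  (`mode = "magnitude"`), which is direction-agnostic and equals the
  projection on the rolling axis whenever motion is axis-aligned.  The
  projection (`mode = "axis_projection"`) is retained for sensitivity
  analysis.

`rolling_parameter()` divides by $\pi D \tau \omega$ with $\tau$ and
$\omega$ taken from the protocol object — they are controlled experimental
inputs, never inferred from the data.  Values above 1 can occur through
noise; they are flagged with a warning and deliberately **never clamped**, so
the raw record stays auditable.

`summary()` on a rolling-parameter set reports the pooled mean over all
measurements with SD and SEM, and also the per-roller means.  The reported
"±" convention is SEM over the pooled measurements (a printed value such as
0.918 ± 0.002 at $N = 324$ is far tighter than any plausible per-roll SD, so
it must be a standard error).  Rolls within one roller are not independent,
which is why the roller-level aggregation and a roller-level t-test
(`compare_conditions(unit = "roller")`) are provided alongside the pooled
defaults; for balanced designs the two means coincide exactly.

## The affinity calibration

Across interactions of known strength, $\log_{10} K_d$ is empirically linear
in $\log_{10} \mathrm{RP}$ — a single line spanning ~15 orders of magnitude
between two anchors:

* a **null anchor**: streptavidin rolling on plain avidin, RP ≈ 0.081,
  assigned $K_d = 1$ M (no interaction is truly measurable there; 1 M sits
  between the weakest reported PPIs and the concentration of water, and both
  the value and the RP are overridable in `anchor_points()`);
* the **biotin–streptavidin anchor**: RP ≈ 0.918 at $K_d = 10^{-15}$ M.

`fit_calibration()` is ordinary least squares of $\log_{10} K_d$ on
$\log_{10} \mathrm{RP}$, with the anchors entering as ordinary unit-weight
points.  Design choices that were genuinely open:

* **Regression direction.** $K_d$ is the quantity being predicted, so it is
  the response.  Inverse (errors-in-x) regression is noted as an alternative
  but not implemented; the calibration is an empirical transfer curve, not a
  measurement-error model.
* **Base 10** on both axes — the spread is 15 decades, and the base cancels
  in any free-energy difference.
* **Intervals.** `predict()` returns a *prediction* interval by default (the
  extrapolated quantity is a new observation's $K_d$), computed on the
  $\log_{10}$ scale with the $t$ distribution on $n-2$ degrees of freedom
  and back-transformed; the narrower confidence interval of the mean line is
  available via `interval = "confidence"`.  A two-point (anchors-only) model
  interpolates both anchors exactly but has zero residual degrees of
  freedom, so its interval is reported as `NA` with a warning rather than
  silently as ±∞ or 0.
* **Families.**  Rolling parameters from different interaction systems
  (different reader domains, different surface chemistries) are not directly
  comparable: each system shows a systematic vertical offset from the global
  line even though within-system fold changes are preserved.
  `fit_report()` fits per-family and global models side by side and flags a
  family whose mean global-fit residual exceeds that family's *own* residual
  spread — i.e. an offset larger than the family's internal scatter.  The
  remedy is `scaling_factor()`: the arithmetic mean of published/calibrated
  $K_d$ ratios within one family.  Multiplying the calibrated values by it
  places them on the literature scale and *provably* leaves every
  within-family fold change and $\Delta\Delta G$ unchanged
  ($RT\ln\frac{f k_1}{f k_2} = RT\ln\frac{k_1}{k_2}$); mixing families in
  one factor is an error.

Free energies use $\Delta\Delta G = RT \ln (K_{d,1}/K_{d,2})$ with
$R = 1.987204 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 298$ K by default;
$K_{d,1}$ is the state of interest and $K_{d,2}$ the reference, so tighter
binding of the state of interest is negative.  Values are rounded to one
decimal only when formatting reports, never in computation.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage (tracking, segmentation, RP,
calibration, reporting) is testable against ground truth without any video
data.  It is phenomenological *at the level of the RP equation*: no Langevin
or hydrodynamic simulation of bead rotation, no magnetic field computation.

Per actuation window the realised rolling parameter is drawn as
$\max(0,\; \mathrm{true\_rp} + \mathcal N(0, \sigma_\mathrm{RP}))$ —
measured per-roll RP distributions are Gaussian, and a displacement
magnitude cannot be negative.  The roller then translates linearly along the
lab-frame x axis (CW = $+x$, CCW = $-x$; the axis choice is arbitrary and
only a convention) by $\mathrm{RP} \cdot \pi D \tau \omega$, and sits still
during off periods.  On top of that: per-frame isotropic Gaussian
localisation noise (default 0.1 µm, the subpixel resolution of ~1 µm/pixel
imaging) and an optional linear stage drift.

Defaults that define the simulated study conditions:

* **Presets** (`metris_presets()`) carry the measured mean RP of each
  condition — biotin–streptavidin 0.918, the avidin null 0.081, the DIDO1
  H3K4me1/2/3 series 0.176/0.213/0.233, the ORC1 H4K20 series, and the
  ubiquitin/UBL set — so tests and examples can reference conditions by name.
* **Per-actuation scatter** $\sigma_\mathrm{RP} = \min(0.07,\,
  \mathrm{mean}/3)$ per preset.  0.07 is a realistic per-roll spread for the
  reader-domain conditions; the $\mathrm{mean}/3$ cap keeps the
  zero-truncation mass below ~0.15% for weakly rolling conditions, so preset
  means remain recoverable and the Gaussian shape is preserved.
* **Frame rate** 10 frames/s.  The experiment defines only pre/post-actuation
  positions, so the rate is exposed as a parameter; any rate that samples
  the window boundaries gives identical displacements.
* **Dimers** (optional): two beads stuck magnetically, simulated as rigidly
  co-moving discs with erratic per-roll RP and an apparent (fused-blob)
  diameter of ~1.55 × the single bead.  They exist to give QC a positive
  control: `qc_exclude()` removes rollers whose apparent diameter falls
  outside 0.7–1.4 × nominal, or whose linking was ambiguous, and logs every
  removal with its reason.

What the generator does **not** emulate: frequency-dependent slip (the assay
fixes $\omega = 1$ Hz), surface heterogeneity, bead-to-bead variation in
true RP within a condition, autocorrelated drift, or out-of-focus imaging
artifacts.  Passing tests therefore demonstrate that the *analysis* is
correct and numerically stable under the stated noise model — not that the
tracker would survive crowded or low-contrast real videos, which is also why
the tracker is deliberately limited to sparse, well-separated beads
(nearest-neighbour linking, no gap closing or Kalman filtering).

## Numerical conventions and degenerate inputs

* Image coordinates are 0-based pixel centres scaled by the pixel size,
  origin top-left; documented to avoid off-by-half disputes between the
  renderer and the tracker (round trips agree to < 0.5 pixel).
* Trajectory generation is bit-reproducible for a given seed, and restores
  the caller's RNG state.
* An empty roller list is an empty table, not an error; a zero-cycle
  protocol yields zero segments; an all-excluded QC result *is* an error
  (nothing left to analyse), as is a trajectory too short for the protocol —
  the error states how many windows would fit.
* A two-sample comparison of two zero-variance, equal-mean sets reports
  $t = 0$, $p = 1$ instead of failing.
* Min–max array normalisation (`minmax_normalize_array()`) averages
  replicate spots per peptide first, then rescales each array to [0, 1];
  a constant array is an error because the scaling is undefined.

## Problem sizes

The test-suite and the acceptance script work at the scale of the real
experiment where that scale matters — 10 rollers × 36 actuations (360
measurements, ~3 600 frames per roller at 10 frames/s) for every statistical
claim — and at reduced cycle counts (1–3 cycles) where only the mechanics of
segmentation, rendering or tracking are under test.  Image-based tests use
small fields of view (~320 × 140 µm at 1 µm/pixel) with 2 rollers.

## Known limitations

* The calibration is empirical.  There is no mechanistic model linking
  friction to affinity, so extrapolated $K_d$ values inherit the
  anchor assumptions (in particular the 1 M null) and should be read as
  order-of-magnitude estimates until scaled against published values from
  the same family.
* Reported intervals reflect calibration-line uncertainty only; they do not
  propagate the SEM of the measured rolling parameter through the line.
* The pooled t-test treats rolls as independent; use `unit = "roller"` when
  that assumption matters.
* The tracker handles sparse fields only, by design.
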