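---
title: "Quantifying glial niche architecture from confocal Z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial niche architecture from confocal Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichechart)
```

## The problem

Cortex glia in the *Drosophila* larval CNS enclose each neural stem cell
(NSC) and its progeny in an individual membrane chamber. Whether that
architecture exists in a given specimen is obvious by eye in an ordered,
well-fed animal and in a starved one where it has collapsed — but "obvious
by eye" is not a measurement. This package turns three-channel confocal
stacks (glial membrane, NSC nuclei, neuronal nuclei) into a small set of
per-specimen numbers that capture the architecture:

* the **chamber organisation chart** — per-channel mean intensity versus
  imaging depth, peak-normalized, with sub-slice peak positions;
* **peak offsets** of the NSC and neuron channels relative to the glial
  top layer, in slice units;
* the **membrane-to-NSC ratio** — summed supra-threshold glial intensity
  per counted NSC;
* **thresholded neuronal volume**, optionally centred on the control mean;
* **marker-positive counts** (automated 3D connected components, or
  manual counts supplied as CSV).

Condition-level inference then uses unpaired Student's t-tests with
mean ± SEM and five-number summaries.

## The chart and its peak refinement

For a stack with channels indexed by role and an X,Y region of interest
(ROI), the profile of channel $c$ is
$$I_c(z) = \frac{1}{|R|}\sum_{(y,x)\in R} V_c(z, y, x),$$
one value per slice $z$. Averaging over the ROI first and normalizing each
curve to a peak of 1 afterwards means the chart describes *where* each
marker lives in depth, not how bright it is; all downstream depth
statistics are invariant to per-channel intensity rescaling (this is
tested as a property).

The depth resolution of a confocal stack is the slice spacing, but the
peak of a smooth intensity profile can be localized more precisely. Let
$z_0$ be the slice of maximal mean intensity and $y_-, y_0, y_+$ the curve
values at $z_0-1, z_0, z_0+1$. The unique parabola through these three
points has its vertex (zero of the derivative) at
$$z^\ast = z_0 + \frac{y_- - y_+}{2\,(y_- - 2y_0 + y_+)},$$
which is the refined peak position. Because three points determine the
quadratic exactly, this recovers the true vertex of any concave quadratic
profile to machine precision, and for noiseless Gaussian profiles with
$\sigma \ge 2$ slices the bias is below 0.25 slices, shrinking as the
profile widens. Numerical edge cases are handled explicitly:

* **Ties** in the argmax break to the lowest slice index (deterministic).
* **Boundary maxima** (slice 0 or the last slice) have no three-point
  stencil; the integer argmax is returned with `refined = FALSE`.
* **Non-concave stencils** ($y_- - 2y_0 + y_+ \ge 0$, possible only in
  degenerate inputs) also fall back to the flagged integer argmax rather
  than reporting the vertex of a non-concave parabola.
* An **all-zero channel** cannot be normalized ("empty channel"); charts
  are still built for the remaining channels with the empty one flagged.

No smoothing is applied before peak-finding by default; an optional
centred moving average (odd window, recorded in the chart object and in
all outputs) exists for very noisy acquisitions.

Depths are reported in slice units — the natural coordinate of the
chart — with slice 0 at the top of the stack. The Z spacing is carried
through the objects, a micrometre conversion is appended to peak tables
when it is known, and `run_profile()` warns when specimens with different
spacings are mixed, since slice-unit offsets are then not comparable
across specimens.

## Thresholded morphometrics

The membrane-to-NSC ratio divides the *sum of supra-threshold
glial-channel voxel intensities* in the ROI by the NSC count. Summing
intensities (rather than counting voxels) weights bright, dense membrane
more than faint haze; the threshold decides which voxels belong to the
membrane signal at all. A threshold is resolved once per experiment —
as an absolute intensity, an intensity quantile (linear interpolation), or
Otsu's criterion on a 256-level histogram — and then held fixed across all
conditions being compared, so that condition contrasts cannot be artifacts
of per-group threshold choices. No background subtraction is performed by
default; thresholds on these data already exclude the background mode, and
a constant-offset subtraction would cancel in the fed/starved contrast.

NSC counting thresholds the nuclear channel and counts 26-connected
components with at least `min_volume` voxels (default 10 in the analysis
workflow, rejecting speckle while keeping any realistic nucleus). Touching
nuclei merge into one component — a documented limitation of connected
components; the package deliberately does not attempt watershed splitting,
and accepts externally determined counts via a `specimen_id, marker,
count` CSV instead. Any object in the NSC channel counts as an NSC: with a
NSC-specific nuclear stain, channel identity is object identity.

Neuronal volume is the supra-threshold voxel count of the neuron channel
(times the voxel volume when known). `normalize_volumes()` divides every
specimen by the control-group mean, centring the control at exactly 1 — a
scale-only transform that preserves all between-specimen ratios.

## The statistical layer

Group comparisons use the classical unpaired Student's t-test with pooled
variance and $n_a + n_b - 2$ degrees of freedom, two-sided. A Welch
variant and a summary-statistic form (computing $t$ from each group's
mean, SD and $n$ — algebraically identical to the pooled raw-data test)
are provided and labelled in every output, so a reader always knows which
route produced a p-value. Zero pooled variance is resolved explicitly:
equal means give $t = 0, p = 1$; unequal means are flagged degenerate.

Summaries follow the two reporting styles the charts accompany: bar
graphs of mean ± SEM, and whisker plots of the five-number summary with
quartiles by linear interpolation between order statistics
(`quantile` type 7). The default significance labels are deliberately
unconventional — `***` for $p < 0.05$, `*` for $p < 0.1$, `ns` otherwise —
for fidelity with the reporting style this pipeline reproduces; a
conventional `*` 0.05 / `**` 0.01 / `***` 0.001 scheme is available via
`standard_star_convention()`. No multiple-testing correction is applied by
default (each figure-level comparison is reported as-is); `p.adjust` can
be applied by the user where a family of tests warrants it.

## The synthetic scene generator

Every stage above is verified against scenes with known ground truth.
A scene is a 30 × 128 × 128 × 3 stack (by default) built from:

| parameter | default (fed) | meaning |
|---|---|---|
| `glia_top_depth` | 8 | depth of the glial sheet, slices |
| `glia_sheet_thickness` | 2 | sheet axial extent (Gaussian, $\sigma$ = 1) |
| `chamber_wall_density` | 0.7 | fraction of chequerboard wall segments present |
| `chamber_size` | 24 px | chamber pitch; one NSC per cell |
| `nsc_depth_band` | (11, 14) | NSC nucleus depths, triangular within band |
| `nsc_radius` | 2.5 px | NSC nucleus radius |
| `neuron_depth_band` | (16, 24) | neuron depths, triangular within band |
| `neuron_count` | 120 | neuronal nuclei per 128 × 128 field |
| `membrane_amplitude` | 200 | sheet intensity; walls at 40% |
| `nuclei_amplitude` | 180 | nuclear signal intensity |
| `noise_sd` | 8 | additive Gaussian noise, clipped at 0 |
| `blur_sigma` | 0 | optional isotropic Gaussian blur |

The starved preset moves the glial sheet to depth 12, collapses both
nuclear bands onto 10.5–13.5, drops wall density to 0.1 and the membrane
amplitude to 70 — the loss of ordered chambers and of membrane signal in
one configuration. An intermediate preset renders a partially remodelled
niche. Voxels are quantized to 16-bit integers, matching real confocal
exports and making TIFF round-trips exact.

Design notes, in the order they mattered:

* **Walls as a chequerboard of vertical sheets** between chamber cells
  plus the horizontal top sheet is the minimal geometry that reproduces
  the observed depth profile (a sharp top-layer peak over a wall
  plateau); full closed-shell chambers would change none of the 1D
  measurements this package makes.
* **Neuron density.** Neuronal nuclei vastly outnumber NSCs in this
  tissue, and the neuron channel of a real stack shows a clear depth
  peak. A sparse neuron layer (tens of nuclei over an 8-slice band)
  renders an almost flat profile whose maximum is ill-defined — a poor
  emulation — so the default is 120 nuclei per 128 × 128 field, drawn
  from a symmetric triangular depth distribution within the band.
* **Ground truth for peak depths** is what a perfect profiler would see:
  the glial sheet depth, and for each nuclear channel the
  continuous-depth maximum of the summed axial profiles of the placed
  spheres, computed analytically on a dense grid independent of the
  voxelized render. (The band centre is only the mode of the sampling
  distribution, not the truth of a particular scene.)
* **Noise** is additive Gaussian clipped at zero rather than Poisson —
  adequate because the chart averages thousands of pixels per slice, so
  only the noise mean and scale matter to any tested quantity; the noise
  model is a single pluggable function if photon-limited simulations are
  ever needed.
* **NSC placement on a jittered grid** (one nucleus per chamber cell,
  jitter bounded so spheres cannot touch) makes counting exact by
  construction, which is what a counting test needs; overlap behaviour is
  exercised separately through explicit centres.
* A **tracheal artifact** flag adds a bright off-target tube in the glial
  channel near the image edge, for testing that ROI selection excludes
  exactly the kind of contamination that motivates ROIs on real data.

What the generator does **not** emulate: optics (no PSF; blur is a plain
Gaussian), depth-dependent attenuation, autofluorescence gradients,
nucleus shape variation, chamber wall curvature, or any developmental
dynamics. Passing tests therefore show that the *measurement code* is
correct and well-calibrated on scenes of known geometry — not that the
biological conclusions of any particular experiment are right, and not
that the pipeline is robust to acquisition pathologies it has never seen.

## Reproducibility and problem sizes

Scene rendering is deterministic for a fixed configuration and seed (the
generator saves and restores the caller's RNG state), and the profiling
and comparison stages write byte-identical CSV/JSON outputs on reruns
with identical inputs. The analysis workflow under `analysis/` uses six
specimens per condition at 30 × 128 × 128 — matching the per-condition
sample sizes typical of this kind of experiment — with fixed base seeds
101 (fed) and 201 (starved). The test suite and acceptance script use the
default 128 × 128 field for single-scene ground-truth checks and a
24 × 64 × 64 field for the replicated cohort simulations (hundreds of
scenes), a size at which every per-scene measurement is still
well-conditioned while a hundred replicate cohort pairs render in about a
minute. Analysis thresholds (glia 40, nuclei 90, `min_volume` 10) sit
between the noise floor (clipped Gaussian, SD 8) and the weakest true
signals (starved membrane at amplitude 70), and one fixed set is used for
both conditions, as the measurement rules require.

## Known limitations

* The chart is a 1D depth summary by design; it cannot detect lateral
  disorganisation at constant depth, and per-specimen ROIs are a numeric
  config (reproducible, but standardizing ROI placement across specimens
  is left to the experimenter).
* Connected-component counting undercounts touching nuclei; supply
  manual counts where nuclei are dense.
* Peak offsets are in slice units; comparing them across specimens
  assumes equal Z spacing (the pipeline warns otherwise).
* The t-test assumes approximate normality of per-specimen metrics; with
  n around 6 per arm there is little power to check that assumption, which
  is inherent to the design being reproduced, not to the implementation.
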