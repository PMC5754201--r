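# nichechart

Quantification of neural-stem-cell (NSC) niche architecture from
multi-channel confocal Z-stacks.

In the *Drosophila* larval central nervous system, cortex glia build a
membrane "chamber" around each NSC and its lineage. In well-fed larvae the
niche is vertically ordered: a dense cortex-glial membrane sheet (the *top
layer*) lies just under the blood–brain barrier, NSC nuclei sit directly
beneath it, and newborn neurons lie deeper still. Under starvation the
chambers fail to form: glial membrane is lost and all three signals pile up
at the same imaging depth. `nichechart` turns those qualitative pictures
into numbers for anyone quantifying this kind of layered niche from
confocal stacks.

## The measurements

**Chamber organisation chart.** Within an X,Y region of interest (chosen to
avoid off-target signal such as tracheal GFP), the mean intensity of each
channel *c* is computed per Z slice,

    I_c(z) = mean over ROI pixels of channel c in slice z,

and each curve is normalized so its peak is 1. The peak of each curve is
localized to sub-slice precision by fitting a quadratic through the maximal
sample and its two neighbours and taking the vertex:

    z* = z0 + (y− − y+) / (2 (y− − 2 y0 + y+))

where `y−, y0, y+` are the curve values at slices `z0 − 1, z0, z0 + 1`. The
per-specimen statistics are the *peak offsets*: NSC and neuron peak depths
minus the glial peak depth (positive = deeper than the glial top layer).
An ordered niche has `0 < nsc_offset < neuron_offset`; a collapsed one has
both near zero.

**Morphometrics.** The membrane-to-NSC ratio is the summed supra-threshold
glial-channel intensity in the ROI divided by the NSC count (nuclei counted
as 26-connected supra-threshold components with a minimum volume, or
supplied manually). Neuronal volume is the supra-threshold voxel count of
the neuron channel, optionally centred so the control group means 1.
Thresholds are set once per experiment (absolute value, intensity quantile,
or Otsu) and held fixed across the conditions being compared.

**Statistics.** Groups are compared with the unpaired (pooled-variance)
Student's t-test and summarized as mean ± SEM and five-number
(min, Q1, median, Q3, max) summaries. The default significance labels are
`***` for p < 0.05, `*` for p < 0.1 and `ns` otherwise (a standard
`*`/`**`/`***` scheme is also provided).

**Synthetic scenes.** Because the quantification is only trustworthy if it
recovers known answers, the package generates 3D scenes with ground truth:
a glial top sheet plus a chequerboard of chamber walls, NSC spheres on a
jittered chamber grid, neuron spheres in a deeper band, with additive noise
and optional blur. `fed_preset()` renders the ordered niche,
`starved_preset()` the collapsed one. Every stage of the pipeline is tested
against these scenes.

## Worked example

```r
library(nichechart)

fed <- generate_scene(fed_preset(seed = 3))
chart <- build_chart(fed$stack)
chart
#> <chamber_chart> fed_seed3 [fed], 30 slices
#>   glia     peak at slice 8.000
#>   nsc      peak at slice 12.477
#>   neuron   peak at slice 19.618
unlist(peak_offsets(chart))
#>    nsc_offset neuron_offset
#>       4.47706      11.61825
```

The glial top layer peaks at slice 8, NSCs ~4.5 slices deeper, neurons ~12
slices deeper — the ordered chamber signature. The full workflow
(`analysis/01_simulate.R` … `04_compare.R`) simulates six specimens per
condition, profiles and measures them, and reports the condition
comparison; on the default seeds it prints:

```
nsc_offset           fed 4.48 +/- 0.047 vs starved -0.0272 +/- 0.064 (mean +/- SEM): t=56.98, p=6.7e-14 ***
membrane_nsc_ratio   fed 4.01e+05 +/- 3e+03 vs starved 8.57e+04 +/- 42 (mean +/- SEM): t=106.92, p=1.3e-16 ***
```

i.e. the fed niche has ordered peaks and roughly 4.7× more supra-threshold
glial membrane per NSC than the starved one. Tables and plots land under
`results/`.

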