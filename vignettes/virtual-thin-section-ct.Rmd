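---
title: "Virtual thin-section CT at phantom scale: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual thin-section CT at phantom scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vtsct)
```

## The problem

Clinical T staging of early-stage lung adenocarcinoma is driven by the
maximal diameter of the tumour's *solid component* measured on thin-section
CT (slice thickness at or below 1 mm) with multiplanar reconstructions
(MPR). In routine practice many chest CTs are only reconstructed at 5 mm:
thin sections multiply data volume 5- to 10-fold (`slice_count_ratio()`
makes this arithmetic explicit), so they are often not archived. On 5 mm
images the craniocaudal resolution is too coarse for reliable solid-size
measurement, and the solid size tends to be under-read.

`vtsct` provides a complete, testable desk-scale laboratory for this
problem: synthetic nodule phantoms with exact ground truth, a physically
standard thick-slice simulator, a conditional adversarial slice-interpolation
model that reconstructs "virtual" thin sections from thick slices, an
automated MPR measurement procedure, the TNM size-based T-category rule
table, and the agreement-statistics battery used to compare observers and
modalities (ICC, Pearson with a dependent-correlation test, Cohen's kappa,
ANCOVA).

## The phantom world

A nodule is modelled as up to two concentric spheres: a solid core at
`solid_hu` (default -50 HU) inside a ground-glass shell at `ggo_hu`
(default -450 HU) on lung background at `lung_hu` (default -850 HU), plus
zero-mean Gaussian HU noise (default sd 20 HU, a typical parenchymal noise
level for low-dose chest CT). The attenuation defaults are deliberately
spaced so that one threshold separates each pair of components: -300 HU
(between solid and GGO) isolates the solid core, -700 HU (between GGO and
lung) isolates the whole nodule. Real lesions have no such clean levels;
these values exist so that ground truth is computable, which is the point of
a phantom.

Voxels are filled by sub-voxel volume-fraction mixing (2x supersampling per
axis), so sphere boundaries carry partial-volume values and sub-voxel size
recovery is meaningful. One consequence worth documenting: a threshold
placed *between* two attenuation levels but not at their midpoint selects a
volume-fraction quantile away from 0.5, and therefore erodes or dilates the
apparent component slightly. At -300 HU a solid-in-lung boundary is
selected at the 0.69 fraction quantile, which under-counts the sphere's
voxel volume by about 5% at 0.5 mm spacing. This is a property of any
faithful partial-volume model, not an implementation artefact; the
voxel-count recovery test therefore uses the midpoint threshold, where
voxelisation is median-unbiased.

Cohorts emulate the validation population: 27 solid / 55 part-solid / 11
pure ground-glass out of 93; solid size truncated-normal (11.3, 9.6) mm on
[0, 36]; total size truncated-normal (19.6, 9.1) mm on [5, 45]; invasive
(pathological) size modelled as solid size + N(2.4, 3^2) mm floored at 0,
reproducing the reported mean gap between pathological invasive and
CT solid size and giving the study harness a clinical-vs-pathological
kappa well below 1. Because pure ground-glass nodules have solid size
exactly 0 and solid nodules have solid = total, the truncated normal
governs the *latent* solid size and the marginal distribution is a mixture;
the distributional test asserts the truncated-normal mean on the nodules it
actually governs. A population whose marginal (zeros included) followed the
truncated normal would contradict the stated type proportions.

## Thick-slice simulation

`degrade()` implements the physically standard thick-slice model: each
output slice is the overlap-weighted mean of the thin slices its slab spans
(a box filter in z). Slabs are half-open to avoid double counting; the
first slab sits flush with the volume's lower z face, so its centre lies
half a thickness above it, and only complete slabs are emitted
(`floor((extent - t)/i) + 1` slices). This alignment is deterministic by
default so that exact oracles exist (aligned 5 mm slabs over 1 mm sources
average exactly 5 slices); training variability comes from random patch
positions and conditions rather than slab phase. The operator is linear,
preserves constants and linear ramps, and conserves the volume mean when
slabs tile the extent exactly. Training conditions (thickness, interval)
are drawn uniformly from [3, 8] mm, thickness rounded to 0.5 mm steps;
the validation regime is 5.0/5.0 mm.

## The slice-interpolation model

The generator is residual: the thick volume is first resampled onto the
target thin grid by linear interpolation, two constant condition channels
(thickness and interval, scaled by 0.1) are appended, and a small
convolutional network predicts a correction added to the linear upsampling.
A zero network is therefore exactly the linear baseline — a guaranteed sane
fallback that also makes the residual contract directly testable. HU are
clipped to [-1024, 600] and scaled to [-1, 1]; outputs are de-normalised
and clipped back.

Losses are the conventional paired-translation defaults: L1 reconstruction
(weight 100) plus least-squares adversarial loss (weight 1) against a
convolutional patch critic that also sees the condition channels. With
`lambda_adv = 0` the model collapses to pure regression, which is what the
scaled-down efficacy checks train (stable, cheap, and sufficient to learn
the through-plane deblurring that drives measurement accuracy); the
adversarial path is exercised by smoke tests.

Design deviations worth noting. The generator is a plain conv stack, not a
U-Net: CPU-only pure-R training cannot afford encoder-decoder depth, and
for spherical phantoms the deblurring problem is local. The kernel shape is
configurable per model: the default is a generic 3x3x3, but the toy
training regime uses z-oriented 1x1x9 kernels, which specialise the network
to through-plane interpolation with a long z receptive field (the task is
fundamentally one-dimensional) at a fraction of the cost. All training is
single-threaded, seeded, and bitwise reproducible; inference involves no
randomness, so repeated calls on the same input are bitwise identical, and
z-chunked inference uses a halo equal to the receptive-field radius so
chunking does not change results.

## Measurement

`measure_size()` automates what human readers do on a workstation:
binarise at the solid threshold, keep the largest 26-connected component,
and take the maximum over axial, coronal and sagittal plane stacks of the
in-plane maximum Feret (caliper) diameter; the same procedure at the total
threshold yields total size. Reported diameters add half a pixel width
projected onto the measurement direction: boundary pixels are on average
about half covered by the object, so centre-to-centre distances alone
under-read by roughly a pixel, while full square-support calipers over-read
(and inflate oblique directions by corner effects up to sqrt(2) pixels).

One protocol decision matters: conventional 5 mm CT is measured on its
axial planes only (`orientations = "axial"` in the study harness), while
thin-section sources use all three MPR orientations. This mirrors the
validation protocol, which describes MPR measurement for virtual and real
thin sections but plain image measurement for conventional CT, and it
matches practice — coronal or sagittal reformats of 5 mm slices are not
diagnostic. It is also what reproduces the under-reading of conventional
CT in the phantom world: the 5 mm through-plane pixel would otherwise
inflate coronal/sagittal Feret reads.

Observers are simulated as additive Gaussian noise (default sd 1 mm) plus
rounding to 1 mm, floored at 0 and clamped solid <= total. Two observers
with these defaults reproduce near-equal reader behaviour (the ANCOVA
observer effect is null by construction) and, against a truth sd of 9.6 mm,
a closed-form inter-observer ICC of 92.16/93.16 ~ 0.989.

## Staging

`assign_t()` encodes the size-based T categories for stage 0-I
adenocarcinoma (Tis, T1mi, T1a, T1b, T1c, T2a) with inclusive upper bounds
at 5/10/20/30/40 mm driven by solid size, with Tis and T1mi additionally
requiring total size at most 30 mm. The table is unit-tested against an
independently written brute-force implementation on an exhaustive 0.1 mm
grid. Two conventions are documented rather than asserted: a pure
ground-glass lesion with total size above 30 mm is assigned T1a (its solid
size, 0, falls in the lowest size band), and in the study harness measured
total sizes are capped at 40 mm before staging — above 30 mm the category
depends only on solid size, so the cap never changes a category but keeps
noisy reads inside the rule table's stated domain.

## Agreement statistics

The statistics mirror a standard two-reader validation analysis, with the
specific variants documented because the choice is often left unstated:

* **ICC**: two-way random effects, absolute agreement, single measures —
  ICC(2,1)/ICC(A,1) — with the McGraw-Wong F-based confidence interval and
  an F test of ICC > 0. Absolute agreement is the right form when a
  constant offset between readers is a real disagreement.
* **Correlation comparison**: the Hotelling-Williams test for two
  dependent correlations sharing a variable (both modalities are correlated
  with the same real thin-section measurement). A plain independent Fisher
  z-test is exposed behind `method = "fisher"` but flagged as generally
  inappropriate for overlapping correlations; the Williams statistic
  reduces to it as the cross-correlation vanishes.
* **Kappa**: unweighted Cohen's kappa over the six ordered T categories,
  Fleiss-Cohen-Everitt large-sample CI, one-sided P for kappa > 0, and the
  qualitative bands (poor < 0.20, fair to 0.40, moderate to 0.60, good to
  0.80, almost perfect to 1.00). A linear-weighted variant exists behind a
  flag; the headline statistic treats categories nominally.
* **ANCOVA**: `size ~ observer + modality + real_size` with type-II F
  tests. The model structure is isolated in one function so alternatives
  are one-line swaps; it is the main point of statistical ambiguity in this
  kind of analysis, and the chosen form is a default, not a claim about any
  particular prior software.

## The study harness

`run_study()` chains everything: cohort, thin phantoms ("real TSCT"), 5 mm
degradation ("conventional"), model reconstruction ("virtual TSCT"), two
simulated observers on all three sources, staging (gold standard clinical
stage: observer B on real thin sections; pathological stage from the
invasive-size proxy), and the full statistics battery. Nodule centres
receive a seeded uniform z-jitter of half the conventional interval so slab
phase varies across cases as it does across patients. Everything derives
from one master seed; identical configs give identical reports.

## What a green test does and does not establish

The phantom world is deliberately minimal: spheres (no spiculation, no
vessels, no lobulated margins), three clean attenuation levels, additive
Gaussian observers. Green tests establish that the machinery is correct —
the degradation is exactly the stated box filter, the staging table is
exactly the rule table, the statistics match closed forms, the model
honours its residual/determinism/serialisation contracts, and the
qualitative phenomena (conventional under-reading; virtual reconstruction
recovering thin-section agreement) emerge for the stated reasons. They do
not establish clinical performance: printed clinical coefficients come from
real patients and are not reproducible from phantoms, and sphere phantoms
are an easier measurement target than real lesions in several respects.

The most consequential of these deserves its own paragraph. Clinically,
conventional 5 mm CT is the weak arm: solid margins of irregular lesions
are perceptually ambiguous on thick slices and readers under-call them
badly, so virtual thin sections correlate with real thin sections far
better than conventional images do. In the sphere world that premise
partially fails: the axial equator of a sphere survives slab averaging
almost unchanged, so the automated conventional axial read is accurate to
about a millimetre, while the virtual arm's coronal/sagittal reads depend
on a genuinely hard through-plane deconvolution. The under-reading
*direction* still reproduces (conventional medians sit below real
thin-section medians), but the *correlation ordering* — virtual above
conventional — does not emerge from sphere phantoms at this scale, and the
acceptance check that asserts it is expected to fail, deliberately: it
implements the stated criterion rather than a weakened one. A phantom
family with irregular, craniocaudally asymmetric solid components would be
required for that clinical phenomenon to transfer.

## Numerical choices

* Slabs are half-open; the first slab is flush with the volume's lower z
  face; only complete slabs are emitted.
* Linear/cubic z-resampling clamps outside the source range (constant
  extrapolation); cubic is Catmull-Rom, which reproduces affine ramps.
* Component labelling uses 26-connectivity; size ties break on the lowest
  lexicographic centroid.
* Thresholds must be strictly ordered (solid above total); an empty mask
  measures 0 and a single-pixel cross-section measures one pixel width.
* Kappa on a single shared category is reported as undefined (NA, with a
  warning), not an error; ICC on constant data returns 0 with a warning.
* All seeds are 32-bit integers; derived streams use a fixed affine map of
  (seed, stream index) modulo a prime below 2^31.
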