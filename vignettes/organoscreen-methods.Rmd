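---
title: "Morphological organoid screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological organoid screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoscreen)
```

## The screening problem

Mesenchymal (claudin-low-like) mammary tumor cells grown in 3D matrix form
organoids with invasive spiky protrusions; driving a mesenchymal–epithelial
transition (MET), for example by inducing miR-200c, switches them to a
smooth round morphology, and cell-free wells image as empty background.
These three conditions — spiky negative controls, round positive controls
and empty media controls — anchor a phenotypic screen: a drug that makes
treated wells look like the positive controls is a candidate EMT-reversing
agent, while a drug whose wells come to resemble media controls is killing
cells rather than reprogramming them. Because the spiky morphology is
interconnected and hard to segment, the pipeline avoids segmentation
entirely: whole-well images are embedded into a fixed-length feature vector
and mapped to the control classes with a k-nearest-neighbor (k-NN) model.

`organoscreen` implements this pipeline end to end in R, together with a
seeded simulator that generates plates with known ground truth so every
stage can be validated quantitatively.

## Image preprocessing

Wells are acquired as bright-field z-stacks (the reference acquisition is
18 slices at 100 µm spacing, covering a ~1 mm matrix layer). The chain is
fixed and recorded in each projected image's provenance:

1. **Inversion** — dark organoids on bright background become bright signal
   on dark: `p -> M - p` with `M` the grey maximum of the bit depth.
   Pixels are carried in integer grey-level units throughout, which makes
   inversion an exact involution and keeps the rolling-ball radius
   commensurable with intensity.
2. **Rolling-ball background subtraction** (per slice, radius 10 px by
   default) — the background is the grayscale opening of the image with a
   non-flat, ball-shaped structuring element; subtracting it removes
   illumination gradients and any structure wider and smoother than the
   ball. Borders are handled by edge replication; as with every
   opening-based background, a sag of up to roughly the ball height can
   remain within one ball radius of a steep border gradient, which is why
   quantitative tests assess residuals in the image interior.
3. **Focus projection** — per pixel, the slice with the largest local
   sharpness wins, where sharpness is the sum of squared discrete
   Laplacian over an 11×11 window (the window size of the original
   stack-focusing plugin is unpublished; 11 px is this package's default
   and is configurable). Ties go to the lowest slice index so projection
   is deterministic. Slice indices are 1-based.

For embedding, the projected image is rescaled to [0,1], resized to a
224 px square, and replicated to three identical channels; channel-wise
standardization by the natural-image corpus statistics is available for
backbones that expect it, while the handcrafted extractor uses raw [0,1]
intensities. Embeddings are only comparable within one normalization
scheme.

## Feature embedding

The reference feature space of the screen is the pooled 512-unit
"flattening" layer of an 18-layer residual network pretrained on natural
images — the only 512-wide layer in that architecture, sitting between the
convolutional feature extractor and the classification head. Executing it
requires a deep-learning runtime and a weight file; `make_extractor("resnet18")`
therefore demands local weights and fails with explicit guidance otherwise.

The package's default extractor is a deterministic handcrafted morphology
descriptor with the same width (512), so that the entire downstream
pipeline — which is deliberately dimension-agnostic — runs identically with
either feature space and without any network access:

* 256 intensity-histogram fractions over [0,1] (foreground mass; cleanly
  separates occupied from empty wells);
* 128 radial mean-darkness annuli about the darkness-weighted centroid,
  with a fixed 0.1 block weight — organoid placement is random within a
  well, so this block carries intrinsically higher per-well variance than
  the others and would otherwise dominate Euclidean distances with
  placement noise;
* 128 gradient-orientation bins over [0, π), magnitude-weighted per pixel
  with a fixed ×30 block weight and deliberately *not* normalized to unit
  mass: total edge density per unit area is the strongest
  spiky-versus-round-versus-empty cue, while the bin shape captures
  orientation anisotropy.

The two block weights are commensurability constants fixed once from the
per-class block statistics of simulated controls; they are part of the
descriptor definition (`extractor_id` "handcrafted-v1"), not tunable
state.

The classification logic does not depend on which space is used; the
screen's own observation that generic image features suffice motivates
this interchangeability, and the package's tests verify that spiky and
round phenotypes separate in the handcrafted space.

## Control-anchored classification

Per plate, controls are split 50/50 within each class under an explicit
seed (`ceiling(n/2)` to training). A k-NN model with k = 6 and Euclidean
distance on raw feature values (no standardization, matching common
practice for embedding spaces) stores the training wells verbatim. For a
query well the six nearest training controls vote; class probabilities are
the vote fractions over k, kept exactly summing to 1, and the hard label is
the majority with deterministic tie-breaks (smaller mean neighbor distance,
then the fixed order negative < positive < media; distance ties in neighbor
selection resolve to the lower training-row index). The neighbor list is
returned so any classification can be explained by inspecting the control
wells that produced it.

Assay quality is monitored on the withheld control half via the confusion
matrix and its accuracy; per-batch models gate batch inclusion (default
threshold 0.8 test accuracy, configurable — published batch-level
accuracies around 80% are considered acceptable practice) and a cumulative
model retrained on the union of qualified batches' training halves performs
the final classification of treated wells. A robustness sweep repeats the
split–fit–evaluate cycle (default 100 iterations for each K in 1..6) to
verify insensitivity to subsampling and to K. PCA on mean-centered,
unscaled features provides the exploratory landscape; components are
ordered by explained variance and constant features are dropped with a
warning.

## Dose–response analytics

Each treated well yields a probability triple; per drug and class the
package fits a radial-kernel support-vector regression of
`probability ~ log10(concentration)` with library-default
cost/gamma/epsilon and a two-fold cross-validated error recorded.
SVR makes no assumption about curve shape, accommodating saturated,
sigmoidal and multi-stage responses (reprogramming switching to toxicity at
high dose) within one fitting scheme. Predictions are clipped to [0,1];
replicates enter as separate points. The **activity score** per class is
the normalized AUC: the trapezoidal integral of the fitted curve over the
tested log10 range on a 101-point grid, divided by the range width, hence
in [0,1]. Hits are ranked by positive-class AUC, and the
(neg, pos, media) AUC triplets are hierarchically clustered (Euclidean,
average linkage by default; the scheme is configurable and recorded) for
heatmap ordering.

**Potency** is summarized by a constrained four-parameter logistic fit of
the positive-class probabilities,

$$p(x) = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
{1 + 10^{\,h\,(\log_{10}\mathrm{EC}_{50} - x)}},$$

with box constraints $0 \le \mathrm{bottom}, \mathrm{top} \le 1$, solved by
bounded nonlinear least squares multi-started from four fixed
initializations (hill ±1 crossed with EC50 at the quartiles of the tested
log range); asymptote order is normalized via the hill-sign equivalence of
the 4PL. Convergence failure — e.g. for atypical multi-stage series — is a
recorded outcome, not an error, as are series with fewer than four distinct
concentrations. **PR50**, the screen's potency metric, is the smallest
concentration in the tested range at which the fitted positive-class
probability reaches 0.5, found by monotone bisection; "not reached" is an
explicit result (`NA` with `pr50_reached = FALSE`).

## The simulator and what it does (not) show

`simulate_plate()` generates a full 384-well screen with known ground
truth. Defaults are the screen's stated conditions wherever they exist:
16 wells per control role per plate, ten half-log (3.3×) dilutions in
technical quadruplicate per drug, 512×512 8-bit well images, and z-stacks
of 18 slices when stack simulation is requested. Organoids are rendered by
signed-distance functions: antialiased discs (default radius 30 px, 8 per
well) carrying triangular radial spikes at uniformly random angles whose
length scales with the well's spikiness in [0, 1] (1 = fully mesenchymal,
0 = fully epithelial); interiors carry fine speckle texture and a darker
rim, because bright-field organoids are not flat plateaus, and it is
exactly these sub-ball-scale structures that survive rolling-ball
background subtraction. Spike geometry (count 12, length 36 px at
spikiness 1) is not quantified by any published measurement; the defaults
were fixed once to give a clear visual contrast and are exposed in
`phenotype_params()`. Treatment wells take spikiness
$1 - 4\mathrm{PL}(c)$ under the drug's ground-truth parameters; doses above
a drug's toxicity threshold render the well media-like (empty). A single
plate seed is forked per well by well index, so plates are bit-reproducible
and independent of generation order.

The simulator emulates phenotype contrast, dose interpolation, defocus and
plate structure; it does **not** emulate Matrigel texture, illumination
inhomogeneity, organoid growth dynamics, debris, or the visual
heterogeneity of real wells. Passing tests on simulated plates therefore
demonstrate that the analytics recover known ground truth under controlled
conditions — they do not certify performance on real images, which is
additionally constrained by acquisition quality and the choice of feature
space.

## Numerical choices and degenerate inputs

* Vote fractions: the third probability is the exact complement of the
  rounded partial sum, so triples sum to exactly 1 in double precision.
* Flat probability series: SVR response scaling is undefined at zero
  variance, so constant series return the constant itself (the exact
  least-squares curve).
* 4PL fits never raise on hard series; they record `converged = FALSE`.
* Focus-projection and k-NN tie-breaks are fully deterministic (lowest
  slice, lowest training-row index).
* The rolling-ball implementation is compiled (C++) grayscale
  erosion/dilation with a non-flat ball; the brute-force definition is kept
  as the oracle in the test suite.
* Degenerate geometry is rejected early with actionable messages: even
  sharpness windows, rolling-ball radii at or above the image size,
  canvases too small for the organoid geometry, wells outside the 384-well
  grid, duplicate well assignments, and configurations without seeds.

## Problem sizes used in the validation suite

The packaged tests validate the full-scale study conditions where the
claims demand them — one control plate at simulator defaults for the
perfect-discrimination and robustness checks, and a twelve-drug recovery
study (four reprogramming drugs with EC50s spanning 10⁻⁸–10⁻⁶ M, four
inert, four toxic; ten half-log doses in quadruplicate across two batches)
for potency recovery — and reduced canvases (96–256 px, fewer organoids)
for unit-level properties, where the claim under test is scale-free.

## Known limitations

* The handcrafted descriptor is engineered for this assay's three-way
  contrast; unlike a pretrained convolutional space it will not transfer
  to arbitrary phenotypes.
* PR50 is only as meaningful as the positive-class probability curve; for
  drugs whose response is dominated by toxicity the 4PL may legitimately
  fail to converge, and the AUC triplet (not PR50) is the robust summary.
* k-NN probabilities are quantized in sixths; dose–response curves built
  from them are step-like at the well level and only smooth after SVR
  fitting across replicates and doses.
* Batch qualification uses a single accuracy threshold; no correction for
  batch effects beyond exclusion is attempted.
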