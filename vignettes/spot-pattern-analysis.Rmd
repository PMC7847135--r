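---
title: "Quantitative analysis of dorsal spot patterns in Triatoma dimidiata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of dorsal spot patterns in Triatoma dimidiata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Triatoma dimidiata*, one of the principal vectors of Chagas disease, comprises
three genetically defined haplogroups (H1–H3) that differ in epidemiological
relevance but are hard to tell apart in the field. The dorsal abdomen carries
a conspicuous pattern of light spots on a dark cuticle — two central spots on
the midline and a series of paired spots along the connexivum (the flattened
abdominal margin). spotmorph implements a complete, reproducible pipeline that
turns a dorsal photograph plus a manual abdomen annotation into a quantitative
description of that pattern, and then asks how well the pattern alone
discriminates the haplogroups.

The pipeline stages are: geometric standardization, spot segmentation, spot
numbering, shape-variable extraction, per-group heat maps, nonparametric group
comparisons, and two classifiers (forward-stepwise linear discriminant
analysis and a multilayer perceptron) with permutation variable importance.
A synthetic-specimen generator reproduces the statistical structure of the
three haplogroup archetypes so that every stage can be exercised and audited
without any external images.

## Standardization

Each photograph is reduced to 8-bit grayscale (unweighted channel mean, the
default conversion of common image software; luma weights are available), its
levels are stretched to the central 50% of the intensity histogram, and the
abdomen is brought into a canonical frame using three annotated landmarks:
the two thorax–abdomen insertion points define the horizontal, the abdomen
tip must lie below them, and an isotropic rescale maps the abdomen width to a
fixed reference width. The applied similarity transform is recorded alongside
every standardized image.

Two choices here deserve explanation:

* **Histogram stretch over the full image, not the abdomen only.** The
  stretch maps the 25% and 75% quantiles to 0 and 255. If those quantiles
  were computed over abdomen pixels alone, the top quartile of the abdomen —
  body cuticle as well as spots, whenever spots cover less than 25% of the
  abdomen, which they always do here — would saturate at 255 and the
  bimodality that the automatic threshold needs would be destroyed. Computed
  over the whole (clipped) image, the light background anchors the upper
  quantile and the dark cuticle the lower one, and the spots end up well
  separated in the middle. An `roi_mask` argument restores the
  abdomen-only variant for images without background.
* **Reference width.** Every area is later expressed relative to the total
  abdomen area Ta and every length relative to sqrt(Ta), so the features do
  not depend on the reference width. `standardize_geometry()` defaults to
  1000 px; the pipeline driver uses 400 px, which keeps a full run of a
  hundred specimens in the minutes range on one core without changing any
  relative feature.

Coordinates follow the image convention (origin top-left, x rightward,
y downward, pixel centers at integer positions); angles are reported in the
mathematical convention with the y axis flipped, so 0° is the left–right
axis and 90° the anterior–posterior axis.

## Segmentation

Binarization uses the Minimum histogram method: the 256-bin histogram is
smoothed with a 3-bin mean filter until exactly two local maxima survive, and
the threshold is the minimum between them. Two numerical details: plateau
maxima (which the iterated smoothing of spike-like histograms produces) are
counted by a half-strict comparison, and when the valley between the modes is
a flat run of (near-)empty bins — the usual case for well-separated modes —
the threshold is placed at the plateau midpoint. The midpoint rule makes the
estimator symmetric under contrast inversion and keeps it near the
area-neutral point of a blurred edge; a first-minimum rule would land at the
valley's left edge, an arbitrary position that moves with sampling noise.

The thresholded class covering the smaller fraction of the abdomen is taken
as the spot class (spots are the minority, light elements; an exact tie
resolves to the brighter class), so inverted-contrast images segment
identically.

Cleanup follows particle-analysis convention: a two-pass conditional median
("remove outliers", circular radius 6, threshold 50 on the 0/255 rendering;
first bright then dark outliers), then hole filling (any background region
not connected to the abdomen border becomes spot). Connected components are
labeled under 8-connectivity (configurable to 4), particles below
`min_spot_area` (default 25 px²) are discarded, and ordered boundary
contours, pixel counts and centroids are extracted.

One property of the conditional median filter is worth knowing: on a curved
boundary it shaves a roughly constant-width rim (the neighborhood of a rim
pixel on a convex arc is majority-background), so it is **not** idempotent —
each pass smooths curved boundaries a little further, and small elongated
spots lose a few percent of their apex area in the single pass the pipeline
applies. This is inherent to the filter's definition, affects all groups
alike, and is the main reason measured relative areas sit a few percent below
the rendered truth of synthetic specimens.

Specimens whose final particle count deviates from the expected
2 + 2 × 6 = 14 are excluded and listed in the QC report rather than silently
edited; fused-spot specimens are thereby rejected.

## Spot variables

Spots are numbered by convention: central spots 1 and 2 (anterior first),
lateral spots odd on the left and even on the right, each side anterior to
posterior, ties in y broken by x. "Central" means the centroid falls within
a configurable band (default ±15% of body width) around the ROI midline; zero
or more than two candidates raise QC conditions instead of being guessed
away.

Per spot we compute the relative area Ra = 100·area/Ta, the maximum Feret
diameter (largest pairwise contour distance, found on the convex hull —
exact, since the maximizing pair is always a hull pair), the minimum Feret
diameter (minimum caliper width over hull-edge orientations; the literal
"minimum pairwise distance" is degenerate at one pixel pitch, so the standard
particle-analysis MinFeret semantics are used), the Feret angle of the
maximum diameter folded into 0–90° so left and right inclinations are
comparable, and the aspect ratio Ar = MinFd/MaxFd. Lengths are divided by
sqrt(Ta).

Per specimen the feature vector collects the total Ra, class means of Ra,
MaxFd, Ar and folded Fa for central and lateral spots, the central/lateral
area ratio, and the summed centroid distance between every central–lateral
pair measured after a generalized Procrustes alignment (translation to the
centroid, unit centroid size, iterative rotation to the consensus, no
reflection, convergence 1e-8) of the full 14-point centroid configurations.
Specimens whose spot-number signature differs from the majority are excluded
from the Procrustes step only. Angle means are arithmetic means of folded
angles (matching how the angles are recorded); with all angles in [0, 90]
the circular-mean question does not arise.

### Measurement precision of rasterized shapes

The Feret angle of a digitized ellipse is limited by how precisely the
contact points on its apexes can be localized: a pixel grid locates a point
on an arc of curvature radius rho = b²/a only to about sqrt(2·rho·0.5) px,
which translates to an angular uncertainty of roughly sqrt(2)·b/a^1.5
radians. For a strongly elongated spot (a = 21, b = 7 px) that is about 4°;
for a rounder one it can exceed 10°. The synthetic-recovery tests therefore
assert a mean orientation error below 3° plus this per-spot bound, rather
than a flat per-spot cap that no finite rendering could meet. Aspect ratios
carry the analogous one-pixel caliper allowance on each axis.

## Heat maps

Per group, the aligned binary masks are averaged pixel-wise: each cell of the
heat map is the fraction of specimens with a spot pixel there, so high values
mark the most shared parts of the pattern. Conservation (sum of cell × n
equals the total spot-pixel count) and order invariance are tested. Rendering
uses a perceptually uniform sequential palette with a colorbar strip and is
byte-deterministic.

## Statistics

Descriptives are the median, quartiles (linear interpolation, quantile
type 7 — recorded, since quartile conventions differ across software) and
range. Group comparisons use the Kruskal–Wallis test (tie-corrected H,
chi-square reference with k−1 degrees of freedom) on every feature, with no
multiple-testing correction by default (raw per-feature tests; Holm is
available). At very small samples the chi-square p is only accurate to about
a tenth against the exact permutation distribution; the tests document this
by checking H exactly against a rank-formula oracle over all permutations
and the p-value against the exact one at that accuracy.

## Classifiers

**Stepwise LDA.** Forward selection by the partial F on the reduction of
Wilks' Λ (enter at F ≥ 4.0, remove below 3.9 — the classical defaults, since
no thresholds are prescribed by common usage), followed by an LDA fit on the
selected variables with equal priors (configurable to proportional).
Reported: the step trace, canonical scores, resubstitution and leave-one-out
confusion matrices, and the overall Λ with Rao's F approximation. Both
resubstitution and cross-validated accuracies are always reported because
published discriminant accuracies often leave the protocol unstated.

**MLP.** A single hidden layer trained full-batch with BFGS and analytic
gradients; softmax outputs; cross-entropy or sum-of-squares loss; tanh,
logistic or sine hidden activations. Sine mirrors the activation reported
for the best network in the protocol this pipeline emulates, but its
periodicity makes desk-scale optimization brittle, so tanh is the default.
Inputs are z-scored on the training rows only. The 60/40 per-group split
reserves the specimens misclassified by the LDA for the validation set — a
deliberately hard validation protocol — and is deterministic given its seed.
Training-set sizes use round(0.6·n) per group (banker's rounding; 39/23/39
gives 23/14/23). A topology search trains a grid of configurations (default
5–25 hidden units in steps of 5) and ranks by validation accuracy, ties
broken by fewer units then lower validation loss.

**Variable importance** is the permutation ratio: evaluation-set error after
permuting one column divided by baseline error, averaged over repetitions,
with add-one smoothing so the ratio is defined at zero baseline error.
Uninformative variables score ≈ 1. This convention replaces the proprietary
"network weights" of the original software with a model-agnostic equivalent.

## The synthetic generator

`default_archetypes()` encodes the three haplogroup archetypes as generative
parameters: a dark elliptical abdomen (300 × 430 px) with 2 central + 6
paired lateral light elliptical spots.

* **H2**: total relative spot area 15.6%, central share 52% (large, rounder
  central spots, aspect ratio 0.85), lateral aspect ratio 0.60.
* **H3**: total 8.7%, lateral-dominant (central share 25%), strongly
  elongated lateral spots (aspect ratio 0.35).
* **H1**: total 11% — between the two published extremes, which is where
  this group's overall spottedness sits; lateral-dominant (share 30%),
  aspect ratio 0.55, and its three anterior lateral pairs tilted forward
  (folded orientations ≈ 28–33° with sd 8°, against ≈ 60–70° with sd 14–16°
  elsewhere).

Spot sizes are area weights rescaled so the expected total relative area
matches the archetype target, with mean-one lognormal per-spot jitter
(sd 0.10); positions are jittered (sd 1.2% of body width); orientations are
sampled per pair and mirrored across the midline. Imaging is emulated by a
random pose (rotation sd 8°, scale uniform on 0.85–1.15), Gaussian intensity
noise (body 55 ± 4, spots 190 ± 8, background 215 ± 5 on the 8-bit scale)
and salt-and-pepper speckle on 0.5% of abdomen pixels. Exact pre-noise
ground truth (masks, per-spot areas, centroids, axes, orientations) is
emitted with every specimen, and everything is deterministic given the seed.

What the generator does **not** emulate: cuticle texture and illumination
gradients, reflectance highlights that bridge adjacent spots (the main cause
of manual edits on real photographs), non-elliptical spot outlines, wing
hyperchromatism, and anatomically detailed insertion landmarks (the widest
points of the abdomen ellipse stand in for them). Passing the recovery tests
therefore shows that the pipeline measures what it claims on clean,
geometrically honest imagery — not that real photographs need no manual QC.

Rendered at this scale, spot areas run from roughly 400 px² (H3 laterals) to
4000 px² (H2 centrals), so rasterization effects (apex shaving by the median
filter, threshold placement within blurred edges after resampling) bias
measured relative areas a few percent below the rendered targets and limit
cross-resolution feature agreement to a few percent as well; the tests set
their tolerances from these mechanisms, as derived above.

## Problem sizes used in the checks

The test-suite and the acceptance script run entirely on synthetic data:
200 random polygons for the caliper oracles, about a hundred specimens for
the segmentation-robustness and classifier-recovery checks (30 per group),
100 feature-level replicates for the noise-variable selection rate, and a
39/23/39 study replica for the end-to-end script — sizes at which every
property under test is already stable.

## Known limitations

* The ROI annotation replaces manual abdomen clipping; the optional
  `auto_roi()` (largest dark region's convex hull) is explicitly lower
  fidelity and cannot remove legs or head.
* Fused spots are rejected by QC, not split; watershed separation is out of
  scope.
* The conditional-median cleanup erodes curved boundaries slightly (see
  above); radius and threshold are configurable if a gentler cleanup is
  wanted.
* Published accuracies from the original study are not reproducible targets:
  they depend on manual clipping and manual noise edits of the source
  photographs. The synthetic replica tests recovery of the same *structure*
  (group ordering of spot areas, orientation contrasts, high discriminant
  accuracy) rather than the exact printed numbers.
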