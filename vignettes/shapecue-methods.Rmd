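---
title: "Auditing classifiers for global-shape versus local-contour cues"
author: "shapecue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing classifiers for global-shape versus local-contour cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecue)
```

## The question the package operationalizes

Human object recognition is dominated by *global shape*: the spatial
configuration of an object's parts as a whole. People recognise silhouettes
effortlessly, tolerate wildly wrong surface textures, and keep recognising
an object whose local edges have been roughened — but fail when the parts
are cut apart and rearranged, even though every local edge fragment is
intact. A classifier that instead relies on *local contour features* —
curvature and orientation statistics over short boundary segments — shows
the mirror-image pattern: part rearrangement barely hurts it, edge
roughening destroys it.

`shapecue` turns that contrast into a reusable audit. It provides

1. a contour geometry engine that makes both notions measurable,
2. generators for the classic diagnostic stimulus families (silhouettes in
   several colorways, outlines, texture chimeras, part-scrambled and
   serrated figures),
3. a seeded synthetic shape/texture catalog so that every stage is testable
   without any image downloads,
4. two deliberately simple ("toy") classifiers that *embody* the two
   hypotheses, and
5. the classification and psychophysics metrics used to score real systems:
   label rank, top-k criterion, chance level, shape-versus-texture
   preference, per-condition human accuracy tables, pooled t tests.

Any external network can be audited through the adapter contract
(`external_adapter_contract()`): a function from an RGB raster to a
probability vector over a fixed vocabulary. Nothing in the package depends
on any particular network.

## Measuring "global shape" and "local features"

Neither notion has a canonical formula, so the package fixes two standard,
testable operationalizations.

**Global shape — elliptic Fourier descriptors (EFD).** A closed contour is
expanded into elliptic Fourier harmonics (the Kuhl–Giardina coefficients
$a_k, b_k, c_k, d_k$). Translation is removed, scale normalized so the
first harmonic has unit magnitude, and (optionally, on by default) the
starting point and orientation are normalized from the first ellipse's
phase and major axis. The first $m = 10$ harmonics describe how parts
relate spatially while ignoring fine detail; `global_shape_distance()` is
the L2 distance between matched coefficient blocks. Ten harmonics is the
conventional "coarse configuration" cut-off: the synthetic generator keeps
all class-defining configural structure at harmonic $\le 8$ and all
contour micro-texture at whole-cycle counts $\ge 12$, so the descriptor
cleanly sees the former and is blind to the latter. The rotation
normalization has the usual two-fold ambiguities (starting point and
axis); the package resolves them by a deterministic, tolerance-guarded
choice among the four candidates. On nearly circular outlines the first
ellipse's phase is ill-conditioned and rotation-normalized descriptors of
rotated copies can disagree; this does not affect the generated catalogs,
whose classes are all deliberately elongated (aspect 1.15–1.5).

**Local features — arc-length-weighted curvature histograms.** The contour
is resampled uniformly (512 vertices by default), the signed turning angle
at each vertex divided by the local spacing gives curvature in radians per
pixel (convex positive), and the histogram over 32 bins spanning
$[-0.5, 0.5]$ rad/px, weighted by arc length, summarises the local edge
content irrespective of where on the object it occurs.
`local_feature_distance()` is the symmetric chi-square distance
$\sum_b (h_1 - h_2)^2 / (h_1 + h_2) \in [0, 2]$. Because the turning
angles are smoothed *along the contour* (a circular Gaussian), their sum —
and hence the turning-number identity $\oint \kappa \, ds = 2\pi$ — is
conserved exactly.

## Subpixel boundary extraction

`extract_contour()` traces the pixel-edge ("crack") boundary of the
largest 8-connected component, then removes the half-pixel staircase by
Gaussian smoothing of the vertex positions along arc length
(`smooth = 2` px by default; `smooth = 0` returns the exact pixel-edge
polygon, e.g. a unit square for a single pixel). The smoothing step is what
makes metric statements meaningful at the pixel scale: the raw crack
boundary of a rasterized disk has length $8r$, the smoothed polyline is
within a fraction of a percent of the true circumference $2\pi r$.
Orientation is canonical (turning angles sum to $+2\pi$), so curvature
signs are unambiguous. The inverse operation, `rasterize()`, uses even-odd
scanline filling at pixel centers; an extract–rasterize round trip moves
the 10-harmonic descriptor by less than $10^{-2}$ on typical smooth
shapes, which is the package's own stability criterion.

## The stimulus families

All renderers place the object identically: centered, isotropically scaled
so the larger bounding-box side spans 80% of the shorter canvas side
(224 × 224 RGB by default — the conventional classifier input size).
Placement transforms the *subpixel contour* and re-rasterizes rather than
resampling the raster, which avoids nearest-neighbour aliasing.

* **Silhouettes** (`render_silhouette()`): uniform figure on uniform
  ground, in black-on-white, white-on-black, or red-on-white colorways.
* **Outlines** (`render_outline()`): a black stroke centered on the
  bounding contour; interior and exterior are the same white, so the only
  contrast in the image is the contour itself.
* **Texture chimeras** (`render_texture_chimera()`): the silhouette of one
  category filled with the surface texture of another (tiled, not
  stretched, to avoid introducing scale cues), putting shape and texture
  labels in conflict.
* **Part-scrambling** (`part_scramble()`): the figure is cut into up to 8
  pieces along straight chords and the pieces rigidly rearranged
  (translations plus 90° rotations, which are exact on the pixel grid;
  mirroring available but off by default) into a non-overlapping
  arrangement on the same canvas. Placement first proposes positions whose
  bounding box is free (via a summed-area table over the dilated
  occupancy), falls back to pixel-exact probes, and redraws the cut chords
  if an arrangement cannot be placed. Global configuration is destroyed;
  local curvature is untouched except along the cuts.
* **Serration** (`serrate()`): the contour is displaced along its outward
  normal by a triangular wave (default amplitude 3% of the bounding-box
  diagonal, period 5% of the perimeter, snapped to a whole number of
  cycles). Local curvature is overwritten; the coarse configuration
  survives. The amplitude must stay below half the shape's minimal feature
  width, estimated from significant medial maxima of the distance
  transform (ridges below a quarter of the largest inscribed radius are
  treated as contour texture, not parts).

Each manipulation returns a `manipulation_report` — the EFD distance, the
curvature-histogram distance (for scrambling, with cut-chord vertices and
a guard band excluded, since those edges are artifacts of the
manipulation), and the foreground area ratio. Over seeded batches of
synthetic shapes the two manipulations doubly dissociate: scrambling's
median global damage and serration's median local damage each exceed the
other manipulation's by well over the 3× design criterion, while both
conserve area.

## The synthetic catalog: what it emulates, and what it does not

`build_catalog()` generates `C` classes — half smooth, elongated
"animal-like" blobs whose radius is a radial Fourier series with harmonics
2–8, half straight-edged "artifact-like" irregular polygons with rounded
corners — with `E` jittered exemplars each, split half/half into train and
test. The default emulation of a forty-category silhouette study is
`C = 40`, `E = 20`; the audit experiments in this package's own tests use
`C = 10`, `E = 20`, which keeps a full run (catalog, two classifier fits,
three conditions, two hundred test stimuli) within a few minutes on one
CPU.

Class identity is carried on two deliberately separated scales:

* **Configuration** (harmonics ≤ 8): per-class wiggliness total (0.18–0.42)
  and spectral tilt for blobs; vertex count (4–10), vertex radii, and
  corner-rounding for polygons; plus a class-fixed elongation and axis.
* **Local contour character** (whole-cycle counts ≥ 12): a sinusoidal
  micro-texture along the outward normal — the silhouette analogue of a
  surface texture such as curly fur. Classes are spread geometrically in
  texture *peak curvature* (0.12–0.45 rad/px): what a curvature histogram
  discriminates is the relative (Weber-like) difference. The wavelength
  band (24–32 px) is kept narrow so that contour-smoothing attenuation,
  which is stronger at short wavelengths, cannot cancel the spread. The
  ripple's amplitude is derived per exemplar from the actual perimeter so
  that peak curvature is the class invariant, and its cycle count and
  phase are class-level, not exemplar noise.

Exemplar jitter (radius 2% log-sd, radial amplitudes 3% relative sd,
rotation ±10°, center ±4 px) was calibrated once so that the catalog is
*learnable through both channels* — the design requires both toy
classifiers to reach ≥95% held-out accuracy on unperturbed silhouettes,
since the audit's logic is a performance *drop* under manipulation. The
deliberate spreading of class parameters plays the same role: a catalog
whose classes collide in either feature space cannot support the
dissociation the audit is designed to exhibit.

What the catalog does **not** emulate: natural image statistics,
photometric variation, interior contours, occlusion, or 3-D pose. Passing
audits on this catalog show that the pipeline's machinery — geometry,
manipulations, metrics, classifier contract — behaves as specified; they
say nothing about how any particular network behaves on photographs.

## The toy classifiers

`fit_toy()` builds a nearest-centroid classifier over one of the two
feature channels; `predict_toy()` returns softmax of negative Euclidean
distance over temperature (default 1). The channels differ in exactly the
way the two hypotheses do:

* the **local** channel pools curvature histograms (soft-binned, turning
  angles smoothed at σ = 4 px for signal-to-noise) over the contours of
  *all* visible pieces — a local-feature observer does not care how pieces
  relate — and ignores featureless stretches: maximal runs of
  $|\kappa| < 0.02$ rad/px lasting ≥ 12 px, plus a 12 px guard band, are
  excluded before pooling. Genuine boundary in the catalog carries texture
  curvature almost everywhere, so this exclusion removes only the straight
  cut edges (and the spurious corners where they meet true boundary) that
  part-scrambling introduces. At prediction time each centroid may
  additionally be mixed with a free share of zero-curvature mass, so
  residual straight filler cannot masquerade as class evidence;
* the **global** channel is the flattened rotation-normalized 10-harmonic
  EFD of the largest component's outline, with harmonic $k$ down-weighted
  by $1/\sqrt{k}$ (class identity lives mostly in the coarse
  configuration; fine-contour perturbations concentrate in the upper
  harmonics) — a configural observer needs one object boundary, so
  scrambling leaves it staring at a single meaningless piece. Matching is
  performed modulo the descriptor's residual four-fold normalization
  ambiguity (a pure sign pattern), which otherwise flips unpredictably on
  near-point-symmetric, i.e. elongated, shapes.

Both classifiers are trained at presentation scale (the placed masks),
because curvature in rad/px is size-specific, and manipulations in the
pipeline are applied after placement for the same reason.

These observers are *hypothesis embodiments*, not models of any network:
the audit's claim is directional. On a ten-class catalog the local
observer's top-1 accuracy barely moves under scrambling but collapses to
near chance under serration; the global observer shows the reverse. That
reproduces, in direction, the dissociation reported between human
observers (configural) and deep networks (local) on scrambled versus
serrated silhouettes — including the networks' hallmark behaviour of
classifying radically scrambled objects far above chance.

## Metrics and human scoring

The analysis layer mirrors the conventions of large-vocabulary
classification studies: competition ranking with a deterministic
vocabulary-order tie rule (`label_rank()`), the top-five criterion
(`in_topk()`), exact chance level $1/K$ (`chance_level()`), strict
shape-versus-texture preference with explicit ties
(`shape_texture_preference()`), strict target-versus-group-mean
comparison (`vs_class_mean()`, true about half the time under an
exchangeable null), and per-group summary tables with the between-group
ratio of mean shape probabilities (`summarize_outcomes()`).

Human responses are scored per item and per condition
(`score_human()`); the condition mean is the unweighted mean over items,
the convention under which a printed condition mean equals the mean of its
item column. Group comparisons use Student's pooled two-sample t test
(`two_sample_t()`, delegating to `stats::t.test(var.equal = TRUE)`):
two groups of ten subjects pool to 18 degrees of freedom, the form used in
the psychophysics this package's tables follow.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)`, rows increasing downward; contours
  canonically oriented (turning sum $+2\pi$); one fixed convention
  prevents curvature sign errors.
* Multi-component masks: operations that need one object take the largest
  8-connected component (components are labelled by `EBImage::bwlabel`,
  merged across diagonal touches).
* Empty masks, vocabularies missing a label, duplicate response keys,
  overlapping comparison sets, amplitude beyond the feature-width bound,
  and self-intersecting contours handed to `rasterize()` are errors;
  degenerate duplicate vertices are dropped with a warning; curvature
  outside the bin range is clipped into the end bins with a warning.
* The zero-variance-equal-means t test returns $t = 0, p = 1$; with
  unequal means it is an error rather than an infinity.
* All randomness flows through explicit integer seeds (kept below
  $2^{31}$); generators restore the caller's RNG state, and a catalog's
  manifest records every sub-seed, so any stimulus can be regenerated
  bit-identically from its provenance record.

## Known limitations

* The EFD rotation normalization is undefined for exactly circular
  first-harmonic ellipses and numerically touchy near them; the audit
  catalogs avoid the regime by construction, but user-supplied
  near-circular shapes should be compared without rotation normalization.
* The curvature histogram is presentation-scale-specific by design
  (rad/px); comparing shapes rendered at very different sizes requires
  rescaling to a common placement first, as the pipeline does.
* The minimal-feature-width estimate measures lobe widths, not narrow
  necks; serration of dumbbell-like shapes can disconnect them, in which
  case the largest-component repair keeps the bigger lobe.
* Scrambling operates on pixel sets; pieces smaller than a few pixels
  across can lose their contour identity, so `n_parts` is capped at 8.
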