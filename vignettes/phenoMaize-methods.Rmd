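---
title: "Mapping maize cropland from phenology-composited time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping maize cropland from phenology-composited time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoMaize)
```

## The problem

Maize grown in one-season planting systems has a distinctive seasonal
spectral trajectory: bare soil in April, rapid green-up in June, a
July--August peak with high near-infrared (NIR) and depressed red and
shortwave-infrared (SWIR) reflectance, and a collapse back to soil
signatures after harvest. A 30 m optical sensor revisiting every 16 days
sees this trajectory through clouds and sensor noise. phenoMaize implements
a complete pipeline that turns such a six-band (Blue, Green, Red, NIR,
SWIR1, SWIR2) surface-reflectance time series into a binary maize map and
validates it: compositing, a recurrent classifier, map cleaning, and
accuracy/area assessment. Because the package must be testable without any
satellite download, it also ships a first-class simulator that generates
scene stacks with exactly the statistical structure the pipeline assumes.

## The simulator: what it emulates and what it does not

`defaultProfiles()` encodes one `PhenologyProfile` per class (maize,
soybean, rice, others) as piecewise-linear mean reflectance curves over
day-of-year 91--334 (Apr 1 to Nov 30, non-leap calendar; the simulation
window is fixed to this season). The curves are qualitative but
physiologically structured:

* maize and soybean differ in green-up timing, peak height, harvest date
  (day 278 vs 258) and in the depth of their SWIR depression -- the same
  cues that make the two crops separable, and confusable, in real imagery;
* rice starts flooded (very low SWIR1/SWIR2, low NIR) before its canopy
  closes;
* "others" (non-crop vegetation, built surfaces) is nearly aseasonal, with
  a seasonal NIR range below 0.1.

Class-contrast invariants (crop NIR green-up of at least 0.2; aseasonal
"others") are enforced by the S4 validity method, so every simulated
experiment is guaranteed to contain the signal the classifier is supposed
to recover. A per-seed perturbation (uniform within ±0.008 on the knots)
varies profiles across replicates without breaking the invariants.

`simulateSceneStack()` builds a parcel-structured truth raster (rectangular
single-class parcels, mean side `parcelSize`), a cropland mask (the
cropland fraction is realized over parcels; class shares inside cropland
are realized by largest-remainder allocation so the requested mixture is
met closely rather than in expectation), a regular-block region raster
standing in for administrative units, and one scene per revisit date.
Clean observations are the profile curve value plus N(0, 0.02) band noise,
truncated to [0, 1]. Cloud-contaminated observations (Bernoulli per pixel
and scene) are flagged and overwritten with a bright cloud signature
(Blue >= 0.4), bright enough that maximum-value compositing *without*
cloud handling is visibly corrupted -- this is what makes the cloud stage
testable.

Defaults (64 x 64 grid, 16-day revisit, 5% cloud probability, class mix
0.35/0.25/0.20/0.20, cropland fraction 0.7, parcel side 5 px, 2 x 2
regions, noise sd 0.02) were chosen once as a plausible toy-scale portrait
of smallholder one-season cropland. The simulator does *not* model
radiative transfer, topography, BRDF, mixed pixels, within-field
heterogeneity, or inter-annual phenology shifts; a pipeline that passes
here has demonstrated correct mechanics and adequate capacity, not
real-world accuracy. Published accuracies on real imagery (overall
accuracy around 0.89) are not reproducible from a desk and are not claimed
by the tests.

## Compositing

`dropCloudyScenes()` removes scenes whose flagged-pixel fraction exceeds a
threshold (default 0.8; scene-level screening of hopeless acquisitions).
`replaceCloudyBands()` then gap-fills every remaining flagged observation
from the nearest-in-time date at which the same pixel and band is clean,
breaking ties toward the earlier date; the search window is unbounded
within the season, and an observation with no clean donor anywhere becomes
invalid (`NA`). `maxValueComposite()` finally takes, per pixel, band and
two-month window (Apr--May, Jun--Jul, Aug--Sep, Oct--Nov), the maximum over
valid observations, yielding the 4 x 6 = 24-dimensional feature sequence.
The maximum is taken independently per band -- the simplest reading of
maximum-value compositing and the one that is easily verified against
brute-force enumeration (the test suite does exactly that on random toy
stacks). An alternative convention selects whole dates per pixel (e.g.
max-NDVI compositing); users porting results from such pipelines should
be aware of the difference. Window boundaries are fixed calendar windows;
"every two months over April--November" admits no other 4-window reading.

NDVI, EVI and NDWI (`computeIndices()`) are provided for ablation studies
but are not part of the default classifier input: stacking them onto the
24 features adds no information that the network cannot form itself.

## The classifier

The model is a 3-layer LSTM (128 hidden units per layer) over the 4-step,
6-band sequence, followed by a fully connected head of 128, 128 and 64
nodes. The first two head layers use tanh; the 64-dimensional output of the
third layer uses a sigmoid and serves as the feature vector \(f\) for the
center loss; a final linear layer with softmax produces the 4-class
probabilities (a per-class sigmoid output is available as a config option).
Training minimizes

\[ L \;=\; L_{ce} + w\,L_c, \qquad
   L_{ce} = -\tfrac1N \sum_i \sum_j q_{ij}\log p_{ij}, \qquad
   L_c = \tfrac12 \sum_i \lVert f_i - c_{y_i}\rVert^2, \]

with Adam (learning rate 0.001), batch size 20, and 250 epochs by default
(convergence typically occurs by epoch 200; the scaled test experiments
use 50). Class centers \(c_j\) are updated after every gradient step by
the standard mini-batch rule \(c_j \leftarrow c_j - \alpha\,
\overline{(c_j - f_i)}\) with \(\alpha = 0.5\); the centers are moved by
this rule only, while the gradient of \(w\,L_c\) with respect to the
features flows through the network. The forward pass, backpropagation
through time and Adam are implemented natively in R against base matrix
operations and are verified against finite-difference gradients to
\(10^{-10}\).

Three design points deserve explanation:

* **Feature bounding and the sign of `w`.** The default center-loss weight
  is the published value \(-0.001\). A negative weight *rewards* distance
  from the class center, so with an unbounded (linear) feature layer it
  drives the features apart without limit and training collapses -- we
  observed exactly this. With the sigmoid feature layer the features live
  in \([0,1]^{64}\), the repulsion is bounded, and training converges for
  either sign. When compact class clusters are the goal (the usual purpose
  of a center loss), a positive weight is the coherent setting. At
  magnitude 0.001, however, the center force is smaller than run-to-run
  trajectory noise: across paired same-seed runs the held-out intraclass
  spread moves both ways, and at short training budgets the pull toward
  lagged centers even slows cross-entropy convergence -- which is itself
  the dominant compaction force. The compaction mechanism is demonstrable
  at `w = 0.01`, where the package's tests observe consistently tighter
  held-out clusters than `w = 0` at convergence; users who want the
  center loss to matter should use weights of that order.
* **Input standardization.** Reflectance contrasts between crop classes
  are a few hundredths on a [0, 1] scale. At the small sample sizes of the
  synthetic experiments (hundreds of samples rather than tens of
  thousands, tens of epochs rather than hundreds over huge archives), the
  printed learning rate and batch size do not move the network far enough
  to exploit those contrasts. `trainClassifier()` therefore estimates a
  per-(period, band) mean and standard deviation on the training set,
  stores them in the model object, and applies them to every input at
  training and prediction time (`standardize = TRUE`). This is the
  standard remedy and is part of the model contract, not a preprocessing
  step the user must remember.
* **Initialization scale.** With only four timesteps, the danger in a
  3-layer stack is signal attenuation, not exploding recurrence. The LSTM
  weight matrices are initialized uniform with bounds
  `initScale / sqrt(hiddenDim)`; the default `initScale = 3` keeps the
  top-layer state responsive to the input, whereas the common
  `1 / sqrt(hiddenDim)` scale leaves it nearly constant and training
  stalls at small step budgets. Both knobs are exposed in
  `classifierConfig()`.

"250 iterations" is read as 250 epochs: at batch size 20 a per-batch
reading would mean fewer than one pass over a realistically sized training
set, which is incompatible with the observation that convergence occurs
"after 200". The cross-entropy is implemented with the one-hot labels as
weights and the predicted probabilities inside the logarithm -- the only
finite reading for hard labels. The 24 features enter as a 4-step by
6-band sequence (spectral vector per period) rather than a 24-step scalar
sequence; this matches the spectral-temporal framing, but the alternative
cannot be ruled out from the published description.

The model is trained on all four classes to keep per-class supervision,
and binarized only at mapping time: `predictBinary()` outputs 1 where the
argmax class is maize and 0 otherwise, with `NA` for pixels lacking a
valid composite period.

## Post-processing

`applyCroplandMask()` zeroes predictions outside an external cropland
layer; a schedule maps each map year to a mask vintage (default: 2013--2015
to a 2015 mask, 2016--2019 to a 2019 mask, 2020--2021 to a 2020 mask).
`removeSpeckle()` removes 4-connected maize components smaller than
`minPatchPx` (default 4 pixels, about 0.36 ha at 30 m -- a conventional
minimum mapping unit; the method choice is ours, as no specific filter is
prescribed by the source material). The pipeline masks first and
despeckles second, following the narrative order of the workflow; the two
orders are not equivalent (masking can cut a large component below the
minimum mapping unit) and the test suite pins down a concrete example.
Both operators are idempotent and can only remove maize pixels, never
create them.

## Evaluation

`confusionCounts()` uses the rows-are-truth, columns-are-prediction
orientation. `accuracyMetrics()` reports per-class user's accuracy
(column-wise precision), producer's accuracy (row-wise recall), their
harmonic mean F1, and overall accuracy (trace over total), both at full
precision and rounded half-up to the printed number of decimals --
published tables round half-up, which R's `round()` does not.
`binarizeMatrix()` collapses the three non-maize classes, conserving
counts. Area consistency is the squared Pearson correlation between
region-level mapped areas (value-1 pixel count x 900 m², in hectares) and
reference areas; the Pearson reading of \(R^2\) is scale- and
offset-invariant, so `agreementR2()` (one minus SSE over SST against the
identity line) is offered as a bias-sensitive secondary statistic. With
zero-noise synthetic reference areas and a perfect map the pipeline
returns \(R^2 = 1\) exactly.

## Numerical and degenerate-input choices

* Probabilities are clipped to \([10^{-12}, 1-10^{-12}]\) before
  logarithms; training aborts with a message on non-finite loss.
* Metrics with empty rows or columns return `NA` rather than erroring;
  zero index denominators likewise yield `NA`.
* All randomness flows from integer seeds through a single splitmix-style
  derivation, so every generator, training run and the whole workflow are
  bit-reproducible; CSV artifacts of `runWorkflow()` are byte-identical
  across re-runs of the same configuration.
* Rasters are exchanged as plain multi-page TIFF (float32 reflectance,
  8-bit categorical; one page per band) on a single local metric grid;
  binary maize maps use the 1/0 encoding with 255 as nodata, and readers
  validate the encoding.

## Problem sizes used by the shipped experiments

The synthetic accuracy experiment runs a 64 x 64 grid, 16 scenes, 5% cloud
probability, 400 samples per class (70/30 split) and 50 training epochs,
and scores the final cleaned map on the held-out split; at these sizes
held-out binary overall accuracy and maize F1 above 0.95 are expected for
most seeds. The center-loss experiments use a 48 x 48 grid: the
printed-magnitude probe (w = 0.001) runs 150 samples per class for 30
epochs, and the mechanism check (w = 0.01) runs 60 samples per class for
200 epochs on a reduced 32-unit architecture so that training reaches
convergence, where the compaction force is no longer masked by the
cross-entropy dynamics. These sizes are the package's reference
experiment scales.

## Known limitations

* The simulator's clouds are spatially independent per pixel; real cloud
  fields are correlated, making scene-level screening more decisive than
  it appears here.
* Gap-filling searches the whole season, so a donor observation can come
  from a different phenological stage (and a different composite window);
  bounded-window replacement would be a natural extension.
* The per-band maximum convention can mix dates within a window
  (different bands' maxima from different days).
* No projection handling: rasters live on one local metric grid.
* Training is single-threaded by design to guarantee determinism.
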