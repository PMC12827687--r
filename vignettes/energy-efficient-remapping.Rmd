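---
title: "Energy-efficient recurrent networks of active vision: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-efficient recurrent networks of active vision: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Primates move their eyes several times a second, yet perception is stable.
A long-standing proposal is that the brain uses efference copies — internal
copies of the saccade command — to predict the post-saccadic input before it
arrives (predictive remapping). `remapnet` implements a model system for a
complementary hypothesis: that such predictive machinery need not be wired in
by design, but can emerge in a recurrent network whose only objective is to
minimize its metabolic energy consumption while excitatory sensory input
keeps arriving.

The package provides the full loop: a synthetic visual world with saccadic
sampling, the recurrent architecture, training under the energy objective and
two alternative objectives, a battery of control predictors, and the
diagnostic analyses (allocentric decoding, in-silico lesioning, feedback
similarity, spatial memory, unit clustering) that test what the trained
network has learned.

## The model

**Input.** A sequence of `F = 7` fixations on a gray-scale scene. Each
fixation contributes a square crop `v_t` (side `C`, flattened, values in
`[0, 1]`) centered on the fixation point, presented for `T = 6` model time
steps. The input vector is `x_t = [v_t, dp_t]` where `dp_t = (dx, dy)` is the
relative saccade vector in pixels toward the *next* fixation (the efference
copy). The efference slots are zero for the first half of the steps of each
fixation and carry `dp_t` for the second half — the movement plan becomes
available shortly before the saccade. The last fixation has no upcoming
saccade; its efference is the zero vector.

**Architecture.** A fully connected recurrent network: layer 0 (the input
layer, `C^2 + 2` units) and hidden layers (default two, 2,048 units each at
full scale; 256 each in the desk preset). Layer 0 receives the input as a
fixed excitatory *input drive* with no learnable parameters — the network
cannot learn to ignore its input — plus learnable top-down feedback from
hidden layer 1. Hidden layer `l` receives bottom-up, lateral, and top-down
connections. There are no biases: a bias would let units buy inhibition for
free and muddy the energy account. Updates are fully synchronous with a
one-step delay; every connection type reads the *previous* step's rectified
(ReLU) activations. Before each sequence a single all-zero warm-up input is
presented so that feedback can, in principle, already inhibit the first crop.

**Energy objective.** The loss is the mean absolute *preactivation* — the
summed input to a unit before the nonlinearity — over all units of all
layers and the `T` steps of each fixation:

```
L = 1 / (T * N) * sum_t sum_i | preactivation_{i,t} |
```

Preactivation jointly proxies the cost of firing and of synaptic
transmission. Because the input drive is fixed and excitatory, the only way
to reduce the layer-0 term is for the top-down feedback to *cancel* the
input: the ideal feedback is the negative of the upcoming crop. The warm-up
step is excluded from the loss (the per-fixation sum runs over the fixation's
steps only), but gradients flow through it.

**Training.** Adam (library-default moments), learning rate 0.0005, batch
1,024 at full scale (64 in the desk preset). One scanpath per scene is drawn
at random each epoch; gradients propagate through the entire 43-step
sequence by backpropagation through time. The learning rate of each weight
matrix is rescaled by its source-layer width: a matrix from a wider source
into a narrower target gets `lr * W_target / W_source`, all others keep the
base rate (at full scale this gives the first bottom-up matrix the factor
2,048/16,386 and leaves every other matrix unchanged). The forward/backward
engine is hand-written in base R matrix algebra; a finite-difference
gradient check is part of the test suite.

**Initialization and criticality.** Weights are He-uniform,
`U(-sqrt(6/N_in), sqrt(6/N_in))`, where `N_in` is the input size of the
matrix's *target layer*: the summed width of all learnable afferents
arriving there (for layer 0 that is just hidden layer 1, since the input
drive is not learnable). This choice is deliberate. If instead each matrix
were scaled by its own source width alone, a hidden layer fed by three
matrices would amplify activity threefold per step and the untrained
network's preactivations would grow explosively over the 43 recurrent steps
of a sequence (mean |preactivation| of order 10^4 at desk scale); training
then spends its entire budget taming the explosion rather than learning
prediction. Sharing `N_in` across a layer's afferents puts the expected
per-step activity gain at one — the dynamics are critical, neither dying
nor exploding — which is what He initialization is meant to achieve for
ReLU units.

## The synthetic world

Model systems of this kind are typically driven by natural photographs with
scanpaths from a saliency model of human fixation behavior. This package is
self-contained instead: scenes are 1/f-filtered Gaussian noise,
min-max rescaled to `[0, 1]` (`generate_scene()`), which reproduces the
spectral statistics of natural images — strong spatial correlations, energy
concentrated at low frequencies — though not their objects, occlusions, or
higher-order structure. Scanpaths start at the scene center and take
isotropic Gaussian saccade steps (sd `side/4` pixels, rounded to integers),
clamped componentwise so every crop lies fully inside the scene: extraction
is a pure slice and never pads. This yields a human-like mixture of short
and long saccades and frequent near-refixations, without a saliency model.
Coordinates are 0-based `(x = column, y = row)`; a crop covers the half-open
window `[c - floor(C/2), c - floor(C/2) + C)`.

For the categorization control objective, scenes can carry synthetic
multi-hot labels: each scene adds a few class-specific grating components
(deterministic frequency/orientation per class) to the noise background, and
the label marks which classes are present — emulating object annotations at
desk scale.

What passing tests on this world do *not* show: that the same quantitative
results hold for natural images (absolute loss values depend strongly on
image statistics), or that scanpath statistics beyond "center-anchored with
bounded, overlapping steps" matter. What they do show: the qualitative
emergence claims — inhibitory feedback, use of efference copies, allocentric
coding, the causal role of the coding units — follow from the energy
objective alone under naturalistic input statistics.

## Controls and the common metric

All conditions are compared on one scale: the mean absolute layer-0
image-unit preactivation at each fixation's *first* step — the transition
moment at which the previous fixation's prediction meets the new input.
For a template control the equivalent quantity is `mean |crop - prediction|`,
the preactivation that would result if the feedback exactly equalled the
negative prediction. The efference slots are excluded from this metric (and
from all feedback images): they are bookkeeping channels, not visual units.
The conditions are: the trained model; the same model evaluated with
shuffled efference copies (coordinates permuted within sequence, never the
identity permutation, crops kept in order, efferences recomputed); a model
trained without efference input; a model trained with a visual field reduced
by 56% (side `round(C * sqrt(0.44))`); and four model-free predictions —
average training luminance, average training crop, the location-specific
crop of the average training scene, and the previous fixation's crop (zero
prediction at the first fixation). Condition means are compared by Welch
two-sample t tests with 99% normal-approximation confidence intervals; Welch
rather than pooled-variance because nothing guarantees equal variances
across conditions.

## The analysis battery

* **Allocentric decoding** (`collect_activations()`,
  `fit_allocentric_decoder()`): one row per test fixation, hidden
  activations concatenated over layers and all `T` steps, z-scored with
  parameters from a scene-wise fit subset. Ridge regression per coordinate
  with the penalty chosen on held-out *scenes* within the fit subset
  (`lambda = 0`, ordinary least squares, is in the grid and wins whenever
  the problem is well-posed); reported R-squared comes from scenes never
  used for fitting. Per-unit importance ("beta") is the summed absolute
  coefficient over the unit's time-step columns and both coordinates.
* **Lesioning** (`select_units_by_beta()`, `lesion_experiment()`): the
  top-beta units (22 of 4,096 at full scale, scaled proportionally with a
  floor of 4 at desk scale) are silenced at runtime and compared against an
  equally sized random lesion on identical fixations.
* **Feedback statistics** (`feedback_inhibition_stats()`): the spatial mean
  of the layer-0 feedback image per crop and step; the grand mean is
  negative in the trained model — the network pays for inhibition because
  it saves more on the input side.
* **Similarity analysis** (`similarity_matrix()`,
  `hypothesis_correlation()`): the feedback image at every step is
  correlated with the *ideal inhibition* (the negative of each crop),
  giving a `(F*T) x F` matrix per sequence; binary hypothesis matrices mark
  the cells where the drive matches the upcoming crop (`H_future`) versus
  the current crop (`H_current`), and per-sequence correlations with each
  are tested against zero.
* **Spatial memory** (`spatial_memory_analysis()`): within-sequence fixation
  pairs up to lag 3 are classified by the distance between their locations
  (terciles of all pairwise distances) and the mean z-scored loss of the
  pair's second fixation is tabulated.
* **Unit clustering** (`unit_spatial_profiles()`,
  `cluster_allocentric_units()`): per-unit spatial tuning profiles (mean
  activation per fixation-position bin) are standardized, projected on up
  to 10 principal components, and k-means clustered with the cluster count
  chosen by silhouette maximization.

## Parameters that matter

| Parameter | Default (full / desk) | Meaning |
|---|---|---|
| scene side `S` | 256 / 64 px | scene resolution |
| crop side `C` | 128 / 32 px | visual field; valid fixation region is `[C/2, S - C/2]` |
| fixations `F` | 7 | sequence length |
| steps per fixation `T` | 6 | recurrent settling time per crop |
| efference onset | 0.5 | fraction of `T` after which `dp` is visible |
| hidden sizes | 2 x 2,048 / 2 x 256 | hidden populations |
| learning rate | 0.0005 | Adam base rate before per-matrix rescaling |
| batch | 1,024 / 64 | sequences per update |
| saccade sd | `S/4` px | scanpath step scale |
| InfoNCE `tau`, negatives, lag | 0.1, 8, 2 | contrastive control objective |
| classes | 91 | categorization control objective |

## Numerical and design choices

* Synchronous one-step-delay updates for all connection types: the simplest
  rule consistent with a fixed number of steps per fixation; no staging
  order has to be invented.
* The warm-up step is a real model step (it shapes later activity and
  gradients flow through it) but is excluded from the loss and from all
  per-step statistics, which count `F * T` steps per sequence.
* Efference values are raw pixel displacements by default
  (`efference_scale = 1`); a scale flag exists for numerical experiments
  but is off in all presets.
* The shuffled-efference control redraws a uniformly random non-identity
  permutation per sequence, seeded.
* Degenerate similarity entries (a constant feedback image or crop) are set
  to 0 and counted rather than propagated as `NA`.
* Distance terciles use the 33.3/66.7 empirical percentiles (type-7
  quantiles); z-scoring uses the mean and sd over all test-fixation losses,
  and collapses to zeros when the losses are constant.
* Decoder tie-breaks: unit selection orders by descending beta, then by
  unit index, so selections are deterministic.
* All randomness flows through a single master seed per experiment
  (`desk_config(seed)`), from which every stage derives its own 32-bit seed.

## The desk preset and what it can show

The desk preset (`desk_config()`) — 64-px scenes, 32-px crops, two hidden
layers of 256 units, 500 training and 50 test scenes, batch 64, at most 50
epochs with early stopping on a held-out plateau — is sized so that the
full pipeline (dataset, training, controls, analyses) runs on a single CPU
in minutes (roughly 13 Gflop per update, 8 updates per epoch).

Emergence is a trajectory, and the position reached on it is set by the
total number of sequence presentations. At desk scale the model reliably
reaches the first stages: the held-out energy loss falls an order of
magnitude below the untrained baseline, the top-down feedback to layer 0
becomes strongly and significantly inhibitory, the model beats the
previous-crop predictor, and evaluating it with shuffled efference copies
raises its loss slightly. The later stages — feedback that beats the
*static* template predictors, efference-conditioned remapping toward the
upcoming crop, and decodable allocentric coordinates with their causally
relevant units — require orders of magnitude more training (the full-scale
regime presents roughly 300 times more sequences than the desk preset's
update budget) and do not appear at desk scale: at this stage the internal
drive still aligns with the *current* crop rather than the future one.
The analysis battery reports all of these quantities either way, and the
package's acceptance tests assert the full set of emergence properties at
the desk preset, documenting which stages the desk budget does and does not
reach. The alternative-objective controls (categorization, contrastive)
never approach the energy-trained model's efficiency at any stage.

## Known limitations

* The world is statistically naturalistic but semantically empty; absolute
  losses and decoding accuracies are not comparable to natural-image runs.
* Backpropagation through time is biologically implausible; the package
  makes no claim about the learning rule, only about the objective.
* The full-scale preset (`paper_config()`) is provided as a configuration
  object; running it requires accelerator-scale resources and is not
  exercised by the test suite.
* Fixation coordinates are integer pixels; sub-pixel saccade modeling and
  retina-like foveated sampling are out of scope.
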