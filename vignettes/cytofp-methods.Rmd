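---
title: "Methods: cytometric fingerprinting and its machine-learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytometric fingerprinting and its machine-learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofp)
```

## The problem and the representation

Label-free microbial flow cytometry records, for every particle passing
the laser, a small vector of scatter and fluorescence intensities. For
community-level monitoring the unit of interest is not the single cell
but the *distribution* of cells: a perturbation (a carbon source, a
nanoparticle dose, an antibiotic) shifts the joint distribution of cell
size (FSC-A), granularity (SSC-A) and autofluorescence (AmCyan-A) long
before any physico-chemical reactor variable reacts.

`cytofp` represents a sample by chunk fingerprints: after gating,
consecutive runs of `chunk_size` events (default **B = 1000**) are
flattened into one vector of length 3B, as three contiguous channel
blocks (FSC-A block first, then SSC-A, then AmCyan-A). Two properties
motivate this default:

* 1000 events is the classical worst-case Wald sample size at roughly a
  3% margin of error for a proportion (`wald_sample_size(0.03)` gives
  1068 at 95% confidence; 1000 corresponds to a slightly lower
  confidence level). A chunk therefore carries a stable estimate of the
  community's event distribution.
* With 100,000 events per sample file the chunking yields exactly 100
  vectors per sample, and a triplicate × five-time-point class design
  yields 1,500,000 events = 1500 vectors per class, which a 75/25
  stratified split divides into 1125/375.

Chunks are consecutive acquisition runs with the trailing remainder
discarded — `floor(N/B)` vectors, no overlap. Whether chunks should be
consecutive runs or random draws of events is a genuinely open design
point; consecutive is the default because it needs no extra randomness
and preserves any slow acquisition-order drift as signal, and
`chunk_method = "random"` is available. Likewise event order inside a
block is kept as acquired by default; `sort_within = "ascending"` sorts
each channel block, making the fingerprint permutation-invariant (a
distribution summary rather than a sequence), at the cost of breaking
the event-wise correspondence across blocks.

### Gating

Instrument gating templates are graphical and instrument-specific, so
the package implements the *intent* — exclude low-signal background
(dead cells, debris) and high-FSC putative doublets — as axis-aligned
thresholds in `gate_config()`: per-channel lower bounds and an FSC-A
upper bound. The default gate is a no-op; numeric thresholds are
configuration because no universally valid values exist. Gating is
idempotent and order-preserving by construction.

### File formats

FCS 3.0/3.1 list-mode files are read directly (float, double or integer
data, either byte order, channel names from `$PnN`, case-sensitive);
files are written as FCS 3.1, single dataset, 32-bit float,
little-endian — the most interoperable combination. Round trips
preserve channel names exactly and values to single precision. CSV
(header row of channel names, one event per row) is supported as the
plain-text equivalent.

## The synthetic study generator

`class_distribution()` models one perturbation class as a mixture of
**zero-truncated Gaussians** in the raw intensity scale, with per-class
component locations, scales and weights, plus an additive mean drift
per time point. This emulates what matters to the downstream analysis:
measured channel values that are approximately normal within a
sub-population, non-negative intensities, multimodality from community
sub-structure, and slow temporal shifts. Truncation uses the exact
inverse-CDF method. Per-sample seeds are derived deterministically from
the study seed and the (class, replicate, time point) coordinates, so a
fixed `study_design()` reproduces byte-identical files.

`default_study_design()` is the package's reference condition: four
classes (cellulose-, glucose-, propionate- and acetate-fed), two
mixture components each, triplicates over five time points, 100,000
events per sample, and between-class channel separations of many pooled
standard deviations (pooled sds are 15–40 intensity units; class
centres differ by hundreds). It is deliberately *separable*: any sound
classifier should approach perfect accuracy on it, so it functions as a
positive control, and label-permuted copies of it as a negative
(chance-level) control.

What the generator does **not** emulate: optics (spillover,
log-amplifier artefacts), doublet formation, event-rate effects,
heavy-tailed debris, or biologically realistic overlap between
functional groups. Passing tests on this generator therefore
demonstrate that the pipeline's mechanics and statistics are correct —
not that real communities are this easy; on instrument data the
accuracies will be far from 1 and threshold choices matter.

## Autoencoder anomaly screening

A single-hidden-layer autoencoder (default width 2000 for 3000-long
fingerprints) is trained to approximate the identity map through a
bottleneck; the anomaly score of a vector is the reconstruction mean
squared error. Numerical choices:

* **MSE scaling.** The squared norm ‖x − x′‖² is divided by the input
  dimension (per-coordinate mean), so thresholds are comparable across
  chunk sizes; `normalize = FALSE` gives the raw squared norm.
* **Input standardization.** Features are standardized per feature on
  the training set and identically at scoring. Reported MSEs are in
  standardized units; raw-scale MSE thresholds from other instruments
  or studies do not transfer, which is why the threshold is
  configuration.
* **Sample score.** One score per sample is the *mean* of its vector
  MSEs (median and max are options; a sample-level plot needs one value
  per sample and the mean is the least variance-inflating choice for
  ~100 vectors).
* **Threshold policy.** When no numeric threshold is supplied,
  `training_threshold()` uses the 95th percentile of training-sample
  scores, so about 5% of in-distribution samples are flagged by
  construction. Outliers are strictly above the threshold (a score
  exactly at the threshold is not an outlier).
* **Training.** Bounded tanh activation by default (standardized inputs
  live in its linear range), Adam with minibatches, 10 epochs by
  default, optional L1/L2. Initialization and minibatch order are
  seeded; training is single-threaded and deterministic, and
  checkpoints round-trip scores bit-for-bit.

The package's anomaly-recovery property (tested and recomputed by the
acceptance script) holds a class out of autoencoder training, shifts
its component means by ≥ 5 pooled standard deviations off the training
support, and checks that (a) the held-out class's mean sample MSE
strictly exceeds every training class's mean, and (b) the
95th-percentile threshold flags all its samples while flagging ≤ 10% of
training samples. Note the direction of the shift matters: a shift that
lands a class *inside* another class's region is not an anomaly in any
detectable sense.

## Supervised models

All four classifiers share `train_classifier()` /
`predict_proba()` / `accuracy()`, so they are directly swappable in
comparisons. Class order is lexicographic everywhere. Defaults pin the
reference configuration; every value is overridable per
`model_spec()`:

| algorithm | backbone | defaults |
|---|---|---|
| GB  | xgboost, multinomial softprob | 200 trees, depth 5, learning rate 0.1 |
| DRF | ranger, probability forest | 200 trees, depth 20 |
| NB  | in-package Gaussian naive Bayes | variance floor 1e-9 × pooled feature variance; Laplace-smoothed priors |
| DL  | in-package feed-forward net | hidden (2000, 1000, 500), rectifier + dropout (input 0.1; hidden 0.2/0.2/0.1), 10 epochs, L1 and L2 both 1e-5 |

Notes on the in-package components:

* **NB** floors per-class variances at `1e-9 ×` the pooled feature
  variance (absolute floor 1e-12) so constant within-class features
  cannot zero a density; posteriors are computed in log space with
  log-sum-exp normalization. The implementation is checked against a
  brute-force Bayes computation and against an independent library
  implementation in the tests.
* **DL** applies both L1 and L2 at 1e-5 by default; each is
  independently switchable to either-or. The network and the
  autoencoder share one seeded engine (Glorot-uniform init, inverted
  dropout, Adam), which keeps the layer weights inspectable — required
  for the variable-importance read-out below.
* Tree models run single-threaded with fixed seeds, so the whole
  comparison is deterministic given (data, specs, seeds).

Per-class accuracy is the recall of the true class under argmax. An
optional per-class decision threshold (`class_thresholds`) reproduces
the fixed-threshold variant of per-class accuracy, in which a
prediction only counts if its probability clears the class's threshold;
threshold-swept AUCs and fixed-threshold accuracies can legitimately
rank models differently, which is why both surfaces are reported.

### Nested cross-validated grid search

`nested_cv_grid_search()` uses stratified 4-fold outer / 3-fold inner
partitions. Per outer fold, the inner CV selects the grid point with
the best inner mean accuracy (ties: smaller inner sd, then grid order);
the selected point is refit on the outer-training part and scored on
the untouched outer fold. The reported best hyperparameters maximize
mean outer accuracy among selections with the same tie-breaking. The
hyperparameter grids themselves are study-specific and are supplied as
configuration (per-algorithm `grid` entries in the pipeline config),
not hard-coded. `kfold_stability()` (default k = 5) is the
overfitting check: fold accuracies of a stable model track its held-out
accuracy.

## Evaluation surfaces

* **One-vs-all ROC/AUC.** Threshold set = unique observed scores plus a
  sentinel above all, giving the exact step-function ROC; AUC is the
  trapezoidal integral and equals the Mann–Whitney pair-counting
  probability with ties counted ½ (asserted to 1e-12 in the tests).
  Only per-class AUCs are reported; no macro/micro averaging is
  introduced.
* **Confusion matrices** over the lexicographic label set; row sums are
  per-class support.
* **Probability box-plot data**: per true class, the five-number
  summary of every class's predicted probability.
* **Gedeon-style importance** for the network: with first- and
  second-layer weight matrices `w1`, `w2`,
  `score_i = Σ_j (|w1_ij| / Σ_i′ |w1_i′j|) · Σ_k (|w2_jk| / Σ_j′ |w2_j′k|)`,
  i.e. absolute weight shares propagated through the first two hidden
  layers — the canonical two-layer magnitude-propagation form. Scores
  are normalized to max 1; channel-block scores are sums of the
  normalized per-variable scores over each block. Importance is defined
  only for the DL model, whose weights are available.

All plot artefacts exist as data first (tidy tibbles / CSVs from the
pipeline); `autoplot()` renders them, so no test ever reads pixels.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/ingest → gate → vectorize →
club → split → anomaly screen → model comparison → reports from one
validated `pipeline_config()` (unknown keys anywhere are errors — a
typo in a hyperparameter name fails fast instead of silently using a
default). All randomness flows from the single top-level seed through
named sub-seeds per stage (a deterministic string hash), so re-running
a resolved config reproduces every report CSV byte for byte. Each
stage logs its input/output record counts to `run_log.csv`; a failing
stage aborts with its name and leaves a `FAILED` marker beside the
partial outputs.

## Problem sizes used in tests

The tests and the acceptance script run the same procedures at reduced
scale, chosen so the full suite completes in minutes while keeping the
study structure intact: 25–50-event chunks (75–150-long fingerprints),
600–2500 events per sample, duplicate-to-triplicate designs over 2–5
time points, tree ensembles of 15–100 trees, network layouts of
(16, 8, 4)–(64, 32, 16) units, and an autoencoder of 8–16 hidden units
trained for up to 20 epochs. The acquisition-scale bookkeeping
(100,000-event samples, 1000-event chunks, 1500 vectors per class,
1125/375 splits) is exercised once at full size, since it is cheap.

## Known limitations

* The FCS writer targets the common list-mode/float case; exotic FCS
  features (multiple datasets, bit-packed integers, analysis segments)
  are out of scope.
* Axis-aligned threshold gating cannot express polygonal or elliptical
  gate geometry; compensation and display transforms (logicle/arcsinh)
  are deliberately not implemented.
* The autoencoder embedding is not exposed as a preprocessing step for
  the supervised models — anomaly screening and classification are
  independent analyses by design.
* The default stratified split is by vector; vectors from one sample
  are correlated, so the default estimate is optimistic about
  generalization to new samples. `group_by_replicate = TRUE` provides
  the leakage-controlled variant.
* Synthetic separability means synthetic accuracies are ceilings, not
  forecasts, for instrument data.
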