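# cytofp — cytometric fingerprinting and machine learning for microbial community monitoring

Label-free flow cytometry measures every cell ("event") of a microbial
community on three channels — forward scatter (`FSC-A`, cell size), side
scatter (`SSC-A`, granularity/morphology) and `AmCyan-A`
autofluorescence — at ~100,000 events per sample in minutes. `cytofp`
turns these raw event clouds into *cytometric fingerprints* and analyzes
them with machine learning, aimed at monitoring anaerobic-digester
microbiomes (and other perturbed communities) far faster than
sequencing-based profiling:

1. **Fingerprinting.** After threshold gating (debris floor, FSC doublet
   ceiling), consecutive chunks of *B* = 1000 events are flattened into
   vectors of length 3·*B* = 3000, laid out as channel blocks
   (`V1..V1000` = FSC-A, `V1001..V2000` = SSC-A, `V2001..V3000` =
   AmCyan-A). A 100,000-event sample yields 100 vectors; a class
   measured in triplicate over five time points yields
   1,500,000 events and 1500 vectors. The chunk size of 1000 is the
   Wald-type sample size at roughly a 3% margin of error
   (n = z²·0.25/e²; see `wald_sample_size()`).
2. **Anomaly screening.** A single-hidden-layer autoencoder (reference
   width 2000) is trained to reconstruct in-distribution fingerprints;
   a sample whose mean reconstruction error
   MSE(x, x′) = ‖x − x′‖²/p exceeds a threshold (by default the 95th
   percentile of training-sample scores) is flagged as a significantly
   perturbed community.
3. **Classification.** Four supervised models — gradient boosting (GB),
   Gaussian naive Bayes (NB), random forests (DRF) and a
   three-hidden-layer feed-forward network (DL; 2000/1000/500 units,
   rectifier with dropout) — share one train/predict surface and are
   compared by per-class accuracy and one-vs-all ROC/AUC, with
   perturbation labels optionally *clubbed* into the four putative
   anaerobic-digestion groups: HYDRO (hydrolyzers, cellulose-fed), ACIDO
   (acidogens, glucose-fed), ACETO (syntrophic acetogens,
   propionate/butyrate-fed) and METHA (methanogens, acetate/sludge/unfed).
   Hyperparameters can be tuned by nested cross-validation (4 outer / 3
   inner folds); the network's channel relevance is read out by
   Gedeon-style weight propagation through the first two hidden layers.

A class-conditional synthetic event-cloud generator (truncated Gaussian
mixtures with per-class locations, scales, weights and time drift)
reproduces the structure of such studies so the whole pipeline is
testable without instrument data. The package reads and writes FCS
3.0/3.1 list-mode files and per-event CSVs.

## Worked example

A compact separable four-class study (1500 events/sample, 50-event
chunks, so 150-long fingerprints):

```r
library(cytofp)
library(dplyr)

design   <- default_study_design(events_per_sample = 1500, seed = 1)
manifest <- read_manifest(simulate_study(design, tempfile("demo")))
ds    <- fingerprint_dataset(manifest, chunk_size = 50) |> club_labels()
parts <- split_train_test(ds, train_fraction = 0.75, seed = 1)

dl <- train_classifier(
  model_spec("DL", list(hidden = c(64, 32, 16), epochs = 10), seed = 1),
  parts$train)
accuracy(dl, parts$test)$per_class
#> ACETO ACIDO HYDRO METHA
#>     1     1     1     1

glance(one_vs_all_roc(predict_proba(dl, parts$test),
                      parts$test$label, "METHA"))
#> # A tibble: 1 × 3
#>   class   auc n_thresholds
#>   <chr> <dbl>        <int>
#> 1 METHA     1          449

ae  <- train_autoencoder(parts$train, autoencoder_config(
  hidden_nodes = 16, epochs = 20, learning_rate = 3e-3, seed = 1))
thr <- training_threshold(ae, parts$train)   # 95th-percentile policy
glance(score_samples(ae, parts$test, threshold = thr))
#> # A tibble: 1 × 4
#>   threshold aggregate n_samples n_outliers
#>       <dbl> <chr>         <int>      <int>
#> 1    0.0572 mean             60          6
```

All four classes are perfectly recoverable on this synthetic study —
the classes are separated by many pooled standard deviations by
construction — and the anomaly screen flags 6/60 in-distribution
samples at the 95th-percentile threshold, i.e. its configured false-flag
budget. Held-out classes shifted off the training distribution score
orders of magnitude higher (see the methods vignette). `autoplot()`
methods draw the MSE-vs-sample screen, ROC curves and channel-block
importance; `run_pipeline()` executes the whole chain from one validated
config and writes every report as CSV.

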