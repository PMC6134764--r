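# Shared small fixtures, built once per test run. Scales are reduced
# (short chunks, few events) so the whole suite runs in minutes; the
# statistical structure (4 separable mixture classes, triplicate-style
# layout) matches the package defaults.

two_comp_class <- function(label, mu, sd = c(20, 20, 20), delta = c(60, 40, 30),
                           w = 0.6) {
  class_distribution(label, list(
    list(weight = w, mean = mu, sd = sd),
    list(weight = 1 - w, mean = mu + delta, sd = sd * 1.2)))
}

# one deterministic event matrix for io/fingerprint tests
tiny_em <- function(n = 120, seed = 42) {
  with_seed <- getFromNamespace("with_seed", "cytofp")
  ev <- with_seed(seed, matrix(abs(rnorm(n * 3, c(300, 200, 100), 30)),
                               n, 3, byrow = TRUE))
  event_matrix(ev, analysis_channels(), sample_id = "tiny")
}

# small separable 4-class fingerprint dataset (cached across tests)
.cytofp_test_cache <- new.env(parent = emptyenv())

small_study_design <- function(events = 1000, reps = 2, tps = 2, seed = 5) {
  default_study_design(events_per_sample = events, replicates = reps,
                       timepoints = tps, seed = seed)
}

small_ds <- function() {
  if (!is.null(.cytofp_test_cache$ds)) return(.cytofp_test_cache$ds)
  dir <- file.path(tempdir(), "cytofp-small-study")
  man <- simulate_study(small_study_design(), dir)
  ds <- fingerprint_dataset(read_manifest(man), chunk_size = 25)
  .cytofp_test_cache$ds <- ds
  ds
}

fp_cols <- function(ds) grep("^V[0-9]+$", names(ds), value = TRUE)

# first n vectors of every label (keeps subsets multi-class)
per_label_head <- function(ds, n) {
  dplyr::ungroup(dplyr::slice_head(dplyr::group_by(ds, label), n = n))
}

# a labelled fingerprint tibble built directly from a value matrix
fp_tibble <- function(X, label, sample_id = "s") {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id,
                   chunk_index = seq_len(nrow(X)),
                   label = label),
    tibble::as_tibble(as.data.frame(X)))
}
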