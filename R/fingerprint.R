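fp_meta_cols <- c("sample_id", "chunk_index", "label", "replicate",
                  "timepoint")

fp_value_cols <- function(ds) grep("^V[0-9]+$", names(ds), value = TRUE)

#' Extract the fingerprint value matrix from a dataset
#'
#' @param ds A fingerprint tibble (columns `V1..Vp` plus metadata).
#' @return Numeric matrix, one row per fingerprint vector.
#' @export
fp_values <- function(ds) {
  cols <- fp_value_cols(ds)
  assert_that(length(cols) > 0, "No fingerprint value columns (V1..Vp) found.")
  as.matrix(ds[, cols])
}

#' Vectorize an event cloud into fixed-length fingerprints
#'
#' Consecutive, non-overlapping chunks of `chunk_size` events (in
#' acquisition order) are flattened into one fingerprint vector each; a
#' trailing remainder shorter than `chunk_size` is discarded. The vector
#' is laid out as three contiguous channel blocks — with the default
#' `chunk_size = 1000`, positions `V1..V1000` hold FSC-A, `V1001..V2000`
#' SSC-A and `V2001..V3000` AmCyan-A — so a 100,000-event sample yields
#' 100 vectors of length 3000.
#'
#' @param em An `event_matrix` with exactly the three analysis channels in
#'   canonical order (see [select_channels()]).
#' @param chunk_size Events per fingerprint vector (default 1000, the
#'   sample size at which a Wald-type confidence interval on a proportion
#'   reaches roughly a 3% margin).
#' @param chunk_method `"consecutive"` (default) assigns acquisition runs;
#'   `"random"` permutes events (seeded) before chunking.
#' @param sort_within `"none"` (default) keeps acquisition order inside
#'   each channel block; `"ascending"` sorts each block, making the
#'   fingerprint invariant to event order.
#' @param seed Seed for `chunk_method = "random"`.
#' @return A tibble with one row per fingerprint: columns `sample_id`,
#'   `chunk_index`, `label` (`NA` until labelled) and `V1..V(3*chunk_size)`.
#' @export
vectorize <- function(em, chunk_size = 1000,
                      chunk_method = c("consecutive", "random"),
                      sort_within = c("none", "ascending"), seed = 1) {
  stopifnot(inherits(em, "event_matrix"))
  chunk_method <- match.arg(chunk_method)
  sort_within <- match.arg(sort_within)
  assert_that(length(em$channel_names) == 3 &&
                all(em$channel_names == analysis_channels()),
              paste("Vectorization expects exactly the channels",
                    paste(analysis_channels(), collapse = ", "),
                    "in that order; use select_channels() first."),
              class = "cytofp_config_error")
  assert_that(chunk_size >= 1, "`chunk_size` must be >= 1.")
  n <- n_events(em)
  n_chunks <- n %/% chunk_size
  p <- 3L * chunk_size
  vnames <- paste0("V", seq_len(p))
  if (n_chunks == 0) {
    out <- as_tibble(matrix(numeric(0), 0, p), .name_repair = ~vnames)
    return(bind_cols(tibble(sample_id = character(0),
                            chunk_index = integer(0),
                            label = character(0)), out))
  }
  ev <- em$events
  if (chunk_method == "random") {
    perm <- with_seed(seed, sample.int(n))
    ev <- ev[perm, , drop = FALSE]
  }
  ev <- ev[seq_len(n_chunks * chunk_size), , drop = FALSE]
  # rows = chunks; channel blocks concatenated FSC -> SSC -> AmCyan
  blocks <- lapply(1:3, function(ch) {
    b <- matrix(ev[, ch], nrow = chunk_size, ncol = n_chunks)
    if (sort_within == "ascending") b <- apply(b, 2, sort)
    t(b)
  })
  vals <- do.call(cbind, blocks)
  colnames(vals) <- vnames
  bind_cols(tibble(sample_id = em$sample_id,
                   chunk_index = seq_len(n_chunks), label = NA_character_),
            as_tibble(vals))
}

#' Summary-statistics featurizer (optional alternative to raw fingerprints)
#'
#' Per-channel distribution statistics (mean, SD and selected percentiles)
#' of a gated event cloud — a much lower-dimensional community summary for
#' quick exploratory work. The raw chunk fingerprint from [vectorize()] is
#' the primary representation.
#'
#' @param em An `event_matrix`.
#' @param probs Percentiles to report.
#' @return A one-row tibble of `channel_stat` columns.
#' @export
channel_stats <- function(em, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stats_one <- function(x) {
    qs <- quantile(x, probs = probs, names = FALSE)
    setNames(c(mean(x), sd(x), qs),
             c("mean", "sd", paste0("p", probs * 100)))
  }
  out <- unlist(lapply(seq_along(em$channel_names), function(i) {
    setNames(stats_one(em$events[, i]),
             paste0(gsub("[^A-Za-z0-9]", "", em$channel_names[i]), "_",
                    names(stats_one(em$events[, i]))))
  }))
  bind_cols(tibble(sample_id = em$sample_id), as_tibble(as.list(out)))
}

#' Build a labelled fingerprint dataset from a manifest
#'
#' Reads each manifest row's event file, gates it, selects the analysis
#' channels, vectorizes and attaches the label and provenance columns.
#'
#' @param manifest Tibble from [read_manifest()] (or with the same
#'   columns).
#' @param gate A [gate_config()] (default: no-op).
#' @param chunk_size,chunk_method,sort_within,seed Passed to [vectorize()].
#' @return A labelled fingerprint tibble with provenance columns
#'   `replicate` and `timepoint`.
#' @export
fingerprint_dataset <- function(manifest, gate = gate_config(),
                                chunk_size = 1000,
                                chunk_method = "consecutive",
                                sort_within = "none", seed = 1) {
  parts <- purrr::pmap(
    list(manifest$sample_id, manifest$path, manifest$label,
         manifest$replicate, manifest$timepoint_day),
    function(sid, path, label, repl, tp) {
      em <- read_events(path, sample_id = sid)
      em <- select_channels(apply_gate(em, gate), analysis_channels())
      fp <- vectorize(em, chunk_size = chunk_size,
                      chunk_method = chunk_method,
                      sort_within = sort_within,
                      seed = derive_seed(seed, sid))
      fp$label <- label
      fp$replicate <- repl
      fp$timepoint <- tp
      fp
    })
  out <- bind_rows(parts)
  relocate(out, any_of(fp_meta_cols))
}

#' Default clubbing of perturbation labels into putative functional groups
#'
#' Maps carbon-source perturbation labels onto the four putative
#' anaerobic-digestion groups: cellulose-fed to hydrolyzers (`HYDRO`),
#' glucose-fed to acidogens (`ACIDO`), propionate/butyrate-fed to
#' syntrophic acetogens (`ACETO`), and acetate-fed, sludge-fed and unfed
#' communities to methanogens (`METHA`).
#'
#' @return Named character vector (source label -> group label).
#' @export
default_clubbing_map <- function() {
  c(CELL = "HYDRO", GLUC = "ACIDO", PROP = "ACETO", BUTY = "ACETO",
    ACET = "METHA", SLUD = "METHA", BLAN = "METHA", NONE = "METHA")
}

#' Club dataset labels into group labels
#'
#' Replaces each fingerprint's label by its group label under `map`;
#' vector values and provenance are untouched.
#'
#' @param ds Labelled fingerprint tibble.
#' @param map Named character vector mapping every label in `ds` to a
#'   group label (default [default_clubbing_map()]).
#' @return The relabelled tibble.
#' @export
club_labels <- function(ds, map = default_clubbing_map()) {
  labels <- unique(ds$label)
  unmapped <- setdiff(labels, names(map))
  if (length(unmapped) > 0) {
    abort(sprintf("Label(s) not covered by the clubbing map: %s",
                  paste(unmapped, collapse = ", ")),
          class = "cytofp_clubbing_error")
  }
  mutate(ds, label = unname(map[.data$label]))
}

#' Stratified train/test split of a fingerprint dataset
#'
#' Per-label random split: with `n` vectors of a label, the training part
#' receives `round(train_fraction * n)` of them (half-up rounding). The
#' parts are disjoint, their union is the input, and the draw is
#' reproducible for a fixed seed. With the study-scale 1500 vectors per
#' label and the default 0.75, this gives 1125 training and 375 test
#' vectors per label.
#'
#' @param ds Labelled fingerprint tibble.
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed RNG seed.
#' @param group_by_replicate If `TRUE`, all vectors of one
#'   `(sample_id)` stay in the same part (leakage-controlled variant);
#'   stratification is then by label at the sample level.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(ds, train_fraction = 0.75, seed = 1,
                             group_by_replicate = FALSE) {
  assert_that(nrow(ds) > 0, "Dataset is empty.")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "`train_fraction` must be in (0, 1).")
  counts <- table(ds$label)
  small <- names(counts)[counts < 2]
  if (length(small) > 0 && !group_by_replicate) {
    abort(sprintf("Cannot stratify: label(s) with < 2 vectors: %s",
                  paste(small, collapse = ", ")),
          class = "cytofp_split_error")
  }
  round_half_up <- function(x) floor(x + 0.5)
  take_train <- with_seed(seed, {
    idx <- logical(nrow(ds))
    if (group_by_replicate) {
      units <- distinct(ds, .data$label, .data$sample_id)
      for (lab in sort(unique(units$label))) {
        sids <- sort(units$sample_id[units$label == lab])
        n_tr <- round_half_up(train_fraction * length(sids))
        tr_sids <- sample(sids, n_tr)
        idx[ds$label == lab & ds$sample_id %in% tr_sids] <- TRUE
      }
    } else {
      for (lab in sort(unique(ds$label))) {
        rows <- which(ds$label == lab)
        n_tr <- round_half_up(train_fraction * length(rows))
        idx[sample(rows, n_tr)] <- TRUE
      }
    }
    idx
  })
  list(train = ds[take_train, , drop = FALSE],
       test = ds[!take_train, , drop = FALSE])
}

#' Wald-type sample size for a proportion
#'
#' Number of events per chunk needed for a two-sided Wald confidence
#' interval on a proportion to reach margin `error` in the worst case
#' (p = 0.5): `n = z^2 * 0.25 / error^2`.
#'
#' @param error Target margin of error (e.g. 0.03).
#' @param conf_level Confidence level (default 0.95).
#' @return Required sample size (rounded up).
#' @export
wald_sample_size <- function(error = 0.03, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  ceiling(z^2 * 0.25 / error^2)
}

#' Write / read a fingerprint dataset as CSV
#'
#' One row per vector: metadata columns then `V1..Vp`. This is the flat
#' layout consumed by the supervised-learning stage.
#'
#' @param ds Fingerprint tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_fingerprints <- function(ds, path) {
  readr::write_csv(ds, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  ds <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  relocate(as_tibble(ds), any_of(fp_meta_cols))
}
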