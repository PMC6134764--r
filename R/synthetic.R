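#' Class-conditional event-cloud distribution
#'
#' Describes the 3-channel intensity distribution of one perturbation
#' class as a mixture of zero-truncated Gaussians, with an optional
#' additive per-time-point mean drift emulating the slow community shift
#' over an incubation. Cytometer intensities are non-negative and, within
#' a community, approximately normal per channel; a mixture with
#' class-specific locations, scales and weights captures the multimodal
#' sub-population structure that distinguishes perturbation classes.
#'
#' @param class_label Class (perturbation) label, e.g. `"GLUC"`.
#' @param components List of mixture components, each a list with `weight`
#'   (fraction; weights sum to 1), `mean` (length-3 intensity vector in
#'   channel order FSC-A, SSC-A, AmCyan-A) and `sd` (length-3 positive
#'   vector).
#' @param drift_per_day Length-3 additive mean shift per time point
#'   (default no drift).
#' @return A `class_distribution` object.
#' @examples
#' cd <- class_distribution("GLUC", list(
#'   list(weight = 0.7, mean = c(500, 300, 100), sd = c(30, 25, 15)),
#'   list(weight = 0.3, mean = c(620, 380, 140), sd = c(35, 30, 18))))
#' @export
class_distribution <- function(class_label, components,
                               drift_per_day = c(0, 0, 0)) {
  assert_that(length(components) >= 1, "At least one mixture component.")
  w <- vapply(components, function(co) co$weight, numeric(1))
  assert_that(abs(sum(w) - 1) <= 1e-9, "Component weights must sum to 1.")
  for (co in components) {
    assert_that(length(co$mean) == 3 && length(co$sd) == 3,
                "Component `mean` and `sd` must have length 3.")
    assert_that(all(co$sd > 0), "Component `sd` must be positive.")
  }
  structure(list(class_label = as.character(class_label),
                 components = components,
                 drift_per_day = as.numeric(drift_per_day)),
            class = "class_distribution")
}

#' Derive an anomaly class from a base class
#'
#' Returns a copy of `base` with every component mean shifted by `shift`
#' and relabelled. Used to emulate a significantly perturbed community
#' that was not part of autoencoder training.
#'
#' @param base A [class_distribution()].
#' @param shift Length-3 additive mean shift.
#' @param label Label for the anomaly class.
#' @return A `class_distribution`.
#' @export
make_anomaly_class <- function(base, shift, label) {
  stopifnot(inherits(base, "class_distribution"))
  comps <- lapply(base$components, function(co) {
    co$mean <- co$mean + as.numeric(shift)
    co
  })
  class_distribution(label, comps, base$drift_per_day)
}

#' Synthetic study design
#'
#' The default layout mirrors the perturbation experiments the pipeline is
#' built for: each class measured in triplicate over five time points with
#' 100,000 events per sample, i.e. 1,500,000 events per class.
#'
#' @param classes List of [class_distribution()] objects.
#' @param replicates Replicates per class per time point.
#' @param timepoints Number of time points.
#' @param events_per_sample Events per sample file.
#' @param seed Study master seed; per-sample seeds are derived
#'   deterministically from it.
#' @return A `study_design` object.
#' @export
study_design <- function(classes, replicates = 3, timepoints = 5,
                         events_per_sample = 100000, seed = 1) {
  assert_that(length(classes) >= 1, "At least one class is required.")
  for (cl in classes) stopifnot(inherits(cl, "class_distribution"))
  labels <- vapply(classes, function(cl) cl$class_label, character(1))
  assert_that(!anyDuplicated(labels), "Class labels must be unique.")
  assert_that(replicates >= 1 && timepoints >= 1 && events_per_sample >= 1,
              "replicates, timepoints and events_per_sample must be >= 1.")
  structure(list(classes = classes, replicates = as.integer(replicates),
                 timepoints = as.integer(timepoints),
                 events_per_sample = as.integer(events_per_sample),
                 seed = as.integer(seed)),
            class = "study_design")
}

# zero-truncated normal via inverse-CDF; exact and vectorized
rtruncnorm0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, lo, 1), mean, sd)
}

#' Simulate one event cloud
#'
#' Draws `n_events` events from the class mixture with component means
#' shifted by `timepoint * drift_per_day`, truncated at zero intensity.
#' Reproducible for a fixed seed.
#'
#' @param cd A [class_distribution()].
#' @param timepoint Time-point index (0-based day; multiplies the drift).
#' @param n_events Number of events.
#' @param seed RNG seed.
#' @param sample_id Sample identifier.
#' @return An [event_matrix()] with channels `FSC-A`, `SSC-A`, `AmCyan-A`.
#' @export
simulate_sample <- function(cd, timepoint = 0, n_events = 100000, seed = 1,
                            sample_id = NULL) {
  stopifnot(inherits(cd, "class_distribution"))
  assert_that(n_events >= 1, "`n_events` must be >= 1.")
  sample_id <- sample_id %||%
    sprintf("%s_t%d", cd$class_label, as.integer(timepoint))
  w <- vapply(cd$components, function(co) co$weight, numeric(1))
  drift <- cd$drift_per_day * timepoint
  ev <- with_seed(seed, {
    comp <- sample.int(length(w), n_events, replace = TRUE, prob = w)
    m <- matrix(0, n_events, 3)
    for (k in seq_along(w)) {
      idx <- which(comp == k)
      if (length(idx) == 0) next
      mu <- cd$components[[k]]$mean + drift
      s <- cd$components[[k]]$sd
      for (ch in 1:3) {
        m[idx, ch] <- rtruncnorm0(length(idx), mu[ch], s[ch])
      }
    }
    attr(m, "component") <- comp
    m
  })
  comp <- attr(ev, "component")
  attr(ev, "component") <- NULL
  em <- event_matrix(ev, analysis_channels(), sample_id = sample_id,
                     metadata = list(class_label = cd$class_label,
                                     timepoint = timepoint))
  attr(em, "component") <- comp
  em
}

#' Simulate a full study to disk
#'
#' Writes one sample file per class x replicate x time point plus a
#' manifest CSV with columns `sample_id, path, label, replicate,
#' timepoint_day`. Per-sample seeds are derived deterministically from the
#' study seed and the (class, replicate, timepoint) coordinates, so a
#' fixed design yields identical files.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"fcs"` for the sample files.
#' @return Path of the manifest file, invisibly a tibble attribute-free.
#' @export
simulate_study <- function(design, out_dir, format = c("csv", "fcs")) {
  stopifnot(inherits(design, "study_design"))
  format <- match.arg(format)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", out_dir),
                   class = "cytofp_io_error")
  }
  rows <- list()
  for (cd in design$classes) {
    for (rep_i in seq_len(design$replicates)) {
      for (tp in seq_len(design$timepoints)) {
        sid <- sprintf("%s_r%d_t%d", cd$class_label, rep_i, tp)
        seed_i <- derive_seed(design$seed, cd$class_label, rep_i, tp)
        em <- simulate_sample(cd, timepoint = tp - 1,
                              n_events = design$events_per_sample,
                              seed = seed_i, sample_id = sid)
        fname <- file.path(out_dir, paste0(sid, ".", format))
        write_events(em, fname, format = format)
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sid, path = fname, label = cd$class_label,
          replicate = rep_i, timepoint_day = tp - 1)
      }
    }
  }
  manifest <- bind_rows(rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  manifest_path
}

#' Read a study manifest
#'
#' @param path Manifest CSV with columns
#'   `sample_id, path, label, replicate, timepoint_day`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), path = readr::col_character(),
    label = readr::col_character(), replicate = readr::col_integer(),
    timepoint_day = readr::col_double()), progress = FALSE)
  required <- c("sample_id", "path", "label", "replicate", "timepoint_day")
  missing <- setdiff(required, names(m))
  assert_that(length(missing) == 0,
              sprintf("Manifest is missing column(s): %s",
                      paste(missing, collapse = ", ")))
  m
}

#' Default separable four-class study
#'
#' A compact reference design with one class per putative
#' anaerobic-digestion functional group feed (cellulose, glucose,
#' propionate, acetate), each a two-component mixture whose channel means
#' are separated from every other class by well over five pooled standard
#' deviations, with a mild mean drift over time points. Used throughout
#' the package's examples and tests as the "separable" condition under
#' which any reasonable classifier should succeed.
#'
#' @param events_per_sample Events per sample (default 100,000).
#' @param replicates,timepoints Study layout (default triplicate x 5).
#' @param seed Study seed.
#' @return A [study_design()].
#' @export
default_study_design <- function(events_per_sample = 100000, replicates = 3,
                                 timepoints = 5, seed = 1) {
  classes <- list(
    class_distribution("CELL", list(
      list(weight = 0.6, mean = c(220, 160, 320), sd = c(25, 20, 20)),
      list(weight = 0.4, mean = c(300, 200, 360), sd = c(30, 25, 25))),
      drift_per_day = c(2, 1, 0.5)),
    class_distribution("GLUC", list(
      list(weight = 0.7, mean = c(520, 420, 130), sd = c(30, 25, 15)),
      list(weight = 0.3, mean = c(640, 500, 170), sd = c(35, 30, 18))),
      drift_per_day = c(-2, 1, 1)),
    class_distribution("PROP", list(
      list(weight = 0.5, mean = c(820, 260, 520), sd = c(35, 25, 25)),
      list(weight = 0.5, mean = c(920, 320, 580), sd = c(40, 30, 30))),
      drift_per_day = c(1, -1, 1)),
    class_distribution("ACET", list(
      list(weight = 0.65, mean = c(380, 700, 820), sd = c(30, 35, 30)),
      list(weight = 0.35, mean = c(450, 820, 900), sd = c(35, 40, 35))),
      drift_per_day = c(0.5, 2, -1)))
  study_design(classes, replicates = replicates, timepoints = timepoints,
               events_per_sample = events_per_sample, seed = seed)
}
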