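#' Per-sample cytometry event matrix
#'
#' An `event_matrix` holds the raw per-event intensities of one cytometry
#' sample: `N` events (rows) by `C` channels (columns), plus acquisition
#' metadata. It is the entry point of the fingerprinting pipeline; events
#' stay in acquisition order throughout.
#'
#' @param events Numeric matrix (or data frame) of N events x C channels;
#'   all values must be finite.
#' @param channel_names Character vector of C unique channel short names
#'   (the FCS `$PnN` keywords, e.g. `"FSC-A"`).
#' @param sample_id Sample identifier.
#' @param metadata Named list of acquisition keywords (all coerced to
#'   character).
#'
#' @return An object of class `event_matrix`.
#' @examples
#' em <- event_matrix(matrix(rnorm(30, 100, 5), 10, 3),
#'                    c("FSC-A", "SSC-A", "AmCyan-A"), sample_id = "s1")
#' n_events(em)
#' @export
event_matrix <- function(events, channel_names, sample_id = "sample",
                         metadata = list()) {
  events <- as.matrix(events)
  if (!is.numeric(events)) abort("`events` must be numeric.")
  storage.mode(events) <- "double"
  channel_names <- as.character(channel_names)
  assert_that(length(channel_names) >= 1, "At least one channel is required.")
  assert_that(ncol(events) == length(channel_names),
              sprintf("`events` has %d columns but %d channel names given.",
                      ncol(events), length(channel_names)))
  assert_that(!anyDuplicated(channel_names),
              "`channel_names` must not contain duplicates.")
  assert_that(all(is.finite(events)),
              "All event intensities must be finite numbers.")
  colnames(events) <- channel_names
  metadata <- lapply(metadata, as.character)
  metadata$n_events <- as.character(nrow(events))
  structure(
    list(sample_id = as.character(sample_id), events = events,
         channel_names = channel_names, metadata = metadata),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %s: %d events x %d channels [%s]\n",
              x$sample_id, nrow(x$events), length(x$channel_names),
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Number of events in an event matrix
#' @param em An `event_matrix`.
#' @return Integer event count.
#' @export
n_events <- function(em) nrow(em$events)

#' @export
as_tibble.event_matrix <- function(x, ...) {
  as_tibble(as.data.frame(x$events))
}

#' The three analysis channels used for label-free fingerprints
#'
#' Forward scatter area (cell size), side scatter area
#' (granularity/morphology) and the AmCyan-A autofluorescence channel.
#' @export
analysis_channels <- function() c("FSC-A", "SSC-A", "AmCyan-A")

#' Subset and reorder channels of an event matrix
#'
#' Channels are matched by their `$PnN` short name, case-sensitively.
#' Typically used to reduce a multi-parameter acquisition to the three
#' analysis channels ([analysis_channels()]).
#'
#' @param em An `event_matrix`.
#' @param wanted Ordered character vector of channel names to keep.
#' @return An `event_matrix` with columns exactly `wanted`, in that order;
#'   the event count is unchanged.
#' @export
select_channels <- function(em, wanted = analysis_channels()) {
  wanted <- as.character(wanted)
  missing <- setdiff(wanted, em$channel_names)
  if (length(missing) > 0) {
    abort(sprintf(
      "Channel(s) %s not present; available channels: %s",
      paste0("'", missing, "'", collapse = ", "),
      paste0("'", em$channel_names, "'", collapse = ", ")),
      class = "cytofp_missing_channel")
  }
  event_matrix(em$events[, wanted, drop = FALSE], wanted,
               sample_id = em$sample_id, metadata = em$metadata)
}

#' Axis-aligned threshold gate
#'
#' Emulates debris/doublet exclusion with per-channel lower bounds (the
#' background floor below which events are treated as dead cells or junk)
#' and an FSC-A upper bound (above which events are treated as putative
#' doublets). The default is a no-op gate: graphical gating templates are
#' instrument- and study-specific, so numeric thresholds are configuration.
#'
#' @param lower_bounds Named numeric vector/list of per-channel floors
#'   (values >= 0, or -Inf for no floor).
#' @param fsc_upper_bound Upper bound on `FSC-A` (doublet ceiling).
#' @return A `gate_config` object.
#' @examples
#' g <- gate_config(lower_bounds = c("FSC-A" = 50, "SSC-A" = 20),
#'                  fsc_upper_bound = 5000)
#' @export
gate_config <- function(lower_bounds = c("FSC-A" = -Inf),
                        fsc_upper_bound = Inf) {
  lower_bounds <- unlist(lower_bounds)
  assert_that(!is.null(names(lower_bounds)) && all(nzchar(names(lower_bounds))),
              "`lower_bounds` must be named by channel.")
  assert_that(all(lower_bounds >= 0 | lower_bounds == -Inf),
              "Gate lower bounds must be >= 0 (or -Inf for none).")
  fsc_floor <- if ("FSC-A" %in% names(lower_bounds)) lower_bounds[["FSC-A"]] else -Inf
  assert_that(fsc_upper_bound > fsc_floor,
              "`fsc_upper_bound` must exceed the FSC-A lower bound.")
  structure(list(lower_bounds = lower_bounds,
                 fsc_upper_bound = fsc_upper_bound),
            class = "gate_config")
}

#' Apply a threshold gate to an event matrix
#'
#' Retains exactly the events with every gated channel at or above its
#' lower bound and `FSC-A` at or below the doublet ceiling. Acquisition
#' order is preserved; gating is idempotent.
#'
#' @param em An `event_matrix` containing every channel named in `gate`.
#' @param gate A [gate_config()].
#' @return The gated `event_matrix`; the retained and excluded counts are
#'   recorded in its metadata.
#' @export
apply_gate <- function(em, gate = gate_config()) {
  stopifnot(inherits(gate, "gate_config"))
  missing <- setdiff(names(gate$lower_bounds), em$channel_names)
  assert_that(length(missing) == 0,
              sprintf("Gated channel(s) %s absent from the event matrix.",
                      paste0("'", missing, "'", collapse = ", ")))
  keep <- rep(TRUE, n_events(em))
  for (ch in names(gate$lower_bounds)) {
    keep <- keep & em$events[, ch] >= gate$lower_bounds[[ch]]
  }
  if (is.finite(gate$fsc_upper_bound) && "FSC-A" %in% em$channel_names) {
    keep <- keep & em$events[, "FSC-A"] <= gate$fsc_upper_bound
  }
  out <- event_matrix(em$events[keep, , drop = FALSE], em$channel_names,
                      sample_id = em$sample_id, metadata = em$metadata)
  out$metadata$n_retained <- as.character(sum(keep))
  out$metadata$n_excluded <- as.character(sum(!keep))
  out
}
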