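#' Read per-event cytometry data
#'
#' Reads a Flow Cytometry Standard (FCS 3.0/3.1) list-mode file or a CSV
#' with a header row of channel names into an [event_matrix()]. All
#' channels present in the file are returned (use [select_channels()] to
#' reduce to the analysis channels) and acquisition (row) order is
#' preserved.
#'
#' @param path Path to the file.
#' @param format `"fcs"`, `"csv"`, or `"auto"` (by file extension).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return An `event_matrix` with the file's acquisition keywords (FCS) in
#'   its metadata.
#' @seealso [write_events()]
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': file does not exist.", path),
          class = "cytofp_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  switch(format,
         fcs = read_fcs(path, sample_id),
         csv = read_events_csv(path, sample_id))
}

#' Write per-event cytometry data
#'
#' Writes an [event_matrix()] as an FCS 3.1 list-mode file (single
#' dataset, 32-bit float, little-endian) or as a CSV with a header row of
#' channel names. `read_events(write_events(em, ...))` reproduces the
#' channel names exactly and the event values within the format's numeric
#' precision (single precision for FCS, full decimal text for CSV).
#'
#' @param em An `event_matrix`.
#' @param path Output path.
#' @param format `"fcs"`, `"csv"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_events <- function(em, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(em, "event_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot write '%s': directory does not exist.", path),
          class = "cytofp_io_error")
  }
  switch(format,
         fcs = write_fcs(em, path),
         csv = readr::write_csv(as_tibble(em), path))
  invisible(path)
}

read_events_csv <- function(path, sample_id) {
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Non-numeric cell in '%s' at data row %d, column %d.",
                  path, probs$row[1] - 1L, probs$col[1]),
          class = "cytofp_parse_error")
  }
  m <- as.matrix(df)
  if (nrow(m) == 0) m <- matrix(numeric(0), 0, ncol(df))
  event_matrix(m, names(df), sample_id = sample_id)
}

# ---- FCS binary format -----------------------------------------------------
# HEADER: 6-byte version + 4 spaces + six 8-byte right-justified ASCII
# offsets (TEXT begin/end, DATA begin/end, ANALYSIS begin/end). TEXT is a
# delimited keyword/value segment; DATA here is event-interleaved ("list
# mode"). We write FCS3.1 / $DATATYPE F / little-endian and read 3.0/3.1
# with float, double or integer data in either byte order.

fcs_pad8 <- function(x) formatC(x, width = 8, flag = " ")

write_fcs <- function(em, path) {
  n_par <- length(em$channel_names)
  n_tot <- n_events(em)
  delim <- "/"
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    # fixed-width placeholders so the TEXT length is known before the
    # offsets are; replaced below by zero-padded 10-digit values
    "$BEGINDATA" = "@@@@@@@@@B", "$ENDDATA" = "@@@@@@@@@E",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$FIL" = basename(path), "$SRC" = em$sample_id
  )
  for (i in seq_len(n_par)) {
    rng <- max(1, ceiling(max(0, em$events[, i], na.rm = FALSE)) + 1)
    kw[[sprintf("$P%dN", i)]] <- em$channel_names[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- as.character(rng)
  }
  text_body <- paste0(delim,
                      paste0(names(kw), delim, unname(kw), delim,
                             collapse = ""))
  text_begin <- 58L
  text_end <- text_begin + nchar(text_body, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  if (n_tot == 0) data_begin <- data_end <- 0L
  text_body <- sub("@@@@@@@@@B", formatC(data_begin, width = 10, flag = "0"),
                   text_body, fixed = TRUE)
  text_body <- sub("@@@@@@@@@E", formatC(data_end, width = 10, flag = "0"),
                   text_body, fixed = TRUE)
  header <- paste0("FCS3.1    ",
                   fcs_pad8(text_begin), fcs_pad8(text_end),
                   fcs_pad8(data_begin), fcs_pad8(data_end),
                   fcs_pad8(0), fcs_pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  if (n_tot > 0) {
    # event-interleaved: p1,p2,...,pC for event 1, then event 2, ...
    writeBin(as.numeric(t(em$events)), con, size = 4, endian = "little")
  }
  invisible(path)
}

parse_fcs_text <- function(txt) {
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  # a doubled delimiter escapes a literal delimiter inside a value; the
  # split then yields empty tokens which are re-joined below
  tokens <- strsplit(body, delim, fixed = TRUE)[[1]]
  merged <- character(0)
  i <- 1
  while (i <= length(tokens)) {
    tok <- tokens[i]
    while (i < length(tokens) && tokens[i + 1] == "" && i + 2 <= length(tokens)) {
      tok <- paste0(tok, delim, tokens[i + 2])
      i <- i + 2
    }
    merged <- c(merged, tok)
    i <- i + 1
  }
  if (length(merged) %% 2 == 1) merged <- merged[-length(merged)]
  keys <- merged[seq(1, length(merged), by = 2)]
  vals <- merged[seq(2, length(merged), by = 2)]
  setNames(as.list(vals), toupper(trimws(keys)))
}

read_fcs <- function(path, sample_id) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = size)
  if (length(raw_all) < 58) {
    abort(sprintf("'%s' is not an FCS file (truncated header).", path),
          class = "cytofp_format_error")
  }
  version <- rawToChar(raw_all[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(sprintf("'%s': unsupported FCS version '%s' (need 3.0/3.1).",
                  path, version), class = "cytofp_format_error")
  }
  offs <- vapply(0:5, function(k) {
    suppressWarnings(as.integer(trimws(
      rawToChar(raw_all[(11 + 8 * k):(18 + 8 * k)]))))
  }, integer(1))
  if (anyNA(offs[1:2]) || offs[1] <= 0 || offs[2] <= offs[1]) {
    abort(sprintf("'%s': missing or invalid TEXT segment offsets.", path),
          class = "cytofp_format_error")
  }
  txt <- rawToChar(raw_all[(offs[1] + 1):(offs[2] + 1)])
  kw <- parse_fcs_text(txt)
  n_par <- suppressWarnings(as.integer(kw[["$PAR"]]))
  n_tot <- suppressWarnings(as.integer(kw[["$TOT"]]))
  if (is.null(kw[["$PAR"]]) || is.na(n_par) || n_par < 1) {
    abort(sprintf("'%s': parameter count ($PAR) undeclared.", path),
          class = "cytofp_format_error")
  }
  if (is.null(kw[["$TOT"]]) || is.na(n_tot) || n_tot < 0) {
    abort(sprintf("'%s': total event count ($TOT) undeclared.", path),
          class = "cytofp_format_error")
  }
  mode <- toupper(kw[["$MODE"]] %||% "L")
  assert_that(mode == "L",
              sprintf("'%s': only list-mode ($MODE L) FCS is supported.", path),
              class = "cytofp_format_error")
  data_begin <- offs[3]
  data_end <- offs[4]
  if (is.na(data_begin) || data_begin == 0) {
    data_begin <- as.integer(kw[["$BEGINDATA"]] %||% 0)
    data_end <- as.integer(kw[["$ENDDATA"]] %||% 0)
  }
  dtype <- toupper(kw[["$DATATYPE"]] %||% "F")
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little" else "big"
  bits <- suppressWarnings(as.integer(kw[["$P1B"]] %||% "32"))
  chans <- vapply(seq_len(n_par), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1))
  n_vals <- n_par * n_tot
  if (n_vals > 0) {
    dcon <- rawConnection(raw_all[(data_begin + 1):length(raw_all)])
    on.exit(close(dcon), add = TRUE)
    vals <- switch(dtype,
      F = readBin(dcon, "numeric", n = n_vals, size = 4, endian = endian),
      D = readBin(dcon, "numeric", n = n_vals, size = 8, endian = endian),
      I = readBin(dcon, "integer", n = n_vals, size = bits / 8,
                  signed = bits > 16, endian = endian),
      abort(sprintf("'%s': unsupported $DATATYPE '%s'.", path, dtype),
            class = "cytofp_format_error"))
    if (length(vals) < n_vals) {
      abort(sprintf("'%s': DATA segment shorter than $TOT x $PAR.", path),
            class = "cytofp_format_error")
    }
    m <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)
  } else {
    m <- matrix(numeric(0), max(n_tot, 0), n_par)
  }
  meta <- kw[!grepl("^\\$P[0-9]+[NBER]$", names(kw))]
  event_matrix(m, chans, sample_id = sample_id, metadata = meta)
}
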