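#' Write a recording to disk
#'
#' The signal matrix is written as delimited text (`signals.csv`: one
#' `time` column in seconds plus one column per channel, header row of
#' names) and the stimulus train, water events, and metadata as a JSON
#' sidecar (`recording.json`). The pair round-trips through
#' [read_recording()] to within 1e-9 a.u.
#'
#' @param rec A `pico_recording`.
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  }
  n <- length(rec$channels[[1]])
  tab <- data.table::as.data.table(rec$channels)
  tab <- cbind(data.table::data.table(time = (seq_len(n) - 1) / rec$sampling_rate), tab)
  data.table::fwrite(tab, file.path(path, "signals.csv"))
  sidecar <- list(
    sampling_rate = rec$sampling_rate,
    stimuli = if (nrow(rec$stimuli)) rec$stimuli else list(),
    water_events = rec$water_events,
    metadata = rec$metadata
  )
  jsonlite::write_json(sidecar, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads the `signals.csv` + `recording.json` pair written by
#' [write_recording()] and validates the result: required channels must be
#' present (a schema error names the missing channel), columns must be
#' rectangular, and the stimulus train sorted and non-overlapping.
#'
#' @param path Directory containing `signals.csv` and `recording.json`.
#' @return A `pico_recording`.
#' @export
read_recording <- function(path) {
  sig_file <- file.path(path, "signals.csv")
  meta_file <- file.path(path, "recording.json")
  if (!file.exists(sig_file) || !file.exists(meta_file)) {
    stop("recording directory must contain signals.csv and recording.json",
         call. = FALSE)
  }
  tab <- data.table::fread(sig_file, fill = FALSE)
  if (!"time" %in% names(tab)) stop("signals.csv must have a 'time' column", call. = FALSE)
  if (anyNA(tab)) stop("ragged or non-numeric signals.csv", call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  channels <- lapply(tab[, setdiff(names(tab), "time"), with = FALSE], as.numeric)
  stimuli <- meta$stimuli
  if (is.null(stimuli) || length(stimuli) == 0) {
    stimuli <- empty_stimuli()
  } else {
    stimuli <- as.data.frame(stimuli, stringsAsFactors = FALSE)
  }
  recording(
    channels = channels,
    sampling_rate = meta$sampling_rate,
    stimuli = stimuli,
    water_events = as.numeric(unlist(meta$water_events)),
    metadata = if (is.null(meta$metadata)) list() else as.list(meta$metadata)
  )
}

#' Write a tidy event/sample table as CSV
#'
#' One row per event, header row of column names; all times in seconds,
#' durations in ms, amplitudes in % of max (columns are suffixed
#' accordingly by the producing functions). An empty table yields a
#' header-only file.
#'
#' @param events A data.frame (homogeneous event list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  if (!is.data.frame(events)) {
    stop("events must be a data.frame (homogeneous event list)", call. = FALSE)
  }
  data.table::fwrite(events, path)
  invisible(path)
}

#' Read back a table written by [write_events_table()]
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_events_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write generator ground truth
#'
#' The per-event ground-truth table goes to `ground_truth.csv` (one row
#' per stimulus / water bolus: intended class, true burst onsets, offsets,
#' peaks, amplitudes, true respiratory phase) and the generating
#' configuration to `config.json`.
#'
#' @param gt A `pico_ground_truth` from [generate_recording()].
#' @param path Directory to write into.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_events_table(gt$events, file.path(path, "ground_truth.csv"))
  cfg <- gt$config
  cfg$behavior_policy <- as.data.frame(cfg$behavior_policy)
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
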