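## Plain-text interchange formats: two-column recording CSV (0-based
## sample_index, amplitude), one-peak-per-line annotation files (0-based
## sample indices) and a YAML dataset manifest.

#' Write a recording to CSV (+ optional annotation sidecar)
#'
#' @param recording a `doppler_recording`.
#' @param path CSV output path.
#' @param annotation_path optional path for the R-peak sidecar (one 0-based
#'   sample index per line); defaults to `<path>.peaks.txt` when the
#'   recording carries annotations.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path, annotation_path = NULL) {
  utils::write.csv(
    data.frame(sample_index = seq_along(recording$samples) - 1L,
               amplitude = recording$samples),
    path, row.names = FALSE)
  if (!is.null(recording$rpeaks)) {
    if (is.null(annotation_path)) annotation_path <- paste0(path, ".peaks.txt")
    writeLines(as.character(recording$rpeaks - 1L), annotation_path)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path recording CSV (columns `sample_index`, `amplitude`).
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param annotation_path optional R-peak sidecar (0-based indices).
#' @return a `doppler_recording`.
#' @export
read_recording_csv <- function(path, fs, subject_id = NA_integer_,
                               annotation_path = NULL) {
  df <- utils::read.csv(path)
  peaks <- NULL
  if (!is.null(annotation_path) && file.exists(annotation_path)) {
    peaks <- as.integer(readLines(annotation_path)) + 1L
    if (is.unsorted(peaks, strictly = TRUE)) stop_beat("annotations not strictly increasing")
  }
  new_recording(subject_id, fs, df$amplitude, peaks)
}

#' Write a simulated dataset to disk
#'
#' One CSV + annotation file per subject plus a `manifest.yaml` listing
#' subject ids, file paths, sampling rate, seed and configuration hash.
#'
#' @param dataset list with `recordings` (e.g. from [simulate_dataset()]).
#' @param dir output directory.
#' @param seed seed recorded in the manifest.
#' @param config_hash configuration hash recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = NA_integer_, config_hash = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(dataset$recordings, function(rec) {
    base <- sprintf("subject_%s", rec$subject_id)
    write_recording_csv(rec, file.path(dir, paste0(base, ".csv")),
                        file.path(dir, paste0(base, ".peaks.txt")))
    list(subject_id = rec$subject_id, fs = rec$fs,
         csv = paste0(base, ".csv"), annotations = paste0(base, ".peaks.txt"))
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(seed = seed, config_hash = config_hash,
                        subjects = entries), manifest)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param manifest path to `manifest.yaml`.
#' @return list with `recordings`.
#' @export
read_dataset <- function(manifest) {
  y <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  recs <- lapply(y$subjects, function(e)
    read_recording_csv(file.path(dir, e$csv), e$fs, e$subject_id,
                       file.path(dir, e$annotations)))
  list(recordings = recs, seed = y$seed, config_hash = y$config_hash)
}
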