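# Readers and writers: EDF or delimited-matrix recordings (+ YAML sidecar),
# rating tables (CSV), selection reports (JSON).

#' Construct a recording object
#'
#' A recording is one subject's multichannel signal: a channels x samples
#' numeric matrix (microvolts), a sampling rate, and ordered unique channel
#' names. Validation rejects non-finite samples, naming the first offending
#' channel.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names character vector of unique names, one per row.
#' @param subject_id subject identifier string.
#' @return an object of class `cchp_recording`.
#' @export
recording <- function(signal, fs, channel_names, subject_id = "s01") {
  if (!is.matrix(signal) || !is.numeric(signal))
    abort_validation("signal must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort_validation("fs must be a positive finite scalar, got %s", format(fs))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(signal))
    abort_validation("channel_names length (%d) != channel count (%d)",
                     length(channel_names), nrow(signal))
  if (anyDuplicated(channel_names))
    abort_validation("duplicate channel names: %s",
                     paste(unique(channel_names[duplicated(channel_names)]),
                           collapse = ", "))
  bad <- !is.finite(signal)
  if (any(bad)) {
    ch <- channel_names[which(rowSums(bad) > 0)[1]]
    abort_validation("non-finite samples in channel '%s'", ch)
  }
  rownames(signal) <- channel_names
  structure(list(subject_id = as.character(subject_id), signal = signal,
                 fs = fs, channel_names = channel_names),
            class = "cchp_recording")
}

#' @export
print.cchp_recording <- function(x, ...) {
  cat(sprintf("<cchp_recording> subject %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Supports two formats: `"edf"` (European Data Format) and `"matrix"`
#' (delimited text, channels as rows and samples as columns, with a YAML
#' sidecar supplying `fs`, `channel_names` and optionally `subject_id`).
#' Channel order is preserved from the file; no sorting.
#'
#' @param path file path.
#' @param format `"edf"` or `"matrix"`.
#' @param sidecar YAML sidecar path, required for `format = "matrix"`;
#'   defaults to `<path>.yaml` if that file exists.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("edf", "matrix"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("file not found: %s", path)
  if (format == "edf") {
    e <- read_edf(path)
    sid <- if (nzchar(e$subject_id)) e$subject_id else "s01"
    return(recording(e$signal, e$fs, e$channel_names, sid))
  }
  if (is.null(sidecar)) {
    guess <- paste0(path, ".yaml")
    if (file.exists(guess)) sidecar <- guess
    else abort_validation("matrix format requires a YAML sidecar")
  }
  if (!file.exists(sidecar)) abort_io("sidecar not found: %s", sidecar)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs) || is.null(meta$channel_names))
    abort_validation("sidecar must define 'fs' and 'channel_names'")
  dt <- data.table::fread(path, header = FALSE, sep = ",")
  sig <- as.matrix(dt)
  storage.mode(sig) <- "double"
  dimnames(sig) <- NULL
  recording(sig, as.numeric(meta$fs), unlist(meta$channel_names),
            subject_id = if (!is.null(meta$subject_id)) meta$subject_id else "s01")
}

#' Write a recording in matrix format (CSV + YAML sidecar)
#'
#' @param rec a [recording()].
#' @param path CSV output path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "cchp_recording"))
  data.table::fwrite(data.table::as.data.table(unname(rec$signal)), path,
                     col.names = FALSE)
  yaml::write_yaml(list(subject_id = rec$subject_id, fs = rec$fs,
                        channel_names = as.list(rec$channel_names)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a valence/arousal rating table
#'
#' Expects a delimited file with header columns `subject`, `trial`,
#' `valence`, `arousal`. Trial indices are 0-based; ratings must lie in
#' `[1, 9]` (the SAM self-assessment scale) and `(subject, trial)` pairs
#' must be unique. Malformed rows are rejected with their row number.
#'
#' @param path CSV file path.
#' @return data.frame with columns subject, trial, valence, arousal.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  df <- tryCatch(
    as.data.frame(data.table::fread(path, header = TRUE, sep = ",")),
    error = function(e) abort_io("cannot parse ratings file %s: %s",
                                 path, conditionMessage(e)))
  need <- c("subject", "trial", "valence", "arousal")
  if (!all(need %in% names(df)))
    abort_validation("ratings file must have columns %s",
                     paste(need, collapse = ", "))
  df <- df[need]
  if (nrow(df) == 0) return(df)
  df$subject <- as.character(df$subject)
  for (col in c("trial", "valence", "arousal")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      abort_validation("ratings row %d: non-numeric '%s'", bad[1], col)
    df[[col]] <- v
  }
  bad <- which(df$trial != floor(df$trial) | df$trial < 0)
  if (length(bad))
    abort_validation("ratings row %d: trial must be a 0-based integer", bad[1])
  df$trial <- as.integer(df$trial)
  bad <- which(df$valence < 1 | df$valence > 9 |
               df$arousal < 1 | df$arousal > 9)
  if (length(bad))
    abort_validation("ratings row %d: valence/arousal outside [1, 9]", bad[1])
  dup <- which(duplicated(df[c("subject", "trial")]))
  if (length(dup))
    abort_validation("ratings row %d: duplicate (subject, trial)", dup[1])
  df
}

#' Write a channel-selection report as JSON
#'
#' Serialises a [cchp_select()] result, including per-subject significant
#' channel sets with merit scores, the cross-subject occurrence table, the
#' occurrence-ranked list, the thresholded general optimal set and the full
#' run configuration (modes, threshold, seed), so the run is reproducible
#' from the report alone. 1-based trial-free channel ranks are implicit in
#' list order. [read_selection_report()] reconstructs the object exactly.
#'
#' @param result a `cchp_selection` object from [cchp_select()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "cchp_selection"))
  ok <- tryCatch({
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io("cannot write report to %s: %s", path,
                            conditionMessage(ok))
  invisible(path)
}

#' Read a channel-selection report written by [write_selection_report()]
#'
#' @param path JSON file path.
#' @return a `cchp_selection` object.
#' @export
read_selection_report <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v))
  x$subjects <- lapply(x$subjects, function(s) {
    s$channels <- chr(s$channels)
    s$merit <- as.numeric(s$merit)
    s
  })
  x$ranked <- chr(x$ranked)
  x$g_optimal <- chr(x$g_optimal)
  x$excluded_ids <- chr(x$excluded_ids)
  structure(x, class = "cchp_selection")
}
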