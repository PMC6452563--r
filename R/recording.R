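#' Multichannel sEMG recording
#'
#' Container for a raw multichannel surface-EMG recording: a channels x samples
#' numeric matrix, the sampling frequency, the electrode [grid_layout()], and a
#' motion schedule giving the labelled intervals. Schedule intervals are
#' half-open `[start, end)` in 0-based sample indices and must be
#' non-overlapping; samples not covered by any interval are unlabelled rest.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling frequency in Hz.
#' @param layout A [grid_layout()]; its channel count must match `nrow(signal)`.
#' @param schedule Data frame with columns `label`, `start`, `end` (samples,
#'   half-open, 0-based starts).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, layout = grid_layout(), schedule) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be a numeric matrix")
  if (nrow(signal) != layout$n_channels)
    stop("channel count mismatch: signal has ", nrow(signal),
         " rows but layout has ", layout$n_channels, " channels")
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(c("label", "start", "end") %in% names(schedule)))
  schedule$start <- as.integer(schedule$start)
  schedule$end <- as.integer(schedule$end)
  n <- ncol(signal)
  if (nrow(schedule)) {
    if (any(schedule$start < 0) || any(schedule$end > n) ||
        any(schedule$end <= schedule$start))
      stop("schedule intervals must satisfy 0 <= start < end <= ", n)
    o <- order(schedule$start)
    s <- schedule[o, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("schedule intervals overlap")
  }
  structure(list(signal = signal, fs = as.numeric(fs), layout = layout,
                 schedule = schedule),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$fs, " Hz; ", nrow(x$schedule),
      " labelled intervals (", length(unique(x$schedule$label)),
      " classes)\n", sep = "")
  invisible(x)
}

#' Read a recording from a delimited matrix plus JSON metadata
#'
#' The matrix file holds the signal with channels as rows (no header); the
#' metadata JSON holds `fs`, the grid (`n_rows`, `n_cols`, `inactive` as an
#' array of `[row, col]` pairs, 1-based), and `schedule` as an array of
#' `{label, start, end}` objects.
#'
#' @param matrix_path Path to a comma- or tab-delimited numeric table.
#' @param meta_path Path to the metadata JSON.
#' @param sep Field separator; inferred from the extension by default
#'   (`.tsv` means tab, otherwise comma).
#' @return An [emg_recording()].
#' @export
read_recording <- function(matrix_path, meta_path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", matrix_path)) "\t" else ","
  sig <- tryCatch(
    as.matrix(utils::read.table(matrix_path, sep = sep, header = FALSE,
                                colClasses = "numeric")),
    error = function(e) stop("failed to parse signal matrix at ", matrix_path,
                             ": ", conditionMessage(e))
  )
  dimnames(sig) <- NULL
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  inactive <- meta$inactive
  if (!is.null(inactive)) {
    inactive <- matrix(as.integer(unlist(inactive)), ncol = 2, byrow = TRUE)
  }
  layout <- grid_layout(meta$n_rows, meta$n_cols, inactive = inactive,
                        pitch_mm = if (is.null(meta$pitch_mm)) 8 else meta$pitch_mm)
  sched <- tibble::as_tibble(meta$schedule)
  emg_recording(sig, fs = meta$fs, layout = layout, schedule = sched)
}

#' Write a recording to a delimited matrix plus JSON metadata
#'
#' Inverse of [read_recording()]. Values are written with 17 significant
#' digits, so a text round trip reproduces the signal to within 1e-12 relative.
#'
#' @param rec An [emg_recording()].
#' @param matrix_path,meta_path Output paths.
#' @export
write_recording <- function(rec, matrix_path, meta_path) {
  stopifnot(inherits(rec, "emg_recording"))
  sep <- if (grepl("\\.tsv$", matrix_path)) "\t" else ","
  utils::write.table(format(rec$signal, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     matrix_path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(
    fs = rec$fs,
    n_rows = rec$layout$n_rows,
    n_cols = rec$layout$n_cols,
    inactive = apply(inactive_positions(rec$layout), 1, identity,
                     simplify = FALSE),
    pitch_mm = rec$layout$pitch_mm,
    schedule = rec$schedule
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
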