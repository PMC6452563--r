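#' Segment a recording into labelled analysis windows
#'
#' Tiles every labelled schedule interval with fixed-length windows. Windows
#' never cross an interval boundary and inherit the interval's label; samples
#' outside the schedule (rest) are never windowed. With the default 2 s motions
#' at 5120 Hz and a 0.25 s window advanced by 0.125 s, each motion yields 15
#' overlapping windows.
#'
#' @param rec An [emg_recording()].
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param bandpass Optional band-pass applied before windowing: a list
#'   `list(low=, high=, order=)` in Hz (zero-phase 4th-order Butterworth via
#'   forward-backward filtering), or `NULL` (default) for none.
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   channels x window matrices), `labels`, `window_samples`, `step_samples`,
#'   `fs`, `layout`.
#' @export
segment_epochs <- function(rec, window_s = 0.25, step_s = 0.125,
                           bandpass = NULL) {
  stopifnot(inherits(rec, "emg_recording"), step_s > 0, window_s > 0)
  w <- as.integer(round(window_s * rec$fs))
  st <- as.integer(round(step_s * rec$fs))
  if (st < 1L) stop("step_s too small for the sampling rate")
  sig <- rec$signal
  if (!is.null(bandpass)) {
    sig <- bandpass_signal(sig, rec$fs, low = bandpass$low,
                           high = bandpass$high,
                           order = if (is.null(bandpass$order)) 4L else bandpass$order)
  }
  epochs <- list(); labels <- character(0)
  for (i in seq_len(nrow(rec$schedule))) {
    s0 <- rec$schedule$start[i]; e0 <- rec$schedule$end[i]
    len <- e0 - s0
    if (w > len)
      stop("window of ", w, " samples longer than interval ", i,
           " (", len, " samples, label '", rec$schedule$label[i], "')")
    starts <- seq.int(s0, e0 - w, by = st)
    for (s in starts) {
      epochs[[length(epochs) + 1L]] <- sig[, (s + 1L):(s + w), drop = FALSE]
      labels <- c(labels, as.character(rec$schedule$label[i]))
    }
  }
  structure(list(epochs = epochs, labels = labels, window_samples = w,
                 step_samples = st, fs = rec$fs, layout = rec$layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", length(x$epochs), " windows of ",
      x$window_samples, " samples, ", length(unique(x$labels)),
      " classes\n", sep = "")
  invisible(x)
}

#' Zero-phase Butterworth band-pass of a multichannel signal
#'
#' @param signal Channels x samples matrix.
#' @param fs Sampling frequency, Hz.
#' @param low,high Pass-band edges, Hz.
#' @param order Butterworth order (applied twice by `filtfilt`).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_signal <- function(signal, fs, low = 20, high = 450, order = 4L) {
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(signal, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- NULL
  out
}

#' Per-class covariance matrices
#'
#' For each class, averages the per-window spatial covariance
#' \eqn{X X^\top / w} (after per-window channel-mean removal) over that class's
#' windows. With `normalize = TRUE` (the default, standard practice before CSP)
#' each window's covariance is divided by its trace before averaging, so every
#' window contributes unit total energy. Class priors are the window-count
#' fractions.
#'
#' @param epochs An [segment_epochs()] result, or any `epoch_set`.
#' @param normalize Trace-normalize each window covariance before averaging.
#' @return An object of class `class_cov_set`: list with `covariances` (named
#'   list of symmetric PSD matrices), `priors`, `labels`.
#' @export
class_covariances <- function(epochs, normalize = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  labs <- sort(unique(epochs$labels))
  if (length(labs) < 2) stop("need at least 2 classes, got ", length(labs))
  counts <- table(factor(epochs$labels, levels = labs))
  if (any(counts == 0))
    stop("classes with zero epochs: ",
         paste(labs[counts == 0], collapse = ", "))
  covs <- lapply(labs, function(lab) {
    idx <- which(epochs$labels == lab)
    acc <- NULL
    for (i in idx) {
      X <- epochs$epochs[[i]]
      X <- X - rowMeans(X)
      C <- tcrossprod(X) / ncol(X)
      if (normalize) {
        tr <- sum(diag(C))
        if (tr > 0) C <- C / tr
      }
      acc <- if (is.null(acc)) C else acc + C
    }
    S <- acc / length(idx)
    (S + t(S)) / 2
  })
  names(covs) <- labs
  structure(list(covariances = covs,
                 priors = as.numeric(counts) / length(epochs$labels),
                 labels = labs),
            class = "class_cov_set")
}

#' Build a covariance set from explicit matrices
#'
#' Low-level constructor used by the analytic synthetic generator and in tests.
#'
#' @param covariances List of symmetric positive semi-definite matrices.
#' @param priors Class priors; default uniform. Must sum to 1.
#' @param labels Class labels; default `class1..classM`.
#' @return A `class_cov_set`.
#' @export
class_cov_set <- function(covariances, priors = NULL, labels = NULL) {
  M <- length(covariances)
  stopifnot(M >= 1)
  if (is.null(priors)) priors <- rep(1 / M, M)
  if (abs(sum(priors) - 1) > 1e-12) stop("priors must sum to 1")
  if (is.null(labels)) {
    labels <- if (!is.null(names(covariances))) names(covariances)
              else paste0("class", seq_len(M))
  }
  covariances <- lapply(covariances, function(S) (as.matrix(S) + t(S)) / 2)
  names(covariances) <- labels
  structure(list(covariances = covariances, priors = as.numeric(priors),
                 labels = labels),
            class = "class_cov_set")
}

#' Prior-weighted mean covariance
#' @param cov A `class_cov_set`.
#' @return The matrix \eqn{\bar\Sigma = \sum_i p(c_i)\,\Sigma_{c_i}}.
#' @export
mean_covariance <- function(cov) {
  stopifnot(inherits(cov, "class_cov_set"))
  Reduce(`+`, Map(`*`, cov$covariances, cov$priors))
}
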