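# Shared fixtures: random SPD matrices, small recordings, compact synthetic
# configurations sized for fast tests.

random_spd <- function(n, ridge = 0.1) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) + ridge * diag(n)
}

# Commuting symmetric family: shared eigenvectors, random positive spectra.
commuting_family <- function(n, m, lo = 0.5, hi = 2) {
  V <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  lapply(seq_len(m), function(i) V %*% diag(stats::runif(n, lo, hi)) %*% t(V))
}

# Minimal labelled recording: `k` classes, one interval each, iid N(0, sd^2).
tiny_recording <- function(n_ch = 4, k = 2, int_len = 2000, fs = 1000,
                           sd = 1, gap = 0) {
  layout <- grid_layout(1, n_ch, inactive = NULL)
  n <- k * (int_len + gap)
  sig <- matrix(stats::rnorm(n_ch * n, sd = sd), n_ch, n)
  sched <- tibble::tibble(
    label = paste0("c", seq_len(k)),
    start = (seq_len(k) - 1) * (int_len + gap),
    end = (seq_len(k) - 1) * (int_len + gap) + int_len)
  emg_recording(sig, fs = fs, layout = layout, schedule = sched)
}

# Compact synthetic config on a 3 x 4 grid (12 channels) for fast end-to-end
# tests; otherwise the default generative model.
small_synth <- function(n_classes = 3, seed = 1, reps = 2, ...) {
  layout <- grid_layout(3, 4, inactive = NULL)
  centers <- cbind(c(2, 2, 2)[seq_len(min(n_classes, 3))],
                   c(1, 2, 4)[seq_len(min(n_classes, 3))])
  centers <- centers[((seq_len(n_classes) - 1) %% nrow(centers)) + 1, ,
                     drop = FALSE]
  synth_config(n_classes = n_classes, layout = layout, fs = 1024,
               motion_s = 1, reps = reps, rest_s = 0.25,
               class_centers = centers, seed = seed, ...)
}
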