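# Orthonormal analysis filter pairs (decomposition low/high pass).
# sym5: least-asymmetric Daubechies family, 10 taps — the standard published
# coefficients. haar included for hand-checkable tests.
wavelet_filters <- function(wavelet = c("sym5", "haar")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    sym5 = c(0.027333068345077982, 0.029519490925774643,
             -0.039134249302383094, 0.1993975339773936,
             0.7234076904024206, 0.6339789634582119,
             0.01660210576452232, -0.17532808990845047,
             -0.021101834024758855, 0.019538882735286728),
    haar = c(1, 1) / sqrt(2)
  )
  F <- length(lo)
  # conjugate quadrature pair: g[m] = (-1)^m h[F-1-m]
  hi <- rev(lo) * (-1)^(seq_len(F) - 1)
  list(lo = lo, hi = hi, length = F)
}

# One periodized analysis step on signals stored column-wise:
# y[k, ] = sum_m f[m] X[(2k + 1 - m) mod n, ], k = 0..n/2-1 (0-based).
# For a conjugate quadrature pair and even n the stacked lo/hi operator is
# orthogonal, so energy is conserved exactly.
wpt_step <- function(X, filt) {
  n <- nrow(X)
  n2 <- n %/% 2L
  acc <- matrix(0, n2, ncol(X))
  k2 <- 2L * (seq_len(n2) - 1L) + 1L
  for (m in seq_along(filt)) {
    rows <- ((k2 - (m - 1L)) %% n) + 1L
    acc <- acc + filt[m] * X[rows, , drop = FALSE]
  }
  acc
}

#' Wavelet-packet configuration
#'
#' @param wavelet Mother wavelet, `"sym5"` (default) or `"haar"`.
#' @param depth Decomposition depth J; the terminal level has `2^J` uniform
#'   subbands.
#' @param log_floor RMS floor applied before the logarithm so silent channels
#'   stay finite.
#' @param order Terminal-node ordering: `"freq"` (default; natural Paley order
#'   re-permuted by the binary-reflected Gray code so node k covers the k-th
#'   frequency band) or `"natural"`.
#' @return A list of class `wpt_config`.
#' @export
wpt_config <- function(wavelet = "sym5", depth = 4L, log_floor = 1e-12,
                       order = c("freq", "natural")) {
  order <- match.arg(order)
  stopifnot(depth >= 1, log_floor > 0)
  structure(list(wavelet = wavelet, depth = as.integer(depth),
                 log_floor = log_floor, order = order),
            class = "wpt_config")
}

gray_code <- function(k) bitwXor(k, k %/% 2L)

# Full wavelet-packet tree on column-wise signals; returns a list of 2^J
# coefficient matrices in natural (Paley) order.
wpt_tree <- function(X, wavelet, depth) {
  f <- wavelet_filters(wavelet)
  nodes <- list(X)
  for (j in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2L * i - 1L]] <- wpt_step(nodes[[i]], f$lo)
      nxt[[2L * i]] <- wpt_step(nodes[[i]], f$hi)
    }
    nodes <- nxt
  }
  nodes
}

# RMS of each terminal node, as a 2^J x n_signals matrix, ordered per cfg.
wpt_node_rms <- function(X, cfg) {
  n <- nrow(X)
  f <- wavelet_filters(cfg$wavelet)
  if (n %% 2^cfg$depth != 0)
    stop("window length ", n, " not divisible by 2^J = ", 2^cfg$depth)
  if (n < f$length * 2^cfg$depth)
    stop("window of ", n, " samples too short for ", cfg$wavelet,
         " at depth ", cfg$depth, "; need at least ", f$length * 2^cfg$depth)
  nodes <- wpt_tree(X, cfg$wavelet, cfg$depth)
  rms <- vapply(nodes, function(M) sqrt(colMeans(M^2)), numeric(ncol(X)))
  rms <- if (is.matrix(rms)) t(rms) else matrix(rms, ncol = 1)
  if (cfg$order == "freq") {
    rms <- rms[gray_code(seq_len(2^cfg$depth) - 1L) + 1L, , drop = FALSE]
  }
  rms
}

#' Wavelet-packet log-RMS features of one window
#'
#' Decomposes a single-channel window by a full wavelet-packet tree to depth
#' J (periodized orthonormal filter bank, so total coefficient energy equals
#' signal energy) and returns the natural log of the RMS of each of the
#' \eqn{2^J} terminal-node coefficient vectors, floored at `log_floor`.
#'
#' @param x Numeric vector; length must be divisible by `2^J` and at least
#'   filter length times `2^J`.
#' @param cfg A [wpt_config()].
#' @return Numeric vector of `2^J` log-RMS values, named `node0..node{2^J-1}`
#'   in the configured subband order.
#' @export
wpt_logrms <- function(x, cfg = wpt_config()) {
  rms <- wpt_node_rms(matrix(as.numeric(x), ncol = 1), cfg)
  out <- log(pmax(rms[, 1], cfg$log_floor))
  names(out) <- paste0("node", seq_along(out) - 1L)
  out
}

#' Feature matrix from selected channels
#'
#' Extracts [wpt_logrms()] features from every analysis window for each
#' selected physical channel and concatenates them: \eqn{L' \times 2^J}
#' features per window, labelled by the window's motion class.
#'
#' @param epochs An `epoch_set`.
#' @param sel A `channel_selection`, or an integer vector of channel indices.
#' @param cfg A [wpt_config()].
#' @return A tibble of class `feature_matrix`: column `label` (factor) then
#'   one numeric column per feature, named `ch{c}_node{k}`.
#' @export
build_feature_matrix <- function(epochs, sel, cfg = wpt_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  channels <- if (inherits(sel, "channel_selection")) sel$channel
              else as.integer(sel)
  if (length(channels) == 0) stop("empty channel selection")
  N <- nrow(epochs$epochs[[1]])
  if (any(channels < 1 | channels > N))
    stop("selected channels outside 1..", N)
  n_ep <- length(epochs$epochs)
  blocks <- lapply(channels, function(ch) {
    X <- vapply(epochs$epochs, function(E) E[ch, ],
                numeric(epochs$window_samples))
    rms <- wpt_node_rms(X, cfg)                 # 2^J x n_ep
    t(log(pmax(rms, cfg$log_floor)))            # n_ep x 2^J
  })
  Xf <- do.call(cbind, blocks)
  colnames(Xf) <- unlist(lapply(channels, function(ch)
    paste0("ch", ch, "_node", seq_len(2^cfg$depth) - 1L)))
  out <- tibble::as_tibble(as.data.frame(Xf))
  out <- tibble::add_column(out, label = factor(epochs$labels),
                            .before = 1)
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Spatial RMS topography of a window
#'
#' Places each channel's RMS amplitude at its electrode-grid position, the
#' standard visualization of which muscle regions are active during a motion.
#'
#' @param epoch Channels x samples matrix (one analysis window).
#' @param layout A [grid_layout()] matching the channel count.
#' @return A tibble with columns `row`, `col`, `channel`, `rms` covering the
#'   active grid positions only (inactive pads are absent).
#' @export
rms_topography <- function(epoch, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != layout$n_channels)
    stop("epoch has ", nrow(epoch), " channels but layout has ",
         layout$n_channels)
  rms <- sqrt(rowMeans(epoch^2))
  pos <- which(!is.na(layout$channel_at), arr.ind = TRUE)
  ch <- layout$channel_at[pos]
  tibble::tibble(row = as.integer(pos[, 1]), col = as.integer(pos[, 2]),
                 channel = as.integer(ch), rms = rms[ch])
}
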