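test_that("terminal node count and log floor behave as specified", {
  cfg <- wpt_config("sym5", 4)
  x <- rnorm(1280)
  feats <- wpt_logrms(x, cfg)
  expect_length(feats, 16L)
  expect_named(feats, paste0("node", 0:15))

  zeros <- wpt_logrms(rep(0, 1280), cfg)
  expect_true(all(is.finite(zeros)))
  expect_equal(unname(zeros), rep(log(1e-12), 16))

  expect_error(wpt_logrms(rnorm(128), cfg), "too short")
  expect_error(wpt_logrms(rnorm(1281), cfg), "divisible")
})

test_that("the packet tree conserves energy (orthonormal filter bank)", {
  set.seed(141)
  for (i in 1:5) {
    x <- rnorm(10240)
    nodes <- hdsemgsel:::wpt_tree(matrix(x, ncol = 1), "sym5", 4)
    e <- sum(vapply(nodes, function(M) sum(M^2), numeric(1)))
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-9)
  }
})

test_that("fast transform equals the explicit-matrix oracle", {
  set.seed(151)
  for (wavelet in c("haar", "sym5")) {
    for (i in 1:5) {
      n <- if (wavelet == "haar") 64 else 256
      x <- rnorm(n)
      depth <- 3
      fast <- hdsemgsel:::wpt_tree(matrix(x, ncol = 1), wavelet, depth)
      slow <- oracle_wpt(x, wavelet, depth)
      for (k in seq_along(fast))
        expect_equal(drop(fast[[k]]), slow[[k]], tolerance = 1e-8)
    }
  }
})

test_that("feature matrices have L' x 2^J columns and log-RMS homogeneity", {
  set.seed(161)
  rec <- tiny_recording(n_ch = 6, k = 2, int_len = 2560, fs = 1024)
  ep <- segment_epochs(rec, window_s = 0.5, step_s = 0.5)
  for (L in c(1, 3, 5)) {
    fm <- build_feature_matrix(ep, seq_len(L), wpt_config("sym5", 4))
    expect_equal(ncol(fm), 1L + L * 16L)
    expect_equal(nrow(fm), length(ep$epochs))
  }
  expect_error(build_feature_matrix(ep, integer(0)), "empty")
  expect_error(build_feature_matrix(ep, 7), "outside")

  # doubling channel 2 shifts exactly its features by ln 2
  fm1 <- build_feature_matrix(ep, 1:2)
  ep2 <- ep
  ep2$epochs <- lapply(ep$epochs, function(E) { E[2, ] <- 2 * E[2, ]; E })
  fm2 <- build_feature_matrix(ep2, 1:2)
  d <- as.matrix(fm2[-1]) - as.matrix(fm1[-1])
  expect_equal(unname(d[, 17:32]), matrix(log(2), nrow(d), 16),
               tolerance = 1e-10)
  expect_equal(unname(d[, 1:16]), matrix(0, nrow(d), 16))

  # determinism: repeated extraction is bit-identical
  expect_identical(build_feature_matrix(ep, 1:2), fm1)
})

test_that("subband ordering tracks frequency content", {
  # a high-frequency tone must land in a high-index subband under freq order
  fs <- 1024; n <- 1024
  t <- seq_len(n) / fs
  hi_tone <- sin(2 * pi * 480 * t)      # near Nyquist
  lo_tone <- sin(2 * pi * 10 * t)       # near DC
  cfg <- wpt_config("sym5", 3, order = "freq")
  expect_equal(unname(which.max(wpt_logrms(lo_tone, cfg))), 1L)
  expect_equal(unname(which.max(wpt_logrms(hi_tone, cfg))), 8L)
})

test_that("RMS topography is local and matches the grid geometry", {
  g <- grid_layout(2, 3, inactive = matrix(c(2L, 3L), ncol = 2))
  ep <- matrix(0, 5, 100)
  ep[3, ] <- 2 * sin(seq_len(100))
  topo <- rms_topography(ep, g)
  expect_equal(nrow(topo), 5L)
  expect_equal(topo$rms[topo$channel == 3],
               sqrt(mean((2 * sin(seq_len(100)))^2)))
  expect_equal(sum(topo$rms > 0), 1L)
  expect_error(rms_topography(ep[1:4, ], g), "channels")

  # equal-variance white noise flattens as the window grows
  set.seed(171)
  flat_long <- rms_topography(matrix(rnorm(5 * 50000), 5), g)
  expect_lt(max(flat_long$rms) / min(flat_long$rms), 1.05)

  p <- plot_topography(topo, highlight = 3L)
  expect_s3_class(p, "ggplot")
})

test_that("topography argmax recovers a planted activation centre", {
  cfg <- small_synth(n_classes = 2, seed = 3)
  rec <- generate_recording(cfg)
  ep <- segment_epochs(rec, window_s = 1, step_s = 1)
  planted <- planted_channels(cfg)
  for (ci in 1:2) {
    idx <- which(ep$labels == paste0("M", ci))
    mean_rms <- rowMeans(vapply(ep$epochs[idx],
                                function(E) sqrt(rowMeans(E^2)),
                                numeric(nrow(ep$epochs[[1]]))))
    expect_equal(which.max(mean_rms), planted[ci])
  }
})
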