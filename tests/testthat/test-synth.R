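test_that("the generator is bit-identical under a fixed seed", {
  cfg <- small_synth(seed = 42)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$schedule, r2$schedule)
  r3 <- generate_recording(small_synth(seed = 43))
  expect_false(identical(r1$signal, r3$signal))
})

test_that("schedule covers reps x classes motions with rest gaps between", {
  cfg <- small_synth(n_classes = 3, reps = 2)
  rec <- generate_recording(cfg)
  expect_equal(nrow(rec$schedule), 6L)
  expect_equal(sort(unique(rec$schedule$label)), c("M1", "M2", "M3"))
  expect_true(all(rec$schedule$end - rec$schedule$start == 1024L))
  gaps <- rec$schedule$start[-1] - rec$schedule$end[-6]
  expect_true(all(gaps == 256L))        # 0.25 s rest at 1024 Hz, unlabelled
})

test_that("empirical covariances converge to the analytic oracle", {
  ana <- generate_covariance_set(small_synth())
  err <- vapply(c(2, 8), function(reps) {
    cfg <- small_synth(seed = 9, reps = reps)
    rec <- generate_recording(cfg)
    ep <- segment_epochs(rec, window_s = 1, step_s = 1)
    emp <- class_covariances(ep, normalize = FALSE)
    max(vapply(seq_along(ana$covariances), function(i)
      norm(emp$covariances[[i]] - ana$covariances[[i]], "F") /
        norm(ana$covariances[[i]], "F"), numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])             # error shrinks with duration
  expect_lt(err[2], 0.2)
})

test_that("the null configuration carries no class information", {
  cfg <- small_synth(seed = 13, source_gain = 0)
  ana <- generate_covariance_set(cfg)
  # all classes identical: pure unit sensor noise
  for (S in ana$covariances)
    expect_equal(S, diag(nrow(S)))
  sel <- select_channels(ana, 3)
  expect_equal(attr(sel, "ranking")$mi, rep(0, nrow(ana$covariances[[1]])))

  # empirical: recorded null data yield near-zero MI for every filter
  rec <- generate_recording(cfg)
  ep <- segment_epochs(rec, window_s = 0.25, step_s = 0.25)
  cs <- class_covariances(ep)
  rk <- rank_filters_by_mi(ffdiag_jad(cs), cs)
  expect_lt(max(rk$mi), 0.01)
})

test_that("planted centre electrodes dominate their class topography", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    cfg <- small_synth(n_classes = 3, seed = 300 + s)
    rec <- generate_recording(cfg)
    ep <- segment_epochs(rec, window_s = 1, step_s = 1)
    planted <- planted_channels(cfg)
    for (ci in 1:3) {
      idx <- which(ep$labels == paste0("M", ci))
      mean_rms <- rowMeans(vapply(ep$epochs[idx],
                                  function(E) sqrt(rowMeans(E^2)),
                                  numeric(cfg$layout$n_channels)))
      total <- total + 1
      if (which.max(mean_rms) == planted[ci]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("class sources are band-limited to the configured band", {
  cfg <- small_synth(n_classes = 2, seed = 17, source_band = c(100, 300))
  rec <- generate_recording(cfg)
  ch <- planted_channels(cfg)[1]
  idx <- (rec$schedule$start[1] + 1):(rec$schedule$end[1])
  x <- rec$signal[ch, idx]
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) / length(x) * cfg$fs
  half <- fr <= cfg$fs / 2
  inband <- half & fr >= 100 & fr <= 300
  # out-of-band power is sensor noise only, far below in-band source power
  expect_gt(mean(sp[inband]), 3 * mean(sp[half & !inband]))
})

test_that("analytic covariances reflect centre sharing and amplitude grades", {
  cfg <- synth_config(seed = 0)          # default: 8 classes on 5 foci
  expect_length(planted_channels(cfg), 5L)
  expect_equal(cfg$class_amps[1:5], rep(0.7, 5))
  expect_equal(cfg$class_amps[6:8], rep(0.7 * 1.6, 3))
  ana <- generate_covariance_set(cfg)
  # classes 1 and 6 share a centre; class 6 has the larger centre variance
  c1 <- planted_channels(cfg)[1]
  expect_gt(ana$covariances[[6]][c1, c1], ana$covariances[[1]][c1, c1])
  # no two class covariances coincide
  for (i in 1:7) for (j in (i + 1):8)
    expect_gt(norm(ana$covariances[[i]] - ana$covariances[[j]], "F"), 0.1)
})
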