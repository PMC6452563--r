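test_that("Gaussian conditional entropy evaluates in nats", {
  # unit variance: 0.5 * ln(2*pi*e)
  expect_equal(conditional_entropy(1, matrix(1)), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  # variance e^2 adds exactly one nat
  expect_equal(conditional_entropy(1, matrix(exp(2))),
               0.5 * log(2 * pi * exp(1)) + 1, tolerance = 1e-12)
  expect_error(conditional_entropy(c(1, 0), diag(c(0, 1))), "positive")
})

test_that("cumulant negentropy approximation matches closed forms", {
  expect_equal(negentropy_approx(0, 0), 0)
  expect_equal(negentropy_approx(0, 1), 1 / 48)
  expect_equal(negentropy_approx(0.6, 0), 0.03)
  expect_gte(negentropy_approx(-2, -3), 0)
})

test_that("closed-form MI matches hand evaluation and null case", {
  # identical class conditionals carry no label information
  eq <- class_cov_set(lapply(1:4, function(i) matrix(1)))
  expect_identical(mutual_information(1, eq), 0)

  # M = 2, p = (1/2, 1/2), variances (0.5, 1.5):
  # -0.25*ln(0.75) - (3/16)*(1.25 - 1)^2 = 0.06020177
  two <- class_cov_set(list(matrix(0.5), matrix(1.5)))
  expect_equal(mutual_information(1, two),
               -0.25 * log(0.75) - (3 / 16) * 0.25^2, tolerance = 1e-12)
  expect_equal(mutual_information(1, two), 0.0602018, tolerance = 1e-6)

  # unscaled filters are rejected
  expect_error(mutual_information(2, two), "scale")
})

test_that("closed-form MI tracks a Monte-Carlo mixture-entropy estimate", {
  set.seed(91)
  for (i in 1:5) {
    v <- runif(8, 0.5, 2); v <- v / mean(v)
    cs <- class_cov_set(lapply(v, function(x) matrix(x)))
    mi_cf <- mutual_information(1, cs)
    n <- 2e5
    lab <- sample.int(8, n, replace = TRUE)
    y <- rnorm(n, sd = sqrt(v[lab]))
    dens <- rowMeans(vapply(1:8, function(k) dnorm(y, sd = sqrt(v[k])),
                            numeric(n)))
    mi_mc <- -mean(log(dens)) - sum(0.125 * 0.5 * log(2 * pi * exp(1) * v))
    expect_lt(abs(mi_cf - mi_mc), 0.05)
  }
})

test_that("MI is invariant to filter sign and class relabelling", {
  set.seed(101)
  covs <- lapply(1:4, function(i) random_spd(3))
  cs <- class_cov_set(covs)
  w <- scale_filter(rnorm(3), cs)
  mi <- mutual_information(w, cs)
  expect_equal(mutual_information(-w, cs), mi, tolerance = 1e-14)
  perm <- c(3, 1, 4, 2)
  csp <- class_cov_set(covs[perm], priors = cs$priors[perm])
  expect_equal(mutual_information(w, csp), mi, tolerance = 1e-14)
  expect_gte(mi, 0)
})

test_that("two-class MI grows with the variance contrast", {
  vs <- seq(1, 1.8, by = 0.1)
  mis <- vapply(vs, function(v) {
    cs <- class_cov_set(list(matrix(2 - v), matrix(v)))
    mutual_information(1, cs)
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("eigenvalue score map has its stated fixed point and symmetry", {
  for (M in c(2, 4, 8))
    expect_equal(score_eigenvalue(1 / M, M), 1 / M, tolerance = 1e-12)
  # lambda -> 1: score -> 1
  expect_equal(score_eigenvalue(0.999, 8), 0.999, tolerance = 1e-12)
  # M = 2 reduces to max(lambda, 1 - lambda), symmetric
  expect_equal(score_eigenvalue(0.02, 2), 0.98)
  lam <- seq(0.05, 0.95, by = 0.05)
  expect_equal(score_eigenvalue(lam, 2), score_eigenvalue(1 - lam, 2))
  # discriminative both ways: small and large lambda score high
  expect_gt(score_eigenvalue(0.02, 8), score_eigenvalue(1 / 8, 8))
  expect_gt(score_eigenvalue(0.9, 8), score_eigenvalue(1 / 8, 8))
  expect_error(score_eigenvalue(1.2, 8), "inside")
  # the literal printed reading stays available
  expect_equal(score_eigenvalue(0.02, 2, form = "literal"),
               max(0.02, (1 / 9) * 0.02 / 0.98))
})

test_that("filter-bank MI evaluation satisfies the entropy bookkeeping", {
  set.seed(111)
  covs <- lapply(1:3, function(i) random_spd(4))
  cs <- class_cov_set(covs, priors = c(0.5, 0.3, 0.2))
  W <- matrix(rnorm(16), 4)
  ev <- evaluate_filter_mi(W, cs)
  # I = H(y) - sum_i p_i H(y | c_i), per column
  recon <- ev$marginal_entropies - colSums(ev$cond_entropies * cs$priors)
  expect_equal(ev$per_filter_mi, recon, tolerance = 1e-12)
  # scaled columns have unit mean-covariance variance
  Sbar <- mean_covariance(cs)
  expect_equal(colSums(ev$scaled_W * (Sbar %*% ev$scaled_W)), rep(1, 4),
               tolerance = 1e-10)
})
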