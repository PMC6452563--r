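test_that("PCA filter count follows the cumulative contribution rate", {
  # rank-1 covariance: one component suffices
  v <- c(1, 2, 3)
  expect_equal(ncol(pca_filters(outer(v, v), 0.95)$W), 1L)
  # eigenvalues (9, 1): 9/10 < 0.95, so k = 2
  expect_equal(ncol(pca_filters(diag(c(9, 1)), 0.95)$W), 2L)
  # identity, N = 64: k = ceil(0.95 * 64) = 61
  expect_equal(ncol(pca_filters(diag(64), 0.95)$W), 61L)
  # columns orthonormal
  b <- pca_filters(random_spd(6), 0.99)
  expect_equal(crossprod(b$W), diag(ncol(b$W)), tolerance = 1e-10)
})

test_that("two-class CSP solves the joint diagonalization identity", {
  # already diagonal, sum = I: filters are the coordinate axes
  b <- csp_two_class(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(b$class_spectra[1, ], c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(b$W), diag(2), tolerance = 1e-10)

  # identical classes: nothing to separate, every D1 entry = 1/2
  S <- random_spd(4)
  b2 <- csp_two_class(S, S)
  expect_equal(b2$class_spectra[1, ], rep(0.5, 4), tolerance = 1e-10)

  # random SPD pairs: D1 + D2 = I, both projections diagonal, descending D1
  set.seed(21)
  for (i in 1:10) {
    S1 <- random_spd(6); S2 <- random_spd(6)
    b3 <- csp_two_class(S1, S2)
    W <- b3$W
    D1 <- t(W) %*% S1 %*% W
    D2 <- t(W) %*% S2 %*% W
    expect_lt(max(abs(D1 + D2 - diag(6))), 1e-10)
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-10)
    expect_false(is.unsorted(rev(diag(D1))))
    # independent oracle: generalized eigenvalues of (S1, S1 + S2)
    gev <- sort(Re(eigen(solve(S1 + S2) %*% S1)$values), decreasing = TRUE)
    expect_equal(diag(D1), gev, tolerance = 1e-8)
  }
})

test_that("joint diagonalization agrees with two-class CSP", {
  set.seed(31)
  for (i in 1:10) {
    S1 <- random_spd(8); S2 <- random_spd(8)
    b <- csp_two_class(S1, S2)
    j <- ffdiag_jad(class_cov_set(list(S1, S2)))
    oc <- order(-b$class_spectra[1, ]); oj <- order(-j$class_spectra[1, ])
    Wc <- b$W[, oc]; Wj <- j$W[, oj]
    cosv <- abs(colSums(Wc * Wj)) / sqrt(colSums(Wc^2) * colSums(Wj^2))
    expect_lt(max(acos(pmin(cosv, 1))), 1e-6)   # per-filter principal angle
  }
})

test_that("commuting families are diagonalized to numerical zero", {
  set.seed(41)
  covs <- commuting_family(8, 4)
  j <- ffdiag_jad(class_cov_set(covs))
  expect_lt(utils::tail(j$offdiag_history, 1), 1e-10)
  expect_true(j$converged)
})

test_that("off-diagonal criterion is non-increasing on near-commuting sets", {
  set.seed(51)
  for (rep in 1:20) {
    covs <- commuting_family(6, 8)
    covs <- lapply(covs, function(S) {
      E <- matrix(rnorm(36, sd = 0.05), 6)
      S + (E + t(E)) / 2
    })
    j <- ffdiag_jad(class_cov_set(covs))
    h <- j$offdiag_history
    expect_true(all(diff(h) <= 1e-12 * pmax(h[-length(h)], 1)))
  }
})

test_that("filter spectra are consistent with the covariances", {
  set.seed(61)
  covs <- lapply(1:4, function(i) random_spd(5))
  cs <- class_cov_set(covs)
  j <- ffdiag_jad(cs)
  direct <- t(vapply(cs$covariances,
                     function(S) colSums(j$W * (S %*% j$W)), numeric(5)))
  expect_equal(unname(j$class_spectra), unname(direct), tolerance = 1e-8)
  # whitening contract: prior-weighted spectra sum to 1 per filter
  expect_equal(colSums(j$class_spectra * cs$priors), rep(1, 5),
               tolerance = 1e-8)
})

test_that("symmetric FastICA recovers independent non-Gaussian sources", {
  set.seed(71)
  n <- 50000
  S <- rbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
  A <- qr.Q(qr(matrix(rnorm(4), 2)))
  X <- A %*% S
  b <- fastica_filters(X, n_ics = 2, seed = 1)
  expect_true(b$converged)
  Y <- crossprod(b$W, X - rowMeans(X))
  expect_equal(tcrossprod(Y) / ncol(Y), diag(2), tolerance = 1e-6)  # whitened
  C <- abs(stats::cor(t(Y), t(S)))
  # each source matched by exactly one component up to permutation/sign
  expect_gt(min(apply(C, 1, max)), 0.99)
  expect_gt(min(apply(C, 2, max)), 0.99)
})

test_that("FastICA on Gaussian sources degrades gracefully", {
  set.seed(81)
  X <- matrix(rnorm(2 * 20000), 2)
  b <- suppressWarnings(fastica_filters(X, n_ics = 2, max_iter = 30, seed = 2))
  Y <- crossprod(b$W, X - rowMeans(X))
  expect_equal(unname(apply(Y, 1, stats::var)), c(1, 1), tolerance = 0.05)
})
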