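#' @keywords internal
new_filter_bank <- function(W, method, class_spectra = NULL, mi = NULL,
                            converged = NA, extra = list()) {
  out <- c(list(W = W, method = method, class_spectra = class_spectra,
                mi_scores = mi, converged = converged), extra)
  class(out) <- "spatial_filter_bank"
  out
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("<spatial_filter_bank> method ", x$method, ", ", nrow(x$W),
      " channels x ", ncol(x$W), " filters\n", sep = "")
  invisible(x)
}

# Deterministic sign convention: flip each column so its largest-|entry| is
# positive; ties broken by first occurrence.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Symmetric inverse square root of an SPD matrix, with ridge regularization
# when badly conditioned.
inv_sqrt_spd <- function(S, cond_limit = 1e12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values
  if (min(vals) <= 0 || max(vals) / min(vals) > cond_limit) {
    eps <- 1e-9 * sum(diag(S)) / nrow(S)
    vals <- vals + eps
    if (min(vals) <= 0) stop("covariance not positive definite even after ",
                             "regularization; check the input")
  }
  list(P = e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors),
       eigen = e)
}

#' PCA spatial filters at a cumulative contribution rate
#'
#' Eigendecomposes the pooled (prior-weighted mean) covariance and retains the
#' smallest number of leading components whose cumulative eigenvalue fraction
#' reaches the requested contribution rate (the convention in HD-sEMG
#' dimensionality reduction is 95%).
#'
#' @param cov A `class_cov_set`, or a single covariance matrix.
#' @param contribution Cumulative variance fraction to retain, in (0, 1].
#' @return A `spatial_filter_bank` with orthonormal columns (method `"PCA"`);
#'   attribute fields `eigenvalues` (all N) and `contribution` achieved.
#' @export
pca_filters <- function(cov, contribution = 0.95) {
  stopifnot(contribution > 0, contribution <= 1)
  S <- if (inherits(cov, "class_cov_set")) mean_covariance(cov) else as.matrix(cov)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("input covariance is not positive semi-definite")
  vals <- pmax(e$values, 0)
  tot <- sum(vals)
  if (tot == 0) stop("zero covariance has no principal components")
  k <- which(cumsum(vals) / tot >= contribution - 1e-15)[1]
  W <- fix_signs(e$vectors[, seq_len(k), drop = FALSE])
  spectra <- if (inherits(cov, "class_cov_set")) filter_spectra(W, cov) else NULL
  new_filter_bank(W, "PCA", class_spectra = spectra,
                  extra = list(eigenvalues = vals,
                               contribution = sum(vals[seq_len(k)]) / tot))
}

#' Per-class diagonal spectra of a filter bank
#'
#' Returns the matrix of projected class variances
#' \eqn{\lambda_i^c = \omega_j^\top \Sigma_{c_i} \omega_j}.
#'
#' @param W N x L filter matrix (columns are filters).
#' @param cov A `class_cov_set`.
#' @return M x L matrix, rows named by class.
#' @export
filter_spectra <- function(W, cov) {
  out <- t(vapply(cov$covariances,
                  function(S) colSums(W * (S %*% W)),
                  numeric(ncol(W))))
  rownames(out) <- cov$labels
  out
}

#' Two-class common spatial patterns
#'
#' Solves the generalized eigenproblem for a pair of class covariances so that
#' the returned filters simultaneously diagonalize both:
#' \eqn{W^\top \Sigma_1 W = D_1}, \eqn{W^\top \Sigma_2 W = D_2}, with
#' \eqn{D_1 + D_2 = I}. Columns are ordered by descending \eqn{D_1} diagonal,
#' so the first filters maximize class-1 variance while minimizing class-2
#' variance and the last do the opposite.
#'
#' @param sigma1,sigma2 Symmetric PSD matrices of equal size; their sum must
#'   be positive definite (a small ridge is added automatically when the sum
#'   is badly conditioned).
#' @return A `spatial_filter_bank` (method `"CSP"`) whose `class_spectra` rows
#'   are the diagonals of \eqn{D_1} and \eqn{D_2}.
#' @export
csp_two_class <- function(sigma1, sigma2) {
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  stopifnot(all(dim(sigma1) == dim(sigma2)))
  Csum <- (sigma1 + sigma2 + t(sigma1) + t(sigma2)) / 2
  P <- inv_sqrt_spd(Csum)$P
  G <- P %*% ((sigma1 + t(sigma1)) / 2) %*% P
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)     # descending eigenvalues
  W <- fix_signs(P %*% e$vectors)
  d1 <- colSums(W * (sigma1 %*% W))
  d2 <- colSums(W * (sigma2 %*% W))
  spectra <- rbind(d1, d2)
  new_filter_bank(W, "CSP", class_spectra = spectra)
}

#' Joint approximate diagonalization of class covariances (multiclass CSP)
#'
#' Finds a single invertible filter matrix W that makes all M class covariance
#' matrices approximately diagonal at once: \eqn{W^\top \Sigma_{c_i} W \approx
#' D_{c_i}}. The prior-weighted mean covariance is whitened exactly first
#' (so \eqn{W^\top \bar\Sigma W = I} and \eqn{\sum_i p(c_i) D_{c_i} = I}, the
#' multiclass analogue of the two-class identity \eqn{D_1 + D_2 = I}); an
#' orthogonal joint diagonalizer of the whitened set is then found by Jacobi
#' rotation sweeps with the closed-form angle that minimizes the summed
#' squared off-diagonal Frobenius norm. Each rotation cannot increase the
#' off-diagonal criterion, so the recorded history is non-increasing.
#'
#' For M = 2 the result spans the same filters as [csp_two_class()].
#'
#' @param cov A `class_cov_set` with M >= 2 symmetric matrices.
#' @param max_iter Maximum number of full Jacobi sweeps.
#' @param tol Stop when the relative decrease of the off-diagonal criterion
#'   over a sweep falls below this (or the criterion reaches numerical zero).
#' @return An object of class `jad_result` (also a `spatial_filter_bank`,
#'   method `"CSP_JAD"`): fields `W` (N x N), `class_spectra` (M x N),
#'   `offdiag_history`, `iterations`, `converged`.
#' @export
ffdiag_jad <- function(cov, max_iter = 100L, tol = 1e-12) {
  stopifnot(inherits(cov, "class_cov_set"))
  M <- length(cov$covariances)
  if (M < 2) stop("need at least two classes")
  N <- nrow(cov$covariances[[1]])
  Sbar <- mean_covariance(cov)
  P <- inv_sqrt_spd(Sbar)$P
  # Whitened class matrices stacked side by side (N x N*M) so each Givens
  # rotation touches all M matrices in a few vectorized slice operations.
  Tm <- do.call(cbind, lapply(cov$covariances, function(S) {
    G <- P %*% S %*% P
    (G + t(G)) / 2
  }))
  col_of <- function(j) j + N * (seq_len(M) - 1L)   # column j of every matrix
  offdiag <- function() {
    diag_sq <- sum(vapply(seq_len(M), function(k)
      sum(diag(Tm[, ((k - 1L) * N + 1L):(k * N)])^2), numeric(1)))
    sum(Tm^2) - diag_sq
  }

  Q <- diag(N)
  history <- offdiag()
  converged <- FALSE
  iter <- 0L
  if (N >= 2) {
    pcols <- lapply(seq_len(N), col_of)
    for (sweep in seq_len(max_iter)) {
      iter <- sweep
      for (p in 1:(N - 1)) for (q in (p + 1):N) {
        pk <- pcols[[p]]; qk <- pcols[[q]]
        # Cardoso-Souloumiac closed-form Givens angle for symmetric matrices
        h1 <- Tm[p, pk] - Tm[q, qk]
        h2 <- 2 * Tm[p, qk]
        ton <- sum(h1^2) - sum(h2^2)
        toff <- 2 * sum(h1 * h2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        if (abs(theta) < 1e-16) next
        cs <- cos(theta); sn <- sin(theta)
        cp <- Tm[, pk]; cq <- Tm[, qk]
        Tm[, pk] <- cp * cs + cq * sn
        Tm[, qk] <- cq * cs - cp * sn
        rp <- Tm[p, ]; rq <- Tm[q, ]
        Tm[p, ] <- rp * cs + rq * sn
        Tm[q, ] <- rq * cs - rp * sn
        qp <- Q[, p] * cs + Q[, q] * sn
        Q[, q] <- Q[, q] * cs - Q[, p] * sn
        Q[, p] <- qp
      }
      history <- c(history, offdiag())
      last <- length(history)
      drop_rel <- (history[last - 1] - history[last]) /
        max(history[last - 1], .Machine$double.eps)
      if (history[last] < 1e-24 || drop_rel < tol) {
        converged <- TRUE
        break
      }
    }
  } else converged <- TRUE

  W <- fix_signs(P %*% Q)
  spectra <- filter_spectra(W, cov)
  out <- new_filter_bank(W, "CSP_JAD", class_spectra = spectra,
                         converged = converged,
                         extra = list(offdiag_history = history,
                                      iterations = iter))
  class(out) <- c("jad_result", class(out))
  out
}

#' Symmetric FastICA spatial filters
#'
#' Estimates independent components from pooled epoch data by fixed-point
#' iteration on a negentropy contrast with symmetric (parallel)
#' orthogonalization: the data are centred and whitened to `n_ics` dimensions
#' by PCA, then all unmixing vectors are updated together and re-orthogonalized
#' each iteration, avoiding the error accumulation of one-at-a-time deflation.
#' Components have unit variance on the training data.
#'
#' @param epochs An `epoch_set` (windows are pooled) or a channels x samples
#'   matrix.
#' @param n_ics Number of independent components (defaults to the PCA
#'   dimension at 95% contribution, the usual way to pick the IC count).
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the update (1 - min diag correlation).
#' @param fun Contrast nonlinearity, `"logcosh"` or `"kurtosis"`.
#' @param seed Seed for the random orthogonal initialization.
#' @return A `spatial_filter_bank` (method `"FASTICA"`): `W` maps channels to
#'   components (`t(W) %*% x`), `converged` flags fixed-point convergence
#'   (non-convergence warns but still returns the current estimate).
#' @export
fastica_filters <- function(epochs, n_ics = NULL, max_iter = 200L,
                            tol = 1e-6, fun = c("logcosh", "kurtosis"),
                            seed = 0L) {
  fun <- match.arg(fun)
  X <- if (inherits(epochs, "epoch_set")) do.call(cbind, epochs$epochs)
       else as.matrix(epochs)
  N <- nrow(X); n <- ncol(X)
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / n
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (is.null(n_ics)) {
    vals <- pmax(e$values, 0)
    n_ics <- which(cumsum(vals) / sum(vals) >= 0.95 - 1e-15)[1]
  }
  stopifnot(n_ics >= 1, n_ics <= N)
  d <- e$values[seq_len(n_ics)]
  if (min(d) <= 0) stop("data rank below n_ics; reduce n_ics")
  K <- diag(1 / sqrt(d), n_ics) %*% t(e$vectors[, seq_len(n_ics), drop = FALSE])
  Z <- K %*% X                                   # whitened, cov(Z) = I

  sym_orth <- function(B) {
    s <- eigen(B %*% t(B), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), nrow(B)) %*%
      t(s$vectors) %*% B
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  B <- sym_orth(matrix(stats::rnorm(n_ics^2), n_ics))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- B %*% Z
    if (fun == "logcosh") {
      G <- tanh(Y)
      B_new <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), n_ics) %*% B
    } else {
      B_new <- (Y^3 %*% t(Z)) / n - 3 * B
    }
    B_new <- sym_orth(B_new)
    delta <- 1 - min(abs(diag(B_new %*% t(B))))
    B <- B_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("FastICA did not converge in ", max_iter, " iterations")
  W <- fix_signs(t(B %*% K))                      # channels x n_ics
  new_filter_bank(W, "FASTICA", converged = converged,
                  extra = list(iterations = it))
}
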