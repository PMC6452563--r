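#' Gaussian conditional entropy of a filtered output
#'
#' Within one motion class the filtered signal \eqn{y = \omega^\top x} is
#' modelled as zero-mean Gaussian with variance
#' \eqn{\sigma^2 = \omega^\top \Sigma_{c} \omega}, whose differential entropy
#' is \eqn{\tfrac12 \ln(2\pi e\,\sigma^2)} nats.
#'
#' @param w Filter column (numeric vector).
#' @param sigma_c Class covariance matrix.
#' @return Entropy in nats.
#' @export
conditional_entropy <- function(w, sigma_c) {
  v <- drop(crossprod(w, sigma_c %*% w))
  if (!is.finite(v) || v <= 0)
    stop("filtered class variance must be positive, got ", v)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Cumulant-based negentropy approximation
#'
#' Approximates the negentropy of a unit-variance variable from its third and
#' fourth cumulants, \eqn{J(y) \approx k_3^2/12 + k_4^2/48} (in nats); zero
#' for a Gaussian, always non-negative.
#'
#' @param k3 Third cumulant \eqn{E\{y^3\}}.
#' @param k4 Fourth cumulant \eqn{E\{y^4\} - 3}.
#' @return Negentropy in nats.
#' @export
negentropy_approx <- function(k3, k4) {
  k3^2 / 12 + k4^2 / 48
}

#' Projected class variances of a filter
#' @keywords internal
class_variances <- function(w, cov) {
  vapply(cov$covariances, function(S) drop(crossprod(w, S %*% w)), numeric(1))
}

#' Closed-form mutual information between class label and filtered output
#'
#' Models the filtered output \eqn{y = \omega^\top x} as a zero-mean Gaussian
#' mixture across the M motion classes and evaluates
#' \deqn{I(c, y) \approx -\sum_i p(c_i) \ln\sqrt{v_i}
#'   \;-\; \tfrac{3}{16}\Bigl(\sum_i p(c_i)\, v_i^2 - 1\Bigr)^2,}
#' where \eqn{v_i = \omega^\top \Sigma_{c_i} \omega}. The first term is the
#' Gaussian part \eqn{H_g(y) - H(y|c)}; the quartic term subtracts the
#' mixture's negentropy approximated from its fourth cumulant (the mixture is
#' symmetric, so the third cumulant vanishes). The formula requires the filter
#' to be scaled to unit variance under the prior-weighted mean covariance
#' (\eqn{\omega^\top \bar\Sigma \omega = 1}), which makes the mixture itself
#' unit-variance.
#'
#' The approximation can undershoot slightly below zero for extreme variance
#' spreads; negative values are clamped to 0 with a warning.
#'
#' @param w Filter column, scaled so that \eqn{\omega^\top\bar\Sigma\omega = 1}
#'   (use [scale_filter()]); an unscaled filter is an error.
#' @param cov A `class_cov_set`.
#' @param clamp Clamp tiny negative values (approximation undershoot) to 0.
#' @return Mutual information in nats.
#' @seealso [scale_filter()], [rank_filters_by_mi()]
#' @export
mutual_information <- function(w, cov, clamp = TRUE) {
  stopifnot(inherits(cov, "class_cov_set"))
  v <- class_variances(w, cov)
  if (any(v <= 0)) stop("all class variances must be positive")
  p <- cov$priors
  s <- sum(p * v)
  if (abs(s - 1) > 1e-6)
    stop("filter not scaled: w' Sigma_bar w = ", format(s),
         "; scale w with scale_filter() first")
  mi <- -sum(p * 0.5 * log(v)) - (3 / 16) * (sum(p * v^2) - 1)^2
  if (mi < 0 && clamp) {
    if (mi < -1e-10)
      warning("negative MI approximation (", format(mi), ") clamped to 0")
    mi <- 0
  }
  mi
}

#' Scale a filter to unit mean-covariance variance
#'
#' Rescales \eqn{\omega} so that \eqn{\omega^\top \bar\Sigma \omega = 1},
#' the normalization required by [mutual_information()].
#'
#' @param w Filter column.
#' @param cov A `class_cov_set` (its prior-weighted mean covariance is used),
#'   or a covariance matrix.
#' @return The rescaled filter.
#' @export
scale_filter <- function(w, cov) {
  S <- if (inherits(cov, "class_cov_set")) mean_covariance(cov) else as.matrix(cov)
  v <- drop(crossprod(w, S %*% w))
  if (v <= 0) stop("filter has non-positive variance under the mean covariance")
  w / sqrt(v)
}

#' Eigenvalue-to-score mapping for multiclass CSP pattern ranking
#'
#' Maps a class eigenvalue \eqn{\lambda \in (0, 1)} (a projected class variance
#' relative to the pooled variance) to
#' \deqn{\mathrm{score}(\lambda) = \max\Bigl(\lambda,\;
#'   \frac{1}{1 + (M-1)^2 \lambda / (1-\lambda)}\Bigr),}
#' so that eigenvalues whose ratios to the mean eigenvalue of the other
#' classes are multiplicatively inverse receive the same score: both very
#' large and very small class variances mark a discriminative filter. The
#' fixed point is \eqn{\lambda = 1/M}, the value of a completely
#' non-discriminative filter; for M = 2 the map reduces to
#' \eqn{\max(\lambda, 1-\lambda)}.
#'
#' `form = "literal"` evaluates the alternative reading
#' \eqn{\max(\lambda, (1+M)^{-2}\lambda/(1-\lambda))} instead.
#'
#' @param lambda Class eigenvalue(s) in (0, 1); vectorised.
#' @param M Number of classes.
#' @param form `"balanced"` (default, the multiplicative-inverse property
#'   holds) or `"literal"`.
#' @return Score value(s).
#' @export
score_eigenvalue <- function(lambda, M, form = c("balanced", "literal")) {
  form <- match.arg(form)
  if (any(lambda <= 0 | lambda >= 1))
    stop("lambda must lie strictly inside (0, 1)")
  if (form == "balanced") {
    pmax(lambda, 1 / (1 + (M - 1)^2 * lambda / (1 - lambda)))
  } else {
    pmax(lambda, (1 / (1 + M)^2) * lambda / (1 - lambda))
  }
}

#' Full MI evaluation of a filter bank
#'
#' Scales every column of a filter bank to unit mean-covariance variance and
#' evaluates the closed-form mutual information, conditional entropies and
#' marginal entropy per column.
#'
#' @param W N x L filter matrix or a `spatial_filter_bank`.
#' @param cov A `class_cov_set`.
#' @return A list of class `mi_evaluation`: `per_filter_mi` (length L, nats),
#'   `cond_entropies` (M x L), `marginal_entropies` (length L),
#'   `scaled_W` (the unit-variance columns), `scaled = TRUE`.
#' @export
evaluate_filter_mi <- function(W, cov) {
  if (inherits(W, "spatial_filter_bank")) W <- W$W
  W <- as.matrix(W)
  Ws <- apply(W, 2, scale_filter, cov = cov)
  Ws <- matrix(Ws, nrow = nrow(W))
  L <- ncol(Ws); M <- length(cov$covariances)
  ce <- matrix(NA_real_, M, L, dimnames = list(cov$labels, NULL))
  mi <- numeric(L)
  for (j in seq_len(L)) {
    for (i in seq_len(M))
      ce[i, j] <- conditional_entropy(Ws[, j], cov$covariances[[i]])
    mi[j] <- mutual_information(Ws[, j], cov)
  }
  marg <- mi + colSums(ce * cov$priors)
  structure(list(per_filter_mi = mi, cond_entropies = ce,
                 marginal_entropies = marg, scaled_W = Ws, scaled = TRUE),
            class = "mi_evaluation")
}
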