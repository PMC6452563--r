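#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One row per fold: `fold`, `accuracy`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracies),
                 accuracy = x$fold_accuracies)
}

#' Glance at a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `folds`, `n`, `accuracy`, `accuracy_sd`.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(model = x$model, folds = x$k, n = x$n,
                 accuracy = x$accuracy,
                 accuracy_sd = stats::sd(x$fold_accuracies))
}

#' Tidy a fitted spatial filter bank
#'
#' @param x A `spatial_filter_bank`.
#' @param ... Unused.
#' @return Long tibble with one row per (filter, channel) weight:
#'   columns `filter`, `channel`, `weight`.
#' @method tidy spatial_filter_bank
#' @export
tidy.spatial_filter_bank <- function(x, ...) {
  out <- tibble::tibble(
    filter = rep(seq_len(ncol(x$W)), each = nrow(x$W)),
    channel = rep(seq_len(nrow(x$W)), ncol(x$W)),
    weight = as.vector(x$W))
  out
}

#' Glance at a spatial filter bank
#'
#' @param x A `spatial_filter_bank`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `n_channels`, `n_filters`, `converged`.
#' @method glance spatial_filter_bank
#' @export
glance.spatial_filter_bank <- function(x, ...) {
  tibble::tibble(method = x$method, n_channels = nrow(x$W),
                 n_filters = ncol(x$W), converged = x$converged)
}
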