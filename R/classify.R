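# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds. Depends only on (labels, k, seed).
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("classes with fewer than ", k, " samples: ",
         paste(names(counts)[counts < k], collapse = ", "))
  fold <- integer(length(labels))
  set.seed(seed)
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Standardize columns using training-fold statistics only.
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

fit_predict <- function(model, xtr, ytr, xte, seed) {
  switch(model,
    SVM = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, scale = FALSE)
      stats::predict(fit, xte)
    },
    LDA = {
      fit <- MASS::lda(xtr, grouping = ytr)
      stats::predict(fit, xte)$class
    },
    KNN = class::knn(xtr, xte, cl = ytr, k = 5),
    ANN = {
      set.seed(seed)
      fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = 32, softmax = TRUE,
                        decay = 1e-3, maxit = 200, trace = FALSE,
                        MaxNWts = 200000)
      pr <- stats::predict(fit, xte)
      factor(colnames(pr)[max.col(pr)], levels = levels(ytr))
    },
    stop("unknown model ", model)
  )
}

#' Cross-validated motion classification
#'
#' Evaluates a classifier on a wavelet-packet feature matrix by stratified
#' k-fold cross validation. Features are standardized with training-fold
#' means and standard deviations only (no test-fold leakage). Fold assignment
#' depends only on the labels, `k` and `seed`, so repeated runs are
#' bit-identical.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()] (column `label`
#'   plus numeric features), or any data frame shaped that way.
#' @param model One of `"SVM"` (radial kernel, cost 1), `"LDA"`, `"KNN"`
#'   (k = 5), `"ANN"` (single hidden layer of 32 units with weight decay).
#' @param k Number of folds (the conventional choice is 5).
#' @param seed Seed controlling fold assignment and ANN initialization.
#' @return An object of class `cv_result`: `accuracy` (mean over folds),
#'   `fold_accuracies`, `confusion` (true class in rows, predicted in
#'   columns, summed over folds), `model`, `k`, `seed`, `n`.
#' @export
crossval_evaluate <- function(fm, model = c("SVM", "LDA", "KNN", "ANN"),
                              k = 5L, seed = 0L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(fm), "label" %in% names(fm))
  y <- factor(fm$label)
  X <- as.matrix(fm[setdiff(names(fm), "label")])
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  fold <- stratified_folds(y, k, seed)
  lev <- levels(y)
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    std <- standardize_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    pred <- fit_predict(model, std$train, y[tr], std$test, seed = seed + f)
    truth <- y[te]
    fold_acc[f] <- mean(pred == truth)
    confusion <- confusion + unclass(table(truth, factor(pred, levels = lev)))
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
                 confusion = confusion, model = model, k = as.integer(k),
                 seed = as.integer(seed), n = nrow(X)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$model, ", ", x$k, "-fold CV on ", x$n,
      " samples: accuracy ", sprintf("%.3f", x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Accuracy as a function of the number of selected channels
#'
#' Runs the full selection pipeline (epoching, per-class covariances,
#' joint-diagonalization CSP, MI ranking) once, then for every requested
#' channel count extracts wavelet-packet features from the top channels and
#' cross-validates each classifier.
#'
#' @param rec An [emg_recording()].
#' @param l_values Integer vector of channel counts L' to evaluate.
#' @param models Character vector of classifiers (see [crossval_evaluate()]).
#' @param window_s,step_s Analysis-window parameters for [segment_epochs()].
#' @param cfg A [wpt_config()].
#' @param k Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @return A tibble with columns `n_channels`, `model`, `accuracy` and a
#'   list-column `fit` holding each `cv_result`.
#' @export
channel_sweep <- function(rec, l_values, models = c("SVM", "LDA", "KNN", "ANN"),
                          window_s = 0.25, step_s = 0.125,
                          cfg = wpt_config(), k = 5L, seed = 0L) {
  epochs <- segment_epochs(rec, window_s, step_s)
  cov <- class_covariances(epochs)
  bank <- ffdiag_jad(cov)
  ranking <- rank_filters_by_mi(bank, cov)
  rows <- list()
  for (L in as.integer(l_values)) {
    sel <- filters_to_channels(bank, ranking, L)
    fm <- build_feature_matrix(epochs, sel, cfg)
    for (m in models) {
      fit <- crossval_evaluate(fm, m, k = k, seed = seed)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_channels = L, model = m, accuracy = fit$accuracy, fit = list(fit))
    }
  }
  dplyr::bind_rows(rows)
}
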