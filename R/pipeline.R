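#' Apply a spatial filter bank to an epoch set
#'
#' Projects every window through the filter columns, \eqn{y = W^\top x},
#' yielding component signals in place of channel signals.
#'
#' @param epochs An `epoch_set`.
#' @param bank A `spatial_filter_bank` (or a plain N x L matrix).
#' @return An `epoch_set` of L-component windows.
#' @export
apply_filters <- function(epochs, bank) {
  W <- if (inherits(bank, "spatial_filter_bank")) bank$W else as.matrix(bank)
  stopifnot(inherits(epochs, "epoch_set"), nrow(W) == nrow(epochs$epochs[[1]]))
  out <- epochs
  out$epochs <- lapply(epochs$epochs, function(E) crossprod(W, E))
  out$layout <- NULL
  out
}

#' Run the full recognition pipeline from a config
#'
#' Executes preprocessing, spatial filtering, channel selection (for the
#' CSP-JAD method), wavelet-packet feature extraction and cross-validated
#' classification, end to end. With `method = "csp-jad"` the top `n_channels`
#' physical electrodes by mutual information are selected and features come
#' from the raw selected channels; with `"pca"` or `"ica"` there is no
#' channel mapping, so features come from the reconstructed component signals
#' instead.
#'
#' @param config A named list, or path to a JSON file holding one. Keys:
#'   \describe{
#'     \item{simulate}{list of [synth_config()] overrides (generates the
#'       input), or}
#'     \item{recording}{`list(matrix_path=, meta_path=)` for
#'       [read_recording()].}
#'     \item{method}{`"csp-jad"` (default), `"pca"`, or `"ica"`.}
#'     \item{n_channels}{channels L' to select (csp-jad; default 5).}
#'     \item{contribution}{PCA contribution rate (default 0.95).}
#'     \item{window_s, step_s}{analysis windows (defaults 0.25 / 0.125 s).}
#'     \item{wavelet, depth}{WPT settings (defaults sym5, 4).}
#'     \item{model}{classifier (default `"SVM"`).}
#'     \item{folds, seed}{CV folds (5) and seed (0).}
#'     \item{out_dir}{optional directory for metrics JSON, selection JSON and
#'       confusion CSV.}
#'   }
#' @return A list of class `pipeline_result`: `metrics` (one-row tibble),
#'   `cv` (`cv_result`), `selection` (`channel_selection` or NULL),
#'   `ranking`, `bank`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  get_opt <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  method <- match.arg(get_opt("method", "csp-jad"), c("csp-jad", "pca", "ica"))
  seed <- as.integer(get_opt("seed", 0L))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  rec <- stage("input", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- seed
      generate_recording(do.call(synth_config, args))
    } else if (!is.null(config$recording)) {
      read_recording(config$recording$matrix_path, config$recording$meta_path)
    } else stop("config needs either 'simulate' or 'recording'")
  })

  epochs <- stage("preprocess",
    segment_epochs(rec, get_opt("window_s", 0.25), get_opt("step_s", 0.125)))
  cov <- stage("preprocess", class_covariances(epochs))
  cfg_wpt <- wpt_config(get_opt("wavelet", "sym5"), get_opt("depth", 4L))

  selection <- NULL; ranking <- NULL
  if (method == "csp-jad") {
    bank <- stage("spatial", ffdiag_jad(cov))
    ranking <- stage("selection", rank_filters_by_mi(bank, cov))
    selection <- stage("selection",
      filters_to_channels(bank, ranking, get_opt("n_channels", 5L),
                          mapping = get_opt("mapping", "peak")))
    fm <- stage("features", build_feature_matrix(epochs, selection, cfg_wpt))
  } else {
    bank <- stage("spatial", if (method == "pca") {
      pca_filters(cov, contribution = get_opt("contribution", 0.95))
    } else {
      fastica_filters(epochs, n_ics = config$n_ics, seed = seed)
    })
    comp <- stage("features", apply_filters(epochs, bank))
    fm <- stage("features",
      build_feature_matrix(comp, seq_len(ncol(bank$W)), cfg_wpt))
  }

  cv <- stage("classify",
    crossval_evaluate(fm, get_opt("model", "SVM"),
                      k = as.integer(get_opt("folds", 5L)), seed = seed))

  metrics <- tibble::tibble(
    method = method, model = cv$model,
    n_channels = if (is.null(selection)) ncol(bank$W) else nrow(selection),
    n_features = ncol(fm) - 1L, n_windows = cv$n, folds = cv$k,
    seed = seed, accuracy = cv$accuracy)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(selection))
      write_selection(selection, file.path(out_dir, "selection.json"))
    utils::write.csv(as.data.frame(cv$confusion),
                     file.path(out_dir, "confusion.csv"))
  }

  structure(list(metrics = metrics, cv = cv, selection = selection,
                 ranking = ranking, bank = bank, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$metrics)
  invisible(x)
}
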