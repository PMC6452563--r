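#' Rank multiclass-CSP filter columns by mutual information
#'
#' Scales every column of the filter bank to unit variance under the
#' prior-weighted mean covariance and ranks columns by the closed-form mutual
#' information between motion class and filtered output, in descending order.
#' Ties are broken by original column index (stable).
#'
#' @param bank A `spatial_filter_bank` from [ffdiag_jad()] (method
#'   `"CSP_JAD"`).
#' @param cov The `class_cov_set` the bank was fitted on (dimensions must
#'   match).
#' @return A tibble of class `mi_ranking` with columns `rank`, `column`
#'   (original column index in `bank$W`), `mi` (nats); the full
#'   `mi_evaluation` is attached as attribute `"evaluation"`.
#' @export
rank_filters_by_mi <- function(bank, cov) {
  stopifnot(inherits(bank, "spatial_filter_bank"),
            inherits(cov, "class_cov_set"))
  if (!identical(bank$method, "CSP_JAD"))
    stop("MI ranking is defined for CSP_JAD banks, got method ", bank$method)
  if (nrow(bank$W) != nrow(cov$covariances[[1]]))
    stop("dimension mismatch: bank has ", nrow(bank$W),
         " channels, covariances have ", nrow(cov$covariances[[1]]))
  ev <- evaluate_filter_mi(bank$W, cov)
  ord <- order(-ev$per_filter_mi, seq_along(ev$per_filter_mi))
  out <- tibble::tibble(rank = seq_along(ord), column = as.integer(ord),
                        mi = ev$per_filter_mi[ord])
  attr(out, "evaluation") <- ev
  class(out) <- c("mi_ranking", class(out))
  out
}

#' Map ranked filter columns to physical electrode channels
#'
#' Walks the MI-ranked filter columns and, for each, nominates the physical
#' channel carrying the column's maximum absolute weight (`mapping = "peak"`,
#' the default); channels already selected are skipped so further columns are
#' consumed until `n_channels` distinct electrodes are collected. The
#' alternative `mapping = "mass"` ranks channels by their total absolute
#' weight across the top-ranked columns (sensitivity analysis).
#'
#' @param bank The `spatial_filter_bank` whose columns were ranked.
#' @param ranking An `mi_ranking` from [rank_filters_by_mi()] (or an integer
#'   vector of column indices in rank order, in which case `mi` is NA).
#' @param n_channels Number of distinct physical channels L' to select.
#' @param mapping `"peak"` or `"mass"`.
#' @return A tibble of class `channel_selection` with columns `channel`
#'   (physical channel index, selection order), `filter_column` (nominating
#'   column; NA for `"mass"`), `mi` (MI of that column).
#' @export
filters_to_channels <- function(bank, ranking, n_channels,
                                mapping = c("peak", "mass")) {
  mapping <- match.arg(mapping)
  W <- if (inherits(bank, "spatial_filter_bank")) bank$W else as.matrix(bank)
  if (inherits(ranking, "mi_ranking")) {
    cols <- ranking$column; mis <- ranking$mi
  } else {
    cols <- as.integer(ranking); mis <- rep(NA_real_, length(cols))
  }
  n_channels <- as.integer(n_channels)
  if (n_channels < 1) stop("n_channels must be at least 1")
  if (n_channels > nrow(W))
    stop("requested ", n_channels, " channels but only ", nrow(W), " exist")

  if (mapping == "peak") {
    chans <- integer(0); from_col <- integer(0); mi_of <- numeric(0)
    for (k in seq_along(cols)) {
      ch <- which.max(abs(W[, cols[k]]))
      if (ch %in% chans) next
      chans <- c(chans, ch)
      from_col <- c(from_col, cols[k])
      mi_of <- c(mi_of, mis[k])
      if (length(chans) == n_channels) break
    }
    if (length(chans) < n_channels)
      stop("only ", length(chans), " distinct channels nominated by the ",
           length(cols), " ranked columns; requested ", n_channels)
  } else {
    use <- cols[seq_len(min(n_channels, length(cols)))]
    mass <- rowSums(abs(W[, use, drop = FALSE]))
    chans <- order(-mass)[seq_len(n_channels)]
    from_col <- rep(NA_integer_, n_channels)
    mi_of <- rep(NA_real_, n_channels)
  }
  out <- tibble::tibble(channel = as.integer(chans),
                        filter_column = as.integer(from_col), mi = mi_of)
  class(out) <- c("channel_selection", class(out))
  out
}

#' One-step channel selection from class covariances
#'
#' Convenience wrapper: joint diagonalization ([ffdiag_jad()]), MI ranking
#' ([rank_filters_by_mi()]) and channel mapping ([filters_to_channels()]).
#'
#' @param cov A `class_cov_set`.
#' @param n_channels Number of physical channels to select.
#' @param mapping See [filters_to_channels()].
#' @param ... Passed to [ffdiag_jad()].
#' @return A `channel_selection` tibble; the fitted bank and ranking are
#'   attached as attributes `"bank"` and `"ranking"`.
#' @export
select_channels <- function(cov, n_channels, mapping = "peak", ...) {
  bank <- ffdiag_jad(cov, ...)
  ranking <- rank_filters_by_mi(bank, cov)
  sel <- filters_to_channels(bank, ranking, n_channels, mapping = mapping)
  attr(sel, "bank") <- bank
  attr(sel, "ranking") <- ranking
  sel
}

#' Write / read a channel selection as JSON
#'
#' The JSON preserves selection order, nominating filter columns and MI
#' values, so `read_selection(write_selection(x))` reproduces `x`
#' field-for-field.
#'
#' @param sel A `channel_selection`.
#' @param path Output path.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "channel_selection"))
  jsonlite::write_json(
    list(channels = sel$channel, filter_columns = sel$filter_column,
         mi = sel$mi),
    path, digits = NA, null = "null", na = "null"
  )
  invisible(NULL)
}

#' @rdname write_selection
#' @return `read_selection()` returns the `channel_selection` tibble.
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(x$channels)
  out <- tibble::tibble(
    channel = as.integer(if (n) x$channels else integer(0)),
    filter_column = as.integer(if (n) x$filter_columns else integer(0)),
    mi = as.numeric(if (n) x$mi else numeric(0))
  )
  class(out) <- c("channel_selection", class(out))
  out
}
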