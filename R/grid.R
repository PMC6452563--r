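#' Electrode grid layout
#'
#' Describes the physical arrangement of a high-density electrode array as a
#' rectangular grid in which a small number of pad positions may be inactive
#' (carry no recording channel). The default is the 5 x 13 grid with 8 mm
#' inter-electrode distance commonly used for 64-channel HD-sEMG arrays: 65 pad
#' positions of which exactly one is unused. Which pad is unused is
#' hardware-specific; it is configurable and defaults to the last row / last
#' column position.
#'
#' Channels are numbered 1..N in row-major order over the active positions
#' (row 1 left-to-right first). All user-facing channel indices in this package
#' are 1-based.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param inactive Integer matrix (or two-column data frame) of (row, col)
#'   positions carrying no channel, or `NULL` for a fully populated grid.
#' @param pitch_mm Centre-to-centre distance between adjacent electrodes, mm.
#'
#' @return An object of class `grid_layout` with fields `n_rows`, `n_cols`,
#'   `pitch_mm`, `n_channels`, and `channel_at`, an `n_rows` x `n_cols` integer
#'   matrix holding the channel index at each position (`NA` where inactive).
#'
#' @examples
#' g <- grid_layout()          # 5 x 13, 64 channels
#' g$n_channels
#' channel_position(g, 1)      # row/col of channel 1
#' @export
grid_layout <- function(n_rows = 5L, n_cols = 13L,
                        inactive = matrix(c(5L, 13L), ncol = 2),
                        pitch_mm = 8) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1)
  active <- matrix(TRUE, n_rows, n_cols)
  if (!is.null(inactive)) {
    inactive <- as.matrix(inactive)
    if (ncol(inactive) != 2) stop("`inactive` must have two columns (row, col)")
    for (i in seq_len(nrow(inactive))) {
      r <- inactive[i, 1]; c <- inactive[i, 2]
      if (r < 1 || r > n_rows || c < 1 || c > n_cols)
        stop("inactive position (", r, ", ", c, ") outside the grid")
      active[r, c] <- FALSE
    }
  }
  channel_at <- matrix(NA_integer_, n_rows, n_cols)
  # row-major numbering over active pads
  idx <- 0L
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    if (active[r, c]) {
      idx <- idx + 1L
      channel_at[r, c] <- idx
    }
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
         n_channels = idx, channel_at = channel_at),
    class = "grid_layout"
  )
}

#' @export
print.grid_layout <- function(x, ...) {
  cat("<grid_layout> ", x$n_rows, " x ", x$n_cols, " grid, ",
      x$n_channels, " channels, pitch ", x$pitch_mm, " mm\n", sep = "")
  invisible(x)
}

#' Position of a channel on the grid
#'
#' @param layout A [grid_layout()].
#' @param channel Channel index (1-based), vectorised.
#' @return A tibble with columns `channel`, `row`, `col`.
#' @export
channel_position <- function(layout, channel) {
  stopifnot(inherits(layout, "grid_layout"))
  pos <- lapply(channel, function(ch) {
    w <- which(layout$channel_at == ch, arr.ind = TRUE)
    if (nrow(w) != 1) stop("channel ", ch, " not on the grid")
    w
  })
  pos <- do.call(rbind, pos)
  tibble::tibble(channel = as.integer(channel),
                 row = as.integer(pos[, 1]), col = as.integer(pos[, 2]))
}

#' List inactive grid positions
#' @param layout A [grid_layout()].
#' @return Integer matrix of (row, col) pairs; zero rows if none.
#' @export
inactive_positions <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  w <- which(is.na(layout$channel_at), arr.ind = TRUE)
  unname(w[, 1:2, drop = FALSE])
}
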