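#' Per-channel coordinate table for a grid layout
#'
#' Expands a [GridLayout-class] into one row per electrode: channel id
#' (row-major, 1-based), 0-based `(row, col)`, layer, and Euclidean
#' distance (um) from the stimulation electrode.
#'
#' @param layout a [GridLayout-class].
#' @return data.frame with columns `channel_id`, `row`, `col`, `layer`,
#'   `dist_um`, `is_stim`.
#' @export
channelGrid <- function(layout) {
  nr <- layout@nRows; nc <- layout@nCols
  row <- rep(seq_len(nr) - 1L, each = nc)
  col <- rep(seq_len(nc) - 1L, times = nr)
  id <- row * nc + col + 1L
  sr <- layout@stimChannel[1L]; sc <- layout@stimChannel[2L]
  d <- sqrt((row - sr)^2 + (col - sc)^2) * layout@pitchUm
  data.frame(channel_id = id, row = row, col = col,
             layer = layout@layerOfColumn[col + 1L],
             dist_um = d,
             is_stim = row == sr & col == sc)
}

## 8-connected (or 4-connected) neighbour channel ids; the grid boundary
## contributes "off-grid" sides, reported by the caller via count comparison.
gridNeighbors <- function(row, col, nRows, nCols, connectivity = 8L) {
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  r <- row + dr; cc <- col + dc
  ok <- r >= 0L & r < nRows & cc >= 0L & cc < nCols
  list(ids = r[ok] * nCols + cc[ok] + 1L, nOffGrid = sum(!ok))
}

## deterministic per-slice sub-seeds below 2^31
deriveSubSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## centered boxcar smoothing with edge shrinkage; width in samples (odd)
boxcarSmooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
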