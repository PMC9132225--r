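## Layer-resolved spatial maps and channel counts.
##
## Each grid cell gets exactly one category: stimulation (the stimulus
## electrode), recruited, silenced, plasticity (an activated channel whose
## last-window label is potentiated or depressed), activated_only, or
## inactive. Counts per layer conserve: n_with + n_without = n_active,
## where the activated set is {activated_only, plasticity, silenced}.

SPATIAL_CATEGORIES <- c("inactive", "activated_only", "plasticity",
                        "recruited", "silenced", "stimulation")

#' Build the spatial category map of one slice
#'
#' @param qc the slice's [QCReport-class].
#' @param calls plasticity calls from [summarizeLastWindow()] (may be
#'   `NULL` when no plasticity analysis applies).
#' @param recruitment recruitment/silencing calls from
#'   [detectRecruited()]/[detectSilenced()] (may be `NULL`).
#' @param layout the slice's [GridLayout-class].
#' @return data.frame `channel_id`, `row`, `col`, `layer`, `category`
#'   (class `SpatialMap`), one row per grid cell.
#' @export
buildSpatialMap <- function(qc, calls = NULL, recruitment = NULL,
                            layout = gridLayout()) {
  stopifnot(is(qc, "QCReport"))
  grid <- channelGrid(layout)
  st <- channelStatus(qc)
  active <- st$channel_id[st$status != "inactive"]

  cat <- rep("inactive", nrow(grid))
  cat[grid$channel_id %in% active] <- "activated_only"
  if (!is.null(calls)) {
    pl <- calls$channel_id[calls$label %in% c("potentiated", "depressed")]
    cat[grid$channel_id %in% pl & cat == "activated_only"] <- "plasticity"
  }
  if (!is.null(recruitment)) {
    rec <- recruitment$channel_id[recruitment$recruited]
    sil <- recruitment$channel_id[recruitment$silenced]
    conflict <- intersect(rec, active)
    if (length(conflict))
      stop(sprintf("channel %d is recruited but was baseline-activated",
                   conflict[1L]))
    conflict <- setdiff(sil, active)
    if (length(conflict))
      stop(sprintf("channel %d is silenced but was not baseline-activated",
                   conflict[1L]))
    if (length(intersect(rec, sil)))
      stop("a channel cannot be both recruited and silenced")
    cat[grid$channel_id %in% rec] <- "recruited"
    cat[grid$channel_id %in% sil] <- "silenced"
  }
  cat[grid$is_stim] <- "stimulation"
  out <- data.frame(grid[, c("channel_id", "row", "col", "layer")],
                    category = factor(cat, levels = SPATIAL_CATEGORIES))
  class(out) <- c("SpatialMap", "data.frame")
  attr(out, "slice_id") <- qc@sliceId
  attr(out, "nRows") <- layout@nRows
  attr(out, "nCols") <- layout@nCols
  out
}

#' Channel counts per layer
#'
#' Counts, per cortical layer, the activated channels with and without a
#' plasticity label, and the recruited and silenced channels. Silenced
#' channels count as "with plasticity" (their responses are depressed to
#' ~0); the stimulation cell is excluded from all counts.
#'
#' @param map a spatial map from [buildSpatialMap()].
#' @return data.frame `layer`, `n_active`, `n_with_plasticity`,
#'   `n_without_plasticity`, `n_recruited`, `n_silenced`.
#' @export
countByLayer <- function(map) {
  m <- map[map$category != "stimulation", ]
  out <- do.call(rbind, lapply(split(m, m$layer), function(d) {
    nW <- sum(d$category %in% c("plasticity", "silenced"))
    nA <- nW + sum(d$category == "activated_only")
    data.frame(layer = d$layer[1L], n_active = nA,
               n_with_plasticity = nW, n_without_plasticity = nA - nW,
               n_recruited = sum(d$category == "recruited"),
               n_silenced = sum(d$category == "silenced"))
  }))
  rownames(out) <- NULL
  out
}

#' Flag edge channels among recruited cells
#'
#' A recruited cell lies on the edge of the activated area when at least
#' one of its neighbors (8-connected by default; off-grid sides count) is
#' outside the baseline-activated set. The activated set comprises the
#' `activated_only`, `plasticity`, `silenced` and `stimulation` cells.
#'
#' @param map a spatial map from [buildSpatialMap()].
#' @param connectivity 8 (default) or 4.
#' @return the map with a logical `edge` column (`NA` for non-recruited
#'   cells) and attribute `edge_fraction` (fraction of recruited cells on
#'   the edge; `NaN` when there are none).
#' @export
flagEdgeChannels <- function(map, connectivity = 8L) {
  nR <- attr(map, "nRows") %||% (max(map$row) + 1L)
  nC <- attr(map, "nCols") %||% (max(map$col) + 1L)
  activeSet <- map$channel_id[map$category %in%
    c("activated_only", "plasticity", "silenced", "stimulation")]
  edge <- rep(NA, nrow(map))
  rec <- which(map$category == "recruited")
  for (i in rec) {
    nb <- gridNeighbors(map$row[i], map$col[i], nR, nC, connectivity)
    edge[i] <- nb$nOffGrid > 0L || any(!nb$ids %in% activeSet)
  }
  map$edge <- edge
  attr(map, "edge_fraction") <- mean(edge[rec])
  map
}

#' Plot a spatial category map
#'
#' Simple base-graphics rendering of the electrode grid with one colored
#' square per category, mirroring the polygonal activation diagrams used
#' for MEA slice maps.
#'
#' @param x a spatial map from [buildSpatialMap()].
#' @param ... ignored.
#' @export
plot.SpatialMap <- function(x, ...) {
  cols <- c(inactive = "grey90", activated_only = "steelblue",
            plasticity = "firebrick", recruited = "seagreen",
            silenced = "goldenrod", stimulation = "black")
  nR <- attr(x, "nRows") %||% (max(x$row) + 1L)
  graphics::plot(x$col, nR - 1 - x$row, pch = 22, cex = 3,
                 bg = cols[as.character(x$category)],
                 xlab = "column", ylab = "row", axes = FALSE,
                 main = attr(x, "slice_id"))
  graphics::axis(1); graphics::axis(2)
  graphics::legend("topright", legend = names(cols), pt.bg = cols,
                   pch = 22, cex = 0.7, bty = "n")
  invisible(x)
}
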