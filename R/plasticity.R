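## Plasticity quantification.
##
## Slopes are normalized per channel as a percentage of that channel's
## baseline mean; LTP/LTD is quantified as the mean normalized slope over
## the final 10 min of the recording (anchored to the recording end).
## Channel labels use configurable thresholds (potentiated >= 115%,
## depressed <= 85%); both the raw per-channel means and the labels are
## reported, since figure-level "channels with LTP" selections in the
## field rarely state their criterion.

#' Normalize slopes to the baseline level
#'
#' For every `active_stable` channel of a retained slice, divides each
#' sweep's slope by the channel's baseline mean slope and expresses it in
#' percent. Channels with a non-positive baseline mean are dropped; the
#' dropped ids and reasons are attached as attribute `dropped`.
#'
#' @param features feature table from [extractFeatures()].
#' @param qc the slice's [QCReport-class].
#' @param baselineMin baseline duration (min); defaults to the table's
#'   attribute.
#' @return data.frame `slice_id`, `channel_id`, `layer`, `sweep_index`,
#'   `time_min`, `phase`, `normalized_slope_pct`.
#' @export
normalizeToBaseline <- function(features, qc, baselineMin = NULL) {
  stopifnot(is(qc, "QCReport"))
  if (sliceExcluded(qc))
    stop(sprintf("slice %s is excluded by QC (%s)", qc@sliceId,
                 qc@exclusionReason))
  keep <- channelStatus(qc)$channel_id[
    channelStatus(qc)$status == "active_stable"]
  f <- features[features$channel_id %in% keep & features$pulse == 1L, ]
  isBase <- .baselineRows(f, baselineMin)
  bm <- tapply(f$slope_uV_per_ms[isBase], f$channel_id[isBase],
               mean, na.rm = TRUE)
  bad <- names(bm)[!is.finite(bm) | bm <= 0]
  bm <- bm[!names(bm) %in% bad]
  f <- f[f$channel_id %in% as.integer(names(bm)), ]
  f$normalized_slope_pct <-
    f$slope_uV_per_ms / as.numeric(bm[as.character(f$channel_id)]) * 100
  out <- f[, c("slice_id", "channel_id", "layer", "sweep_index",
               "time_min", "phase", "normalized_slope_pct")]
  rownames(out) <- NULL
  attr(out, "dropped") <-
    if (length(bad)) data.frame(channel_id = as.integer(bad),
                                reason = "non-positive baseline mean")
    else NULL
  attr(out, "baseline_min") <- baselineMin %||% attr(features, "baseline_min")
  out
}

#' Per-channel plasticity calls from the last recording window
#'
#' Averages each channel's normalized slope over the final `windowMin`
#' minutes of the recording and labels the channel `potentiated`
#' (mean >= `potThresholdPct`), `depressed` (mean <= `depThresholdPct`)
#' or `unchanged`.
#'
#' @param series normalized series from [normalizeToBaseline()].
#' @param windowMin last-window duration (min; default the final 10 min).
#' @param potThresholdPct,depThresholdPct label thresholds (% of
#'   baseline).
#' @return data.frame `slice_id`, `channel_id`, `layer`,
#'   `last_window_mean_pct`, `label`.
#' @seealso [layerSummary()] for the per-layer group mean.
#' @export
summarizeLastWindow <- function(series, windowMin = 10,
                                potThresholdPct = 115,
                                depThresholdPct = 85) {
  post <- series[!is.na(series$phase) & series$phase == "post", ]
  if (!nrow(post)) stop("no post-induction samples in series")
  span <- max(post$time_min) - min(post$time_min)
  if (span + 1e-9 < windowMin)
    stop(sprintf("post-induction span (%.1f min) shorter than the %g-min window",
                 span, windowMin))
  cut <- max(post$time_min) - windowMin
  w <- post[post$time_min > cut, ]
  mu <- tapply(w$normalized_slope_pct, w$channel_id, mean, na.rm = TRUE)
  ids <- as.integer(names(mu))
  gi <- match(ids, series$channel_id)
  out <- data.frame(slice_id = series$slice_id[gi],
                    channel_id = ids,
                    layer = series$layer[gi],
                    last_window_mean_pct = as.numeric(mu))
  out$label <- ifelse(out$last_window_mean_pct >= potThresholdPct,
                      "potentiated",
                      ifelse(out$last_window_mean_pct <= depThresholdPct,
                             "depressed", "unchanged"))
  out[order(out$channel_id), ]
}

#' Layer-level group summary of plasticity calls
#'
#' Mean and SEM of the last-window normalized slope over channels, per
#' layer (channels are the unit of analysis). Channels in `"outside"`
#' columns are excluded, as are any channel ids passed in `exclude`
#' (e.g. channels called silenced, which the silencing analysis reports
#' separately).
#'
#' @param calls output of [summarizeLastWindow()] (possibly several
#'   slices row-bound).
#' @param exclude channel key data.frame (`slice_id`, `channel_id`) or
#'   vector of channel ids to leave out.
#' @return data.frame `layer`, `n_channels`, `mean_pct`, `sem_pct`.
#' @export
layerSummary <- function(calls, exclude = NULL) {
  x <- calls[calls$layer %in% c("superficial", "deep"), ]
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) {
      key <- paste(x$slice_id, x$channel_id)
      x <- x[!key %in% paste(exclude$slice_id, exclude$channel_id), ]
    } else {
      x <- x[!x$channel_id %in% exclude, ]
    }
  }
  if (!nrow(x))
    return(data.frame(layer = character(), n_channels = integer(),
                      mean_pct = numeric(), sem_pct = numeric()))
  agg <- lapply(split(x$last_window_mean_pct, x$layer), function(v) {
    v <- v[is.finite(v)]
    c(n = length(v), mean = mean(v),
      sem = stats::sd(v) / sqrt(max(length(v), 1L)))
  })
  data.frame(layer = names(agg),
             n_channels = vapply(agg, `[[`, 0, "n"),
             mean_pct = vapply(agg, `[[`, 0, "mean"),
             sem_pct = vapply(agg, `[[`, 0, "sem"),
             row.names = NULL)
}

#' Paired-pulse ratios
#'
#' Computes `slope2 / slope1` per channel, sweep and interval from the
#' paired-pulse rows of a feature table, then averages per channel and
#' interval. Pairs whose first slope is missing or zero are flagged
#' unmeasurable and dropped from the averages.
#'
#' @param features feature table of a PPF bundle (two rows per channel
#'   and sweep, `pulse` 1 and 2).
#' @param intervals intervals to include (ms); default all present.
#' @param activatedOnly restrict to channels whose first-pulse amplitude
#'   median exceeds 10 uV (default `TRUE`).
#' @return data.frame `channel_id`, `layer`, `interval_ms`, `ppr`,
#'   `n_pairs`.
#' @export
computePPR <- function(features, intervals = NULL, activatedOnly = TRUE) {
  f <- features[!is.na(features$interval_ms), ]
  if (!nrow(f)) stop("no paired-pulse rows in feature table")
  if (is.null(intervals)) intervals <- sort(unique(f$interval_ms))
  f <- f[f$interval_ms %in% intervals, ]
  p1 <- f[f$pulse == 1L, ]
  p2 <- f[f$pulse == 2L, ]
  key <- function(d) paste(d$channel_id, d$sweep_index)
  i2 <- match(key(p1), key(p2))
  pairs <- data.frame(channel_id = p1$channel_id, layer = p1$layer,
                      interval_ms = p1$interval_ms,
                      slope1 = p1$slope_uV_per_ms,
                      slope2 = p2$slope_uV_per_ms[i2],
                      amp1 = p1$amplitude_uV)
  if (activatedOnly) {
    med <- tapply(pairs$amp1, pairs$channel_id, stats::median, na.rm = TRUE)
    act <- as.integer(names(med))[!is.na(med) & med > 10]
    pairs <- pairs[pairs$channel_id %in% act, ]
  }
  ok <- is.finite(pairs$slope1) & pairs$slope1 > 0 & is.finite(pairs$slope2)
  pairs$ppr <- ifelse(ok, pairs$slope2 / pairs$slope1, NA_real_)
  sp <- split(pairs, list(pairs$channel_id, pairs$interval_ms), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(channel_id = d$channel_id[1L], layer = d$layer[1L],
               interval_ms = d$interval_ms[1L],
               ppr = mean(d$ppr, na.rm = TRUE),
               n_pairs = sum(is.finite(d$ppr)))))
  out <- out[order(out$channel_id, out$interval_ms), ]
  rownames(out) <- NULL
  out
}

.finalWindowAmp <- function(features, postWindowMin) {
  post <- features[!is.na(features$phase) & features$phase == "post" &
                     features$pulse == 1L, ]
  cut <- max(post$time_min) - postWindowMin
  w <- post[post$time_min > cut, ]
  tapply(w$amplitude_uV, w$channel_id, stats::median, na.rm = TRUE)
}

.recruitmentFrame <- function(features, qc, thresholdUv, postWindowMin) {
  act <- classifyActivated(features, thresholdUv)
  fin <- .finalWindowAmp(features, postWindowMin)
  ids <- act$channel_id
  gi <- match(ids, features$channel_id)
  data.frame(slice_id = features$slice_id[gi],
             channel_id = ids,
             layer = features$layer[gi],
             baseline_amp_uV = act$baseline_median_amp_uV,
             post_window_amp_uV = as.numeric(fin[as.character(ids)]),
             activated = act$activated)
}

#' Detect recruited (unsilenced) channels after LTP induction
#'
#' A channel is recruited when it was not activated at baseline (median
#' baseline amplitude at or below the activation threshold, i.e. a
#' response of approximately 0 uV) and its median amplitude in the final
#' `postWindowMin` minutes exceeds the threshold.
#'
#' @param features feature table of a TBS (LTP) bundle.
#' @param qc the slice's [QCReport-class]; the slice must be retained.
#' @param thresholdUv activation threshold (uV).
#' @param postWindowMin final amplitude window (min).
#' @return data.frame `slice_id`, `channel_id`, `layer`,
#'   `baseline_amp_uV`, `post_window_amp_uV`, `recruited`, `silenced`.
#' @export
detectRecruited <- function(features, qc, thresholdUv = 10,
                            postWindowMin = 10) {
  stopifnot(is(qc, "QCReport"))
  if (sliceExcluded(qc)) stop("slice is excluded by QC")
  kind <- attr(features, "protocol_kind")
  if (!is.null(kind) && kind != "TBS_LTP")
    stop("recruitment detection requires a TBS_LTP protocol")
  d <- .recruitmentFrame(features, qc, thresholdUv, postWindowMin)
  d$recruited <- !d$activated & !is.na(d$post_window_amp_uV) &
    d$post_window_amp_uV > thresholdUv
  d$silenced <- FALSE
  d[, setdiff(names(d), "activated")]
}

#' Detect silenced channels after LTD induction
#'
#' A channel is silenced when it was activated at baseline and its median
#' amplitude in the final `postWindowMin` minutes has fallen to or below
#' the activation threshold (approximately 0 uV).
#'
#' @param features feature table of an LFS (LTD) bundle.
#' @inheritParams detectRecruited
#' @return as [detectRecruited()], with `silenced` filled.
#' @export
detectSilenced <- function(features, qc, thresholdUv = 10,
                           postWindowMin = 10) {
  stopifnot(is(qc, "QCReport"))
  if (sliceExcluded(qc)) stop("slice is excluded by QC")
  kind <- attr(features, "protocol_kind")
  if (!is.null(kind) && kind != "LFS_LTD")
    stop("silencing detection requires an LFS_LTD protocol")
  d <- .recruitmentFrame(features, qc, thresholdUv, postWindowMin)
  d$silenced <- d$activated & !is.na(d$post_window_amp_uV) &
    d$post_window_amp_uV <= thresholdUv
  d$recruited <- FALSE
  d[, setdiff(names(d), "activated")]
}
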