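## Channel and slice quality control.
##
## Activation: a channel is "activated" when its median baseline fEPSP
## amplitude is strictly above 10 uV. Stability: the coefficient of
## variation (population SD / mean) of the baseline slopes in the final
## 15-min baseline window must be strictly below 5%. A slice is excluded
## when more than 10% of its activated channels are unstable, or when it
## has no activated channel.

.baselineRows <- function(features, baselineMin = NULL) {
  if (!is.null(features$phase) && !all(is.na(features$phase)))
    return(features$phase == "baseline" & features$pulse == 1L)
  bl <- baselineMin %||% attr(features, "baseline_min")
  if (is.null(bl))
    stop("cannot identify baseline sweeps: no phase column or baseline_min")
  features$time_min <= bl & features$pulse == 1L
}

#' Classify activated channels
#'
#' A channel is activated when its median baseline amplitude is strictly
#' above `thresholdUv` (10 uV by default; "above" is a strict inequality,
#' so a median of exactly 10 uV is inactive).
#'
#' @param features feature table from [extractFeatures()].
#' @param thresholdUv activation threshold (uV).
#' @param baselineMin baseline duration (min); taken from the table's
#'   attributes when omitted.
#' @return data.frame `channel_id`, `baseline_median_amp_uV`, `activated`.
#' @export
classifyActivated <- function(features, thresholdUv = 10,
                              baselineMin = NULL) {
  if (!nrow(features)) stop("empty feature table")
  b <- features[.baselineRows(features, baselineMin), ]
  if (!nrow(b)) stop("no baseline sweeps in feature table")
  med <- tapply(b$amplitude_uV, b$channel_id, stats::median, na.rm = TRUE)
  data.frame(channel_id = as.integer(names(med)),
             baseline_median_amp_uV = as.numeric(med),
             activated = !is.na(med) & med > thresholdUv,
             row.names = NULL)
}

#' Assess baseline stability per channel
#'
#' The stability metric is the coefficient of variation (population SD /
#' mean) of the baseline slopes within the final `windowMin` minutes of
#' baseline; a channel is stable when the metric is strictly below
#' `cvLimit`. Channels with a non-positive or undefined mean slope are
#' flagged unstable with reason `"degenerate baseline"`.
#'
#' @inheritParams classifyActivated
#' @param windowMin stability window (min, counted back from the end of
#'   baseline).
#' @param cvLimit CV limit (fraction; default 0.05).
#' @return data.frame `channel_id`, `baseline_mean_slope`, `baseline_cv`,
#'   `stable`, `reason`.
#' @export
assessBaselineStability <- function(features, windowMin = 15,
                                    cvLimit = 0.05, baselineMin = NULL) {
  if (!nrow(features)) stop("empty feature table")
  bl <- baselineMin %||% attr(features, "baseline_min") %||%
    max(features$time_min[.baselineRows(features, baselineMin)])
  rows <- .baselineRows(features, bl) & features$time_min > bl - windowMin
  b <- features[rows, ]
  if (!nrow(b)) stop("baseline span shorter than the stability window")
  one <- function(x) {
    x <- x[is.finite(x)]
    m <- if (length(x)) mean(x) else NA_real_
    if (!length(x) || !is.finite(m) || m <= 0)
      return(c(mean = m, cv = NA_real_, stable = 0, degen = 1))
    cv <- sqrt(mean((x - m)^2)) / m
    c(mean = m, cv = cv, stable = as.numeric(cv < cvLimit), degen = 0)
  }
  st <- do.call(rbind, tapply(b$slope_uV_per_ms, b$channel_id, one))
  data.frame(channel_id = as.integer(rownames(st)),
             baseline_mean_slope = st[, "mean"],
             baseline_cv = st[, "cv"],
             stable = st[, "stable"] == 1,
             reason = ifelse(st[, "degen"] == 1, "degenerate baseline", ""),
             row.names = NULL)
}

#' Build the per-slice QC report
#'
#' Combines [classifyActivated()] and [assessBaselineStability()] into a
#' [QCReport-class] and applies the slice-exclusion rule via
#' [applySliceExclusion()].
#'
#' @inheritParams classifyActivated
#' @inheritParams assessBaselineStability
#' @param maxUnstableFrac maximum tolerated unstable fraction among
#'   activated channels (strictly above excludes; default 0.10).
#' @return A [QCReport-class].
#' @export
sliceQC <- function(features, thresholdUv = 10, windowMin = 15,
                    cvLimit = 0.05, maxUnstableFrac = 0.10,
                    baselineMin = NULL) {
  act <- classifyActivated(features, thresholdUv, baselineMin)
  stab <- assessBaselineStability(features, windowMin, cvLimit, baselineMin)
  cs <- merge(act, stab, by = "channel_id", all.x = TRUE)
  cs$status <- ifelse(!cs$activated, "inactive",
                      ifelse(!is.na(cs$stable) & cs$stable,
                             "active_stable", "active_unstable"))
  cs$reason[is.na(cs$reason)] <- ""
  cs <- cs[order(cs$channel_id),
           c("channel_id", "status", "baseline_median_amp_uV",
             "baseline_mean_slope", "baseline_cv", "reason")]
  rownames(cs) <- NULL
  nA <- sum(cs$status != "inactive")
  nU <- sum(cs$status == "active_unstable")
  rep <- new("QCReport",
             sliceId = features$slice_id[1L] %||% "slice",
             channelStatus = cs,
             nActive = nA, nUnstable = nU,
             unstableFraction = if (nA > 0L) nU / nA else 0,
             sliceExcluded = FALSE, exclusionReason = "")
  applySliceExclusion(rep, maxUnstableFrac)
}

#' Apply the slice-exclusion rule
#'
#' A slice is excluded when its unstable fraction is strictly above
#' `maxUnstableFrac` (a fraction of exactly 10% is retained), or when it
#' has no activated channel at all (no analyzable signal).
#'
#' @param report a [QCReport-class] with activation and stability filled.
#' @param maxUnstableFrac exclusion threshold (strictly above excludes).
#' @return The updated [QCReport-class].
#' @export
applySliceExclusion <- function(report, maxUnstableFrac = 0.10) {
  stopifnot(is(report, "QCReport"))
  if (report@nActive == 0L) {
    report@sliceExcluded <- TRUE
    report@exclusionReason <- "no active channels"
  } else if (report@unstableFraction > maxUnstableFrac) {
    report@sliceExcluded <- TRUE
    report@exclusionReason <- sprintf("unstable fraction %.1f%% > %.0f%%",
                                      100 * report@unstableFraction,
                                      100 * maxUnstableFrac)
  } else {
    report@sliceExcluded <- FALSE
    report@exclusionReason <- ""
  }
  report
}

#' Attach layer labels from a grid layout
#'
#' Overwrites/creates the `layer` column of a feature table from the
#' layout's column-to-layer map. Channels in `"outside"` columns are kept
#' in the table but excluded from layer summaries downstream.
#'
#' @param layout a [GridLayout-class].
#' @param features feature table with `channel_id`.
#' @return the feature table with `layer` (and `row`/`col`) set.
#' @export
assignLayers <- function(layout, features) {
  grid <- channelGrid(layout)
  gi <- match(features$channel_id, grid$channel_id)
  if (anyNA(gi)) stop("feature table contains channel ids not on the grid")
  features$row <- grid$row[gi]
  features$col <- grid$col[gi]
  features$layer <- grid$layer[gi]
  features
}

#' Calibrate stimulus intensity from an input-output curve
#'
#' Chooses the smallest tested intensity whose slope lies within
#' `[lo, hi]` of the maximum slope (the 40-60% band used to set the test
#' stimulus). If no intensity falls in the band, the intensity whose
#' fractional response is closest to the band midpoint is returned with a
#' warning.
#'
#' @param ioCurve data.frame with columns `intensity` and `slope`.
#' @param lo,hi band bounds as fractions of the maximum slope.
#' @return chosen intensity (scalar), with attribute `fraction` giving its
#'   fraction of the maximum slope.
#' @examples
#' calibrateStimIntensity(data.frame(intensity = c(.1, .2, .3, .4),
#'                                   slope = c(10, 30, 55, 100)))
#' @export
calibrateStimIntensity <- function(ioCurve, lo = 0.4, hi = 0.6) {
  stopifnot(is.data.frame(ioCurve),
            all(c("intensity", "slope") %in% names(ioCurve)))
  if (nrow(ioCurve) < 3L)
    stop("need at least 3 tested intensities")
  if (any(ioCurve$slope < 0, na.rm = TRUE))
    stop("slopes must be non-negative")
  mx <- max(ioCurve$slope, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("calibration error: input-output curve is all zero")
  frac <- ioCurve$slope / mx
  inBand <- which(frac >= lo & frac <= hi)
  if (length(inBand)) {
    i <- inBand[which.min(ioCurve$intensity[inBand])]
  } else {
    i <- which.min(abs(frac - (lo + hi) / 2))
    warning(sprintf(
      "no intensity in the %.0f-%.0f%% band; using %g (%.0f%% of max)",
      100 * lo, 100 * hi, ioCurve$intensity[i], 100 * frac[i]))
  }
  structure(ioCurve$intensity[i], fraction = frac[i])
}
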