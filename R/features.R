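## fEPSP feature extraction.
##
## Measurement conventions (all configurable):
##  * stimulus artifact blanked by linear interpolation over the first
##    blankMs after each stimulus onset;
##  * baseline voltage reference = mean of the 5 ms immediately before the
##    stimulus (robust to slow drift);
##  * traces are boxcar-smoothed (0.4 ms) before peak search and slope
##    fitting, which keeps single-sample noise out of the extreme-value
##    amplitude statistic and out of the regression window;
##  * amplitude = |most negative excursion from the baseline reference|
##    within 2-50 ms after the stimulus (negative-going convention,
##    magnitudes reported positive);
##  * slope = |least-squares line| through the smoothed samples between 20%
##    and 80% of the peak amplitude on the initial downstroke, in uV/ms.

.featureConfig <- function(blankMs = 1, searchMs = c(2, 50),
                           baselineRefMs = 5, smoothMs = 0.4,
                           fracLo = 0.2, fracHi = 0.8,
                           tailFitFromMs = 12) {
  stopifnot(blankMs >= 0, length(searchMs) == 2L, searchMs[1] < searchMs[2],
            fracLo >= 0, fracLo < fracHi, fracHi <= 1)
  list(blankMs = blankMs, searchMs = searchMs, baselineRefMs = baselineRefMs,
       smoothMs = smoothMs, fracLo = fracLo, fracHi = fracHi,
       tailFitFromMs = tailFitFromMs)
}

.degenerateWindow <- function(msg, window) {
  stop(structure(class = c("degenerateWindowError", "error", "condition"),
                 list(message = sprintf("%s [window: %s]", msg,
                                        paste(signif(window, 4), collapse = ", ")),
                      call = sys.call(-1), window = window)))
}

## blank [onset, onset + blankMs] (0-based onset) by linear interpolation
.blankVec <- function(x, onset, khz, blankMs) {
  if (blankMs == 0) return(x)
  nb <- as.integer(round(blankMs * khz))
  p0 <- onset + 1L                      # 1-based stimulus sample
  p1 <- p0 + nb
  if (p1 > length(x))
    stop("blank window exceeds the trace")
  vL <- if (p0 > 1L) x[p0 - 1L] else x[p1]
  vR <- x[p1]
  w <- seq_len(p1 - p0 + 1L) / (p1 - p0 + 1L)
  x[p0:p1] <- vL + (vR - vL) * w
  x
}

## matrix version: traces in columns, shared onset
.blankMat <- function(X, onset, khz, blankMs) {
  if (blankMs == 0) return(X)
  nb <- as.integer(round(blankMs * khz))
  p0 <- onset + 1L
  p1 <- p0 + nb
  if (p1 > nrow(X)) stop("blank window exceeds the trace")
  vL <- if (p0 > 1L) X[p0 - 1L, ] else X[p1, ]
  vR <- X[p1, ]
  w <- seq_len(p1 - p0 + 1L) / (p1 - p0 + 1L)
  X[p0:p1, ] <- outer(w, vR - vL) + rep(vL, each = p1 - p0 + 1L)
  X
}

.smoothMat <- function(X, khz, smoothMs) {
  w <- as.integer(round(smoothMs * khz))
  if (w <= 1L) return(X)
  if (w %% 2L == 0L) w <- w + 1L
  Xs <- stats::filter(X, rep(1 / w, w), sides = 2)
  ## stats::filter leaves NA margins; fall back to the raw samples there
  h <- (w - 1L) %/% 2L
  n <- nrow(X)
  edge <- c(seq_len(h), seq.int(n - h + 1L, n))
  Xs[edge, ] <- X[edge, ]
  matrix(Xs, nrow = n, dimnames = dimnames(X))
}

## Measure amplitude/slope for every column of a samples x sweeps matrix.
## onset is 0-based; searchMs relative to the stimulus. Returns a
## data.frame with one row per column; failures yield NA + flag.
.measureMatrix <- function(X, onset, khz, cfg, blank = TRUE) {
  n <- nrow(X); nS <- ncol(X)
  if (blank) X <- .blankMat(X, onset, khz, cfg$blankMs)
  bLo <- max(1L, onset + 1L - as.integer(round(cfg$baselineRefMs * khz)))
  bHi <- max(1L, onset)
  baseRef <- colMeans(X[bLo:bHi, , drop = FALSE])
  Xs <- .smoothMat(X, khz, cfg$smoothMs)
  sLo <- onset + 1L + as.integer(ceiling(cfg$searchMs[1] * khz))
  sHi <- min(n, onset + 1L + as.integer(floor(cfg$searchMs[2] * khz)))
  if (sLo >= sHi)
    .degenerateWindow("empty amplitude search window", cfg$searchMs)
  D <- rep(baseRef, each = n) - Xs      # depth: positive = negative-going
  sub <- D[sLo:sHi, , drop = FALSE]
  ipkRel <- max.col(t(sub), ties.method = "first")
  amp <- sub[cbind(ipkRel, seq_len(nS))]
  ipkAbs <- sLo + ipkRel - 1L

  slope <- rep(NA_real_, nS); r2 <- rep(NA_real_, nS)
  flag <- character(nS)
  for (s in seq_len(nS)) {
    if (!is.finite(amp[s]) || amp[s] <= 0) {
      flag[s] <- "no negative-going response"
      next
    }
    seg <- sLo:ipkAbs[s]
    d <- D[seg, s]
    lo <- cfg$fracLo * amp[s]; hi <- cfg$fracHi * amp[s]
    belowLo <- which(d <= lo)
    belowHi <- which(d <= hi)
    if (!length(belowLo) || !length(belowHi) ||
        max(belowLo) >= length(seg) || max(belowHi) >= length(seg)) {
      flag[s] <- "slope window not resolvable"
      next
    }
    iLo <- max(belowLo); iHi <- max(belowHi)
    ## sub-sample crossing times by linear interpolation on the smoothed
    ## depth, so the fit window does not jitter on the sample grid
    tOf <- function(i) (seg[i] - 1L - onset) / khz
    crossT <- function(i, level) {
      d0 <- d[i]; d1 <- d[i + 1L]
      frac <- if (d1 != d0) (level - d0) / (d1 - d0) else 0
      tOf(i) + frac / khz
    }
    tLo <- crossT(iLo, lo); tHi <- crossT(iHi, hi)
    if (!(tHi > tLo)) {
      flag[s] <- "degenerate slope window"
      next
    }
    inner <- seg[(iLo + 1L):iHi]
    tIn <- (inner - 1L - onset) / khz
    keep <- tIn > tLo & tIn < tHi
    tms <- c(tLo, tIn[keep], tHi)
    y <- c(lo, D[inner[keep], s], hi)
    if (length(tms) < 3L) {
      flag[s] <- "degenerate slope window"
      next
    }
    ft <- stats::.lm.fit(cbind(1, tms), y)
    slope[s] <- abs(ft$coefficients[2L])
    ssT <- sum((y - mean(y))^2)
    r2[s] <- if (ssT > 0) 1 - sum(ft$residuals^2) / ssT else NA_real_
  }
  data.frame(amplitude_uV = amp, slope_uV_per_ms = slope, fit_r2 = r2,
             flag = flag)
}

#' Blank the stimulus artifact
#'
#' Replaces the samples within `blankMs` after each stimulus onset by
#' linear interpolation across the blank window.
#'
#' @param trace a [FEPSPTrace-class].
#' @param blankMs blank duration (ms, >= 0).
#' @return The blanked [FEPSPTrace-class].
#' @export
setGeneric("blankArtifact", function(trace, blankMs = 1)
  standardGeneric("blankArtifact"))

#' @rdname blankArtifact
#' @export
setMethod("blankArtifact", "FEPSPTrace", function(trace, blankMs = 1) {
  stopifnot(blankMs >= 0)
  x <- trace@samples
  for (on in trace@stimOnsetSample)
    x <- .blankVec(x, on, trace@samplingKhz, blankMs)
  fepspTrace(x, trace@samplingKhz, trace@stimOnsetSample)
})

#' Measure fEPSP amplitude
#'
#' Amplitude is the magnitude of the most negative excursion from the
#' pre-stimulus baseline mean within the search window (default 2-50 ms
#' after the stimulus), measured on the lightly smoothed trace.
#'
#' @param trace a [FEPSPTrace-class] (artifact should be blanked first;
#'   see [blankArtifact()]).
#' @param searchMs search window `c(from, to)` in ms post-stimulus.
#' @param baselineRefMs pre-stimulus baseline reference duration (ms).
#' @param smoothMs boxcar smoothing width (ms; 0 disables).
#' @return amplitude in uV (positive for a negative-going response).
#' @export
setGeneric("measureAmplitude",
  function(trace, searchMs = c(2, 50), baselineRefMs = 5, smoothMs = 0.4)
    standardGeneric("measureAmplitude"))

#' @rdname measureAmplitude
#' @export
setMethod("measureAmplitude", "FEPSPTrace",
  function(trace, searchMs = c(2, 50), baselineRefMs = 5, smoothMs = 0.4) {
    cfg <- .featureConfig(blankMs = 0, searchMs = searchMs,
                          baselineRefMs = baselineRefMs, smoothMs = smoothMs)
    X <- matrix(trace@samples, ncol = 1L)
    .measureMatrix(X, trace@stimOnsetSample[1L], trace@samplingKhz, cfg,
                   blank = FALSE)$amplitude_uV
  })

#' Measure fEPSP slope
#'
#' Fits a least-squares line to the smoothed samples between `fracLo` and
#' `fracHi` of the peak amplitude on the initial downstroke and reports
#' its magnitude in uV/ms.
#'
#' @inheritParams measureAmplitude
#' @param fracLo,fracHi window bounds as fractions of peak amplitude
#'   (defaults 0.2 and 0.8).
#' @return list with `slope_uV_per_ms`, `window` (start/end, ms
#'   post-stimulus) and `fit_r2`.
#' @export
setGeneric("measureSlope",
  function(trace, fracLo = 0.2, fracHi = 0.8, searchMs = c(2, 50),
           baselineRefMs = 5, smoothMs = 0.4)
    standardGeneric("measureSlope"))

#' @rdname measureSlope
#' @export
setMethod("measureSlope", "FEPSPTrace",
  function(trace, fracLo = 0.2, fracHi = 0.8, searchMs = c(2, 50),
           baselineRefMs = 5, smoothMs = 0.4) {
    cfg <- .featureConfig(blankMs = 0, searchMs = searchMs,
                          baselineRefMs = baselineRefMs, smoothMs = smoothMs,
                          fracLo = fracLo, fracHi = fracHi)
    X <- matrix(trace@samples, ncol = 1L)
    res <- .measureMatrix(X, trace@stimOnsetSample[1L], trace@samplingKhz,
                          cfg, blank = FALSE)
    if (is.na(res$slope_uV_per_ms))
      .degenerateWindow(res$flag, c(fracLo, fracHi))
    list(slope_uV_per_ms = res$slope_uV_per_ms,
         window = c(fracLo, fracHi), fit_r2 = res$fit_r2)
  })

## exponential tail of the first paired-pulse response, extrapolated and
## subtracted so the second response is measured against the inter-pulse
## voltage rather than the decaying tail of the first
.subtractTail <- function(x, xs, baseRef, onset1, onset2, khz, cfg, amp1) {
  fLo <- onset1 + 1L + as.integer(round(cfg$tailFitFromMs * khz))
  fHi <- onset2 - as.integer(round(0.5 * khz))
  if (fHi - fLo < 8L || !is.finite(amp1) || amp1 <= 0) return(x)
  idx <- fLo:fHi
  d <- baseRef - xs[idx]
  keep <- d > pmax(0.5, 0.02 * amp1)
  if (sum(keep) < 8L) return(x)
  tms <- (idx[keep] - 1L - onset1) / khz
  ft <- stats::.lm.fit(cbind(1, tms), log(d[keep]))
  if (ft$coefficients[2L] >= 0) return(x)
  ## remove the tail from the fit window onward, so the second response's
  ## own pre-stimulus baseline region is corrected too
  tAll <- (seq_along(x) - 1L - onset1) / khz
  post <- seq_along(x) >= fLo
  x[post] <- x[post] + exp(ft$coefficients[1L] + ft$coefficients[2L] * tAll[post])
  x
}

#' Extract per-sweep, per-channel fEPSP features from a bundle
#'
#' Produces the tidy feature table driving all downstream analysis: one
#' row per channel and sweep (two rows - one per pulse - for paired-pulse
#' sweeps). Per-trace measurement failures are flagged in the `flag`
#' column with amplitude/slope set to `NA`; they never abort the slice.
#' For paired-pulse sweeps the extrapolated exponential tail of the first
#' response is subtracted before the second response is measured, so short
#' intervals do not inflate the ratio.
#'
#' @param bundle a [SliceBundle-class].
#' @param blankMs artifact blank duration (ms).
#' @param searchMs amplitude search window (ms post-stimulus).
#' @param baselineRefMs pre-stimulus baseline reference (ms).
#' @param smoothMs boxcar smoothing width (ms).
#' @param fracLo,fracHi slope window as fractions of peak amplitude.
#' @return data.frame with columns `slice_id`, `mouse_id`, `condition`,
#'   `channel_id`, `row`, `col`, `layer`, `sweep_index`, `time_min`,
#'   `phase` (`baseline`/`post`, `NA` for PPF/IO), `pulse`, `interval_ms`,
#'   `intensity_ma`, `amplitude_uV`, `slope_uV_per_ms`, `fit_r2`, `flag`.
#'   Attributes `protocol_kind`, `baseline_min`, `sample_period_min` carry
#'   the protocol context.
#' @export
extractFeatures <- function(bundle, blankMs = 1, searchMs = c(2, 50),
                            baselineRefMs = 5, smoothMs = 0.4,
                            fracLo = 0.2, fracHi = 0.8) {
  stopifnot(is(bundle, "SliceBundle"))
  cfg <- .featureConfig(blankMs = blankMs, searchMs = searchMs,
                        baselineRefMs = baselineRefMs, smoothMs = smoothMs,
                        fracLo = fracLo, fracHi = fracHi)
  proto <- bundle@protocol
  grid <- channelGrid(bundle@layout)
  khz <- bundle@waveform@samplingKhz
  onset <- bundle@stimOnsetSample
  info <- bundle@sweepInfo
  nCh <- nrow(grid); nSw <- nrow(info)

  perChannel <- vector("list", nCh)
  for (ch in seq_len(nCh)) {
    X <- bundle@traces[ch, , , drop = TRUE]
    if (nSw == 1L) X <- matrix(X, ncol = 1L)
    if (proto@kind == "PPF") {
      perChannel[[ch]] <- .extractPPFChannel(X, info, onset, khz, cfg)
    } else {
      res <- tryCatch(.measureMatrix(X, onset, khz, cfg),
                      error = function(e)
                        data.frame(amplitude_uV = NA_real_,
                                   slope_uV_per_ms = NA_real_,
                                   fit_r2 = NA_real_,
                                   flag = conditionMessage(e))[rep(1L, nSw), ])
      bad <- !apply(is.finite(X), 2L, all)
      if (any(bad)) {
        res$amplitude_uV[bad] <- NA_real_
        res$slope_uV_per_ms[bad] <- NA_real_
        res$flag[bad] <- "corrupt sweep"
      }
      res$pulse <- 1L
      res$sweep_index <- info$sweep_index
      perChannel[[ch]] <- res
    }
  }
  rowsPer <- nrow(perChannel[[1L]])
  out <- do.call(rbind, perChannel)
  out$channel_id <- rep(grid$channel_id, each = rowsPer)
  gi <- match(out$channel_id, grid$channel_id)
  out$row <- grid$row[gi]; out$col <- grid$col[gi]
  out$layer <- grid$layer[gi]
  si <- match(out$sweep_index, info$sweep_index)
  out$time_min <- info$time_min[si]
  out$interval_ms <- info$interval_ms[si]
  out$intensity_ma <- info$intensity_ma[si]
  out$slice_id <- bundle@sliceId
  out$mouse_id <- bundle@mouseId
  out$condition <- bundle@condition
  out$phase <- if (proto@kind %in% c("TBS_LTP", "LFS_LTD"))
    ifelse(out$time_min <= proto@baselineMin, "baseline", "post")
  else NA_character_
  out <- out[order(out$channel_id, out$sweep_index, out$pulse),
             c("slice_id", "mouse_id", "condition", "channel_id", "row",
               "col", "layer", "sweep_index", "time_min", "phase", "pulse",
               "interval_ms", "intensity_ma", "amplitude_uV",
               "slope_uV_per_ms", "fit_r2", "flag")]
  rownames(out) <- NULL
  attr(out, "protocol_kind") <- proto@kind
  attr(out, "baseline_min") <- proto@baselineMin
  attr(out, "sample_period_min") <- proto@samplePeriodMin
  attr(out, "post_min") <- proto@postMin
  out
}

## paired-pulse: measure pulse 1 (search confined before pulse 2), subtract
## the extrapolated tail, then measure pulse 2 against its own baseline
.extractPPFChannel <- function(X, info, onset1, khz, cfg) {
  nSw <- nrow(info)
  res <- vector("list", nSw)
  for (s in seq_len(nSw)) {
    iv <- info$interval_ms[s]
    onset2 <- onset1 + as.integer(round(iv * khz))
    x <- X[, s]
    row1 <- row2 <- data.frame(amplitude_uV = NA_real_,
                               slope_uV_per_ms = NA_real_,
                               fit_r2 = NA_real_, flag = "corrupt sweep")
    if (all(is.finite(x))) {
      x <- .blankVec(x, onset1, khz, cfg$blankMs)
      x <- .blankVec(x, onset2, khz, cfg$blankMs)
      cfg1 <- cfg
      cfg1$searchMs <- c(cfg$searchMs[1], min(cfg$searchMs[2], iv - 0.5))
      cfg1$blankMs <- 0
      row1 <- .measureMatrix(matrix(x, ncol = 1L), onset1, khz, cfg1,
                             blank = FALSE)
      xs <- boxcarSmooth(x, as.integer(round(cfg$smoothMs * khz)))
      bLo <- max(1L, onset1 + 1L - as.integer(round(cfg$baselineRefMs * khz)))
      baseRef <- mean(x[bLo:onset1])
      xc <- .subtractTail(x, xs, baseRef, onset1, onset2, khz, cfg,
                          row1$amplitude_uV)
      cfg2 <- cfg; cfg2$blankMs <- 0
      row2 <- .measureMatrix(matrix(xc, ncol = 1L), onset2, khz, cfg2,
                             blank = FALSE)
    }
    both <- rbind(row1, row2)
    both$pulse <- c(1L, 2L)
    both$sweep_index <- info$sweep_index[s]
    res[[s]] <- both
  }
  do.call(rbind, res)
}
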