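## Synthetic 8x8-grid slice-recording generator.
##
## A sweep is modelled as: biphasic stimulus artifact at the stimulus onset,
## then (after a synaptic latency) a negative-going dual-exponential fEPSP
## whose peak magnitude carries all the signal, plus white Gaussian noise.
## Plasticity scales the per-channel amplitude by
##   m(t) = 1 + (plateau - 1) * (1 - exp(-(t - t0)/tau))       (t > t0)
## so the mean of m over the last 10 min of a 60-min post-induction
## recording equals the plateau to ~1e-5.

## unit-amplitude (peak magnitude 1) negative fEPSP starting latency after
## the stimulus onset; vector over nSamples
.fepspKernel <- function(params, nSamples, onsetSample) {
  khz <- params@samplingKhz
  tr <- params@tauRiseMs; td <- params@tauDecayMs
  t <- (seq_len(nSamples) - 1L - onsetSample) / khz - params@latencyMs
  g <- numeric(nSamples)
  pos <- t > 0
  g[pos] <- exp(-t[pos] / td) - exp(-t[pos] / tr)
  tPeak <- tr * td / (td - tr) * log(td / tr)
  gMax <- exp(-tPeak / td) - exp(-tPeak / tr)
  -g / gMax
}

## biphasic rectangular stimulus artifact
.artifactVec <- function(params, nSamples, onsetSample) {
  khz <- params@samplingKhz
  a <- numeric(nSamples)
  half <- max(1L, round(params@artifactWidthMs / 2 * khz))
  i1 <- onsetSample + seq_len(half)
  i2 <- onsetSample + half + seq_len(half)
  a[i1[i1 <= nSamples]] <- params@artifactAmpUv
  a[i2[i2 <= nSamples]] <- -params@artifactAmpUv
  a
}

## analytic time of the fEPSP peak, ms after the *stimulus* onset
.fepspPeakTimeMs <- function(params) {
  tr <- params@tauRiseMs; td <- params@tauDecayMs
  params@latencyMs + tr * td / (td - tr) * log(td / tr)
}

#' Simulate a single evoked fEPSP trace
#'
#' Generates one synthetic trace: biphasic stimulus artifact at the onset,
#' a negative-going dual-exponential fEPSP of peak magnitude `peakAmp`
#' beginning one synaptic latency later, and additive Gaussian noise drawn
#' from the current RNG state.
#'
#' @param params a [WaveformParams-class].
#' @param peakAmp fEPSP peak magnitude (uV, non-negative).
#' @return A [FEPSPTrace-class] with the stimulus onset marked.
#' @examples
#' set.seed(1)
#' tr <- simulateWaveform(waveformParams(noiseSdUv = 0), peakAmp = 50)
#' min(tr@samples)
#' @export
simulateWaveform <- function(params, peakAmp) {
  stopifnot(is(params, "WaveformParams"))
  if (params@samplingKhz <= 0)
    stop("samplingKhz must be positive")
  khz <- params@samplingKhz
  nSamples <- as.integer(round((params@preMs + params@postMs) * khz))
  onset <- as.integer(round(params@preMs * khz))
  x <- peakAmp * .fepspKernel(params, nSamples, onset) +
    .artifactVec(params, nSamples, onset)
  if (params@noiseSdUv > 0)
    x <- x + stats::rnorm(nSamples, 0, params@noiseSdUv)
  fepspTrace(x, khz, onset)
}

## sweep time grid and induction time for a plasticity protocol
.sweepTimes <- function(protocol) {
  seq(protocol@samplePeriodMin, protocol@baselineMin + protocol@postMin,
      by = protocol@samplePeriodMin)
}

#' Plasticity multiplier m(t)
#'
#' The amplitude multiplier applied to a channel's baseline response:
#' 1 before induction, then an exponential approach to `plateau`.
#'
#' @param timeMin recording times (min).
#' @param kinetics a [PlasticityKinetics-class].
#' @param inductionMin induction time (min).
#' @return numeric vector of multipliers.
#' @export
plasticityMultiplier <- function(timeMin, kinetics, inductionMin) {
  m <- rep(1, length(timeMin))
  post <- timeMin > inductionMin
  m[post] <- 1 + (kinetics@plateau - 1) *
    (1 - exp(-(timeMin[post] - inductionMin) / kinetics@tauPlasticityMin))
  m
}

#' Simulate the sweep series of one channel through a plasticity protocol
#'
#' One evoked trace per sample time (every `samplePeriodMin` minutes):
#' pre-induction traces at `channelAmp`, post-induction traces scaled by
#' the plasticity multiplier of `kinetics`.
#'
#' @param channelAmp baseline fEPSP peak magnitude (uV).
#' @param kinetics a [PlasticityKinetics-class] (its `channelSd` is not
#'   used here: the plateau is taken as this channel's own).
#' @param protocol a [ProtocolSpec-class] of kind `"TBS_LTP"` or
#'   `"LFS_LTD"`.
#' @param params a [WaveformParams-class].
#' @return list with `timeMin`, `multiplier`, and `traces` (matrix
#'   `[nSamples, nSweeps]`, uV) plus `stimOnsetSample` (0-based).
#' @export
simulateSweepSeries <- function(channelAmp, kinetics, protocol,
                                params = waveformParams()) {
  stopifnot(is(kinetics, "PlasticityKinetics"), is(protocol, "ProtocolSpec"))
  if (!protocol@kind %in% c("TBS_LTP", "LFS_LTD"))
    stop("simulateSweepSeries requires a TBS_LTP or LFS_LTD protocol")
  times <- .sweepTimes(protocol)
  m <- plasticityMultiplier(times, kinetics, protocol@baselineMin)
  khz <- params@samplingKhz
  nSamples <- as.integer(round((params@preMs + params@postMs) * khz))
  onset <- as.integer(round(params@preMs * khz))
  kern <- .fepspKernel(params, nSamples, onset)
  art <- .artifactVec(params, nSamples, onset)
  tr <- outer(kern, channelAmp * m) + art
  if (params@noiseSdUv > 0)
    tr <- tr + matrix(stats::rnorm(length(tr), 0, params@noiseSdUv),
                      nrow = nSamples)
  list(timeMin = times, multiplier = m, traces = tr,
       stimOnsetSample = onset)
}

## integer count with the given expectation: floor + Bernoulli remainder
.expectedCount <- function(m) {
  k <- floor(m)
  as.integer(k + stats::rbinom(1L, 1L, m - k))
}

#' Simulate one slice-recording bundle
#'
#' Builds a full synthetic [SliceBundle-class] under a condition preset:
#' channels around the stimulation electrode respond with amplitudes
#' decaying exponentially with grid distance (truncated to 0 below the
#' preset's `activeMinUv`); per-channel plasticity plateaus are drawn from
#' `Normal(layer plateau, channelSd)`; recruited channels (0 uV at
#' baseline, rising to the preset amplitude after TBS) are placed on the
#' edge of the activated area; silenced channels (LFS only) are activated
#' channels whose response decays to ~0. The generative ground truth is
#' stored in the bundle's `truth` slot.
#'
#' @param preset a [ConditionPreset-class].
#' @param protocol a [ProtocolSpec-class] (`"TBS_LTP"`, `"LFS_LTD"`,
#'   `"PPF"` or `"IO"`).
#' @param layout a [GridLayout-class].
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @param params a [WaveformParams-class].
#' @param sliceId,mouseId identifiers.
#' @return A [SliceBundle-class] with truth attached.
#' @examples
#' b <- simulateSlice(conditionPreset("observer"),
#'                    protocolSpec("TBS_LTP", baselineMin = 2, postMin = 4),
#'                    seed = 1)
#' b
#' @export
simulateSlice <- function(preset, protocol = protocolSpec("TBS_LTP"),
                          layout = gridLayout(), seed = NULL,
                          params = waveformParams(),
                          sliceId = paste0(preset@condition, "_slice"),
                          mouseId = paste0(preset@condition, "_mouse")) {
  stopifnot(is(preset, "ConditionPreset"), is(protocol, "ProtocolSpec"),
            is(layout, "GridLayout"))
  if (!is.null(seed)) set.seed(seed)
  grid <- channelGrid(layout)
  nCh <- nrow(grid)

  ## baseline amplitude field: radial decay, truncated below activeMinUv
  amp0 <- preset@peakAmpUv * exp(-grid$dist_um / params@decayLengthUm)
  active <- amp0 >= preset@activeMinUv
  amp0[!active] <- 0

  truth <- data.frame(grid,
                      active = active, baseline_amp_uV = amp0,
                      plateau = NA_real_, recruited = FALSE,
                      silenced = FALSE, recruited_amp_uV = NA_real_)

  if (protocol@kind %in% c("TBS_LTP", "LFS_LTD")) {
    bundle <- .simulatePlasticitySlice(preset, protocol, layout, params,
                                       grid, truth, sliceId, mouseId)
  } else if (protocol@kind == "PPF") {
    bundle <- .simulatePPFSlice(preset, protocol, layout, params,
                                grid, truth, sliceId, mouseId)
  } else {
    bundle <- .simulateIOSlice(preset, protocol, layout, params,
                               grid, truth, sliceId, mouseId)
  }
  bundle
}

.simulatePlasticitySlice <- function(preset, protocol, layout, params,
                                     grid, truth, sliceId, mouseId) {
  isLTP <- protocol@kind == "TBS_LTP"
  platePct <- if (isLTP) preset@ltpPlateauPct else preset@ltdPlateauPct
  times <- .sweepTimes(protocol)
  t0 <- protocol@baselineMin
  nSweeps <- length(times)
  khz <- params@samplingKhz
  nSamples <- as.integer(round((params@preMs + params@postMs) * khz))
  onset <- as.integer(round(params@preMs * khz))
  nCh <- nrow(grid)

  ## per-channel plateaus for active channels (analysed layers only get
  ## preset means; "outside" columns inherit the deep value so every
  ## active channel has a defined time course)
  plateau <- rep(NA_real_, nCh)
  act <- which(truth$active)
  layFor <- function(l) ifelse(l == "superficial", "superficial", "deep")
  plateau[act] <- stats::rnorm(length(act),
                               platePct[layFor(grid$layer[act])] / 100,
                               preset@channelSd)
  plateau[act] <- pmax(plateau[act], 0.05)

  ## silenced channels (LFS): edge-biased draw from active, non-stim cells
  if (!isLTP) {
    for (lay in c("superficial", "deep")) {
      k <- .expectedCount(preset@nSilenced[[lay]])
      cand <- act[grid$layer[act] == lay & !grid$is_stim[act]]
      if (k > 0L && length(cand) > 0L) {
        cand <- cand[order(-grid$dist_um[cand])]
        pool <- cand[seq_len(min(length(cand), max(k, ceiling(length(cand) / 2))))]
        sel <- pool[sample.int(length(pool), min(k, length(pool)))]
        truth$silenced[sel] <- TRUE
        plateau[sel] <- 0       # response decays to ~0 uV
      }
    }
  }

  ## recruited channels (TBS): inactive cells adjacent to the activated set
  if (isLTP) {
    activeSet <- which(truth$active)
    adj <- vapply(seq_len(nCh), function(i) {
      if (truth$active[i]) return(FALSE)
      nb <- gridNeighbors(grid$row[i], grid$col[i],
                          layout@nRows, layout@nCols)
      any(nb$ids %in% activeSet)
    }, logical(1L))
    for (lay in c("superficial", "deep")) {
      k <- .expectedCount(preset@nRecruited[[lay]])
      cand <- which(adj & grid$layer == lay)
      if (k > 0L && length(cand) > 0L) {
        sel <- cand[sample.int(length(cand), min(k, length(cand)))]
        truth$recruited[sel] <- TRUE
        truth$recruited_amp_uV[sel] <- preset@recruitedAmpUv[[lay]]
      }
    }
  }
  truth$plateau <- plateau

  ## amplitude time course per channel
  kern <- .fepspKernel(params, nSamples, onset)
  art <- .artifactVec(params, nSamples, onset)
  post <- times > t0
  tau <- preset@tauPlasticityMin
  traces <- array(0, dim = c(nCh, nSamples, nSweeps))
  for (ch in seq_len(nCh)) {
    ampT <- rep(truth$baseline_amp_uV[ch], nSweeps)
    if (!is.na(plateau[ch])) {
      m <- rep(1, nSweeps)
      m[post] <- 1 + (plateau[ch] - 1) * (1 - exp(-(times[post] - t0) / tau))
      ampT <- ampT * m
    }
    if (truth$recruited[ch]) {
      ampT[post] <- truth$recruited_amp_uV[ch] *
        (1 - exp(-(times[post] - t0) / tau))
    }
    tr <- outer(kern, ampT) + art
    if (params@noiseSdUv > 0)
      tr <- tr + stats::rnorm(length(tr), 0, params@noiseSdUv)
    traces[ch, , ] <- tr
  }

  sweepInfo <- data.frame(sweep_index = seq_len(nSweeps) - 1L,
                          time_min = times,
                          interval_ms = NA_real_, intensity_ma = NA_real_)
  new("SliceBundle", sliceId = sliceId, mouseId = mouseId,
      condition = preset@condition, layout = layout, protocol = protocol,
      waveform = params, traces = traces, sweepInfo = sweepInfo,
      stimOnsetSample = onset, truth = truth)
}

.simulatePPFSlice <- function(preset, protocol, layout, params,
                              grid, truth, sliceId, mouseId) {
  ivs <- protocol@ppfIntervalsMs
  reps <- protocol@ppfRepeats
  sweepIv <- rep(ivs, times = reps)
  nSweeps <- length(sweepIv)
  khz <- params@samplingKhz
  nSamples <- as.integer(round((params@preMs + max(ivs) + params@postMs) * khz))
  onset1 <- as.integer(round(params@preMs * khz))
  nCh <- nrow(grid)

  facil <- preset@pprCurve[as.character(ivs)]
  if (anyNA(facil))
    stop("preset pprCurve does not cover all protocol intervals")

  ## per-interval composite kernel: pulse 1 + facilitation * pulse 2
  base <- lapply(seq_along(ivs), function(j) {
    on2 <- onset1 + as.integer(round(ivs[j] * khz))
    k <- .fepspKernel(params, nSamples, onset1) +
      facil[j] * .fepspKernel(params, nSamples, on2)
    a <- .artifactVec(params, nSamples, onset1) +
      .artifactVec(params, nSamples, on2)
    list(kernel = k, artifact = a, onset2 = on2)
  })
  names(base) <- as.character(ivs)

  traces <- array(0, dim = c(nCh, nSamples, nSweeps))
  for (s in seq_len(nSweeps)) {
    b <- base[[as.character(sweepIv[s])]]
    m <- outer(truth$baseline_amp_uV, b$kernel) +
      matrix(b$artifact, nrow = nCh, ncol = nSamples, byrow = TRUE)
    if (params@noiseSdUv > 0)
      m <- m + stats::rnorm(length(m), 0, params@noiseSdUv)
    traces[, , s] <- m
  }
  sweepInfo <- data.frame(sweep_index = seq_len(nSweeps) - 1L,
                          time_min = seq_len(nSweeps) * protocol@samplePeriodMin,
                          interval_ms = sweepIv, intensity_ma = NA_real_)
  new("SliceBundle", sliceId = sliceId, mouseId = mouseId,
      condition = preset@condition, layout = layout, protocol = protocol,
      waveform = params, traces = traces, sweepInfo = sweepInfo,
      stimOnsetSample = onset1, truth = truth)
}

.simulateIOSlice <- function(preset, protocol, layout, params,
                             grid, truth, sliceId, mouseId) {
  ints <- protocol@ioIntensitiesMa
  nSweeps <- length(ints)
  khz <- params@samplingKhz
  nSamples <- as.integer(round((params@preMs + params@postMs) * khz))
  onset <- as.integer(round(params@preMs * khz))
  nCh <- nrow(grid)
  ## saturating (Hill, n = 2) stimulus-response scaling, 1 at max intensity
  hill <- function(i) i^2 / (i^2 + 0.35^2)
  scale <- hill(ints) / hill(max(ints))
  kern <- .fepspKernel(params, nSamples, onset)
  art <- .artifactVec(params, nSamples, onset)
  traces <- array(0, dim = c(nCh, nSamples, nSweeps))
  for (s in seq_len(nSweeps)) {
    m <- outer(truth$baseline_amp_uV * scale[s], kern) +
      matrix(art, nrow = nCh, ncol = nSamples, byrow = TRUE)
    if (params@noiseSdUv > 0)
      m <- m + stats::rnorm(length(m), 0, params@noiseSdUv)
    traces[, , s] <- m
  }
  sweepInfo <- data.frame(sweep_index = seq_len(nSweeps) - 1L,
                          time_min = seq_len(nSweeps) * protocol@samplePeriodMin,
                          interval_ms = NA_real_, intensity_ma = ints)
  new("SliceBundle", sliceId = sliceId, mouseId = mouseId,
      condition = preset@condition, layout = layout, protocol = protocol,
      waveform = params, traces = traces, sweepInfo = sweepInfo,
      stimOnsetSample = onset, truth = truth)
}

#' Simulate a cohort of slices
#'
#' Generates `nSlices` independent bundles; each slice uses a sub-seed
#' derived deterministically from `seed`, so the cohort is reproducible
#' and slices are exchangeable.
#'
#' @inheritParams simulateSlice
#' @param nSlices number of slices (>= 1).
#' @param seed integer cohort seed.
#' @return list of [SliceBundle-class] objects with distinct slice ids.
#' @export
simulateCohort <- function(preset, nSlices, protocol = protocolSpec("TBS_LTP"),
                           layout = gridLayout(), seed = 1,
                           params = waveformParams()) {
  stopifnot(nSlices >= 1L)
  subSeeds <- deriveSubSeeds(seed, nSlices)
  lapply(seq_len(nSlices), function(i) {
    simulateSlice(preset, protocol, layout, seed = subSeeds[i],
                  params = params,
                  sliceId = sprintf("%s_%s_%02d", preset@condition,
                                    tolower(protocol@kind), i),
                  mouseId = sprintf("%s_mouse_%02d", preset@condition, i))
  })
}
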