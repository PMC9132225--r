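#' @import methods
NULL

LAYER_LEVELS <- c("superficial", "deep", "outside")

#' Electrode grid geometry of a planar multielectrode array
#'
#' `GridLayout` describes the 8x8 (by default) electrode grid of a planar
#' MEA dish: electrode size and pitch, the stimulation electrode, and the
#' mapping from grid column to cortical layer. Columns are assigned to
#' `"superficial"` (layers II-III), `"deep"` (layers V-VI) or `"outside"`
#' (beyond the tissue of interest); the stimulation electrode must sit in a
#' deep-layer column. Channel ids run 1..nRows*nCols in row-major order;
#' grid coordinates are 0-based `(row, col)`.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot electrodeSizeUm,pitchUm electrode side length and center-to-center
#'   spacing in micrometres.
#' @slot stimChannel integer vector `c(row, col)`, 0-based, of the
#'   stimulation electrode.
#' @slot layerOfColumn character vector of length `nCols`; one of
#'   `"superficial"`, `"deep"`, `"outside"` per column.
#'
#' @seealso [gridLayout()] for the standard constructor,
#'   [channelGrid()] for the per-channel coordinate table.
#' @export
setClass("GridLayout",
  representation(
    nRows = "integer", nCols = "integer",
    electrodeSizeUm = "numeric", pitchUm = "numeric",
    stimChannel = "integer",
    layerOfColumn = "character"
  )
)

setValidity("GridLayout", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (length(object@stimChannel) != 2L)
    msg <- c(msg, "stimChannel must be c(row, col)")
  else {
    r <- object@stimChannel[1L]; cc <- object@stimChannel[2L]
    if (r < 0L || r >= object@nRows || cc < 0L || cc >= object@nCols)
      msg <- c(msg, "stimChannel lies off the grid")
    else if (object@layerOfColumn[cc + 1L] != "deep")
      msg <- c(msg, "stimChannel's column must map to the deep layer")
  }
  if (length(object@layerOfColumn) != object@nCols)
    msg <- c(msg, "layerOfColumn must assign every column")
  if (!all(object@layerOfColumn %in% LAYER_LEVELS))
    msg <- c(msg, "layerOfColumn values must be superficial/deep/outside")
  if (object@electrodeSizeUm <= 0 || object@pitchUm <= 0)
    msg <- c(msg, "electrode size and pitch must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a GridLayout
#'
#' Defaults mirror a MED64-style dish: 8x8 grid of 50 um electrodes at
#' 150 um pitch, the stimulation electrode at 0-based `(3, 5)` in a deep
#' column, column 0 outside the tissue, columns 1-3 superficial and
#' columns 4-7 deep.
#'
#' @param nRows,nCols grid dimensions.
#' @param electrodeSizeUm,pitchUm electrode size and pitch (um).
#' @param stimChannel 0-based `c(row, col)` of the stimulation electrode.
#' @param layerOfColumn layer per column (`"superficial"`, `"deep"`,
#'   `"outside"`).
#' @return A [GridLayout-class] object.
#' @examples
#' gl <- gridLayout()
#' channelGrid(gl)[1:3, ]
#' @export
gridLayout <- function(nRows = 8L, nCols = 8L,
                       electrodeSizeUm = 50, pitchUm = 150,
                       stimChannel = c(3L, 5L),
                       layerOfColumn = c("outside",
                                         rep("superficial", 3L),
                                         rep("deep", 4L))) {
  new("GridLayout",
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      electrodeSizeUm = electrodeSizeUm, pitchUm = pitchUm,
      stimChannel = as.integer(stimChannel),
      layerOfColumn = layerOfColumn)
}

#' Stimulation protocol description
#'
#' Holds the timing structure the analysis relies on: a baseline recorded at
#' one sweep every `samplePeriodMin` minutes, plasticity induction (theta
#' burst stimulation for LTP, 1 Hz low-frequency stimulation for LTD), and a
#' post-induction recording at the same sweep rate. Paired-pulse (`"PPF"`)
#' and input-output (`"IO"`) protocols carry their own fields.
#'
#' @slot kind one of `"IO"`, `"PPF"`, `"TBS_LTP"`, `"LFS_LTD"`.
#' @slot pulseWidthMs biphasic stimulus pulse width (ms).
#' @slot baselineMin,postMin baseline and post-induction durations (min).
#' @slot samplePeriodMin sweep sampling period (min); one evoked response
#'   every 0.5 min by default.
#' @slot tbsPulsesPerBurst,tbsNBursts,tbsBurstHz,tbsInterBurstHz theta-burst
#'   structure (4 pulses at 100 Hz per burst; burst count and 5 Hz
#'   inter-burst rate are configurable).
#' @slot lfsFreqHz,lfsNPulses low-frequency stimulation: 1 Hz, 900 pulses.
#' @slot ppfIntervalsMs paired-pulse intervals (ms).
#' @slot ppfRepeats paired-pulse sweeps per interval.
#' @slot ioIntensitiesMa stimulus intensities for input-output curves (mA).
#' @export
setClass("ProtocolSpec",
  representation(
    kind = "character",
    pulseWidthMs = "numeric",
    baselineMin = "numeric", postMin = "numeric",
    samplePeriodMin = "numeric",
    tbsPulsesPerBurst = "integer", tbsNBursts = "integer",
    tbsBurstHz = "numeric", tbsInterBurstHz = "numeric",
    lfsFreqHz = "numeric", lfsNPulses = "integer",
    ppfIntervalsMs = "numeric", ppfRepeats = "integer",
    ioIntensitiesMa = "numeric"
  )
)

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("IO", "PPF", "TBS_LTP", "LFS_LTD"))
    msg <- c(msg, "kind must be IO, PPF, TBS_LTP or LFS_LTD")
  p <- object@samplePeriodMin
  if (p <= 0) msg <- c(msg, "samplePeriodMin must be positive")
  else {
    if (abs(object@baselineMin / p - round(object@baselineMin / p)) > 1e-9)
      msg <- c(msg, "samplePeriodMin must divide baselineMin")
    if (abs(object@postMin / p - round(object@postMin / p)) > 1e-9)
      msg <- c(msg, "samplePeriodMin must divide postMin")
  }
  if (object@lfsFreqHz <= 0) msg <- c(msg, "lfsFreqHz must be positive")
  if (object@kind == "PPF" && length(object@ppfIntervalsMs) < 1L)
    msg <- c(msg, "PPF protocol needs at least one interval")
  if (length(msg)) msg else TRUE
})

#' Construct a ProtocolSpec
#'
#' @param kind protocol kind: `"TBS_LTP"`, `"LFS_LTD"`, `"PPF"` or `"IO"`.
#' @param pulseWidthMs stimulus pulse width (ms, biphasic).
#' @param baselineMin,postMin baseline / post-induction durations (min).
#' @param samplePeriodMin minutes between sweeps.
#' @param tbsPulsesPerBurst,tbsNBursts,tbsBurstHz,tbsInterBurstHz TBS
#'   structure.
#' @param lfsFreqHz,lfsNPulses LFS structure (1 Hz, 900 pulses: 900 s).
#' @param ppfIntervalsMs,ppfRepeats paired-pulse intervals and repeats.
#' @param ioIntensitiesMa input-output stimulus intensities (mA).
#' @return A [ProtocolSpec-class].
#' @examples
#' protocolSpec("TBS_LTP")
#' @export
protocolSpec <- function(kind = c("TBS_LTP", "LFS_LTD", "PPF", "IO"),
                         pulseWidthMs = 0.2,
                         baselineMin = 15, postMin = 60,
                         samplePeriodMin = 0.5,
                         tbsPulsesPerBurst = 4L, tbsNBursts = 10L,
                         tbsBurstHz = 100, tbsInterBurstHz = 5,
                         lfsFreqHz = 1, lfsNPulses = 900L,
                         ppfIntervalsMs = c(25, 50, 75, 100),
                         ppfRepeats = 4L,
                         ioIntensitiesMa = seq(0.1, 0.8, by = 0.1)) {
  kind <- match.arg(kind)
  new("ProtocolSpec", kind = kind, pulseWidthMs = pulseWidthMs,
      baselineMin = baselineMin, postMin = postMin,
      samplePeriodMin = samplePeriodMin,
      tbsPulsesPerBurst = as.integer(tbsPulsesPerBurst),
      tbsNBursts = as.integer(tbsNBursts),
      tbsBurstHz = tbsBurstHz, tbsInterBurstHz = tbsInterBurstHz,
      lfsFreqHz = lfsFreqHz, lfsNPulses = as.integer(lfsNPulses),
      ppfIntervalsMs = ppfIntervalsMs, ppfRepeats = as.integer(ppfRepeats),
      ioIntensitiesMa = ioIntensitiesMa)
}

#' Waveform-shape parameters for synthetic fEPSPs
#'
#' Shape of one evoked trace: a biphasic stimulus artifact at the stimulus
#' onset followed, after a short synaptic latency, by a negative-going
#' dual-exponential field EPSP, plus additive Gaussian noise. Amplitude
#' falls off with grid distance from the stimulation electrode with spatial
#' constant `decayLengthUm`.
#'
#' @slot tauRiseMs,tauDecayMs dual-exponential rise/decay constants (ms).
#' @slot latencyMs synaptic latency from stimulus onset to fEPSP onset (ms).
#' @slot artifactAmpUv,artifactWidthMs biphasic artifact amplitude (uV) and
#'   total width (ms).
#' @slot noiseSdUv additive Gaussian noise SD (uV).
#' @slot samplingKhz sampling rate (kHz).
#' @slot preMs,postMs recorded window before/after stimulus onset (ms).
#' @slot decayLengthUm spatial amplitude decay constant (um).
#' @export
setClass("WaveformParams",
  representation(
    tauRiseMs = "numeric", tauDecayMs = "numeric", latencyMs = "numeric",
    artifactAmpUv = "numeric", artifactWidthMs = "numeric",
    noiseSdUv = "numeric", samplingKhz = "numeric",
    preMs = "numeric", postMs = "numeric",
    decayLengthUm = "numeric"
  )
)

setValidity("WaveformParams", function(object) {
  msg <- character()
  if (object@samplingKhz <= 0) msg <- c(msg, "samplingKhz must be positive")
  if (!(object@tauDecayMs > object@tauRiseMs && object@tauRiseMs > 0))
    msg <- c(msg, "need tauDecayMs > tauRiseMs > 0")
  if (object@noiseSdUv < 0) msg <- c(msg, "noiseSdUv must be >= 0")
  if (object@postMs < 50)
    msg <- c(msg, "postMs must cover >= 50 ms after the stimulus")
  vals <- c(object@latencyMs, object@artifactAmpUv, object@artifactWidthMs,
            object@preMs, object@decayLengthUm)
  if (!all(is.finite(vals))) msg <- c(msg, "parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct WaveformParams
#'
#' @param tauRiseMs,tauDecayMs fEPSP dual-exponential time constants (ms).
#' @param latencyMs synaptic latency (ms).
#' @param artifactAmpUv,artifactWidthMs stimulus artifact amplitude/width.
#' @param noiseSdUv additive Gaussian noise SD (uV).
#' @param samplingKhz sampling rate (kHz).
#' @param preMs,postMs recorded window around the stimulus (ms).
#' @param decayLengthUm spatial decay constant of amplitude with grid
#'   distance from the stimulation electrode (um).
#' @return A [WaveformParams-class].
#' @export
waveformParams <- function(tauRiseMs = 1, tauDecayMs = 8, latencyMs = 2,
                           artifactAmpUv = 200, artifactWidthMs = 0.4,
                           noiseSdUv = 2, samplingKhz = 20,
                           preMs = 8, postMs = 55,
                           decayLengthUm = 300) {
  new("WaveformParams", tauRiseMs = tauRiseMs, tauDecayMs = tauDecayMs,
      latencyMs = latencyMs, artifactAmpUv = artifactAmpUv,
      artifactWidthMs = artifactWidthMs, noiseSdUv = noiseSdUv,
      samplingKhz = samplingKhz, preMs = preMs, postMs = postMs,
      decayLengthUm = decayLengthUm)
}

#' Plasticity time-course kinetics
#'
#' After induction at time `t0`, each channel's response scales by
#' `m(t) = 1 + (plateau - 1) * (1 - exp(-(t - t0)/tau))`; before induction
#' `m(t) = 1`. `plateau > 1` yields potentiation, `< 1` depression. Channel
#' plateaus are drawn from `Normal(plateau, channelSd)`.
#'
#' @slot plateau asymptotic multiplier of the baseline response.
#' @slot tauPlasticityMin approach time constant (min).
#' @slot channelSd between-channel SD of the plateau.
#' @export
setClass("PlasticityKinetics",
  representation(plateau = "numeric", tauPlasticityMin = "numeric",
                 channelSd = "numeric"))

setValidity("PlasticityKinetics", function(object) {
  msg <- character()
  if (object@plateau < 0) msg <- c(msg, "plateau must be >= 0")
  if (object@tauPlasticityMin <= 0) msg <- c(msg, "tau must be positive")
  if (object@channelSd < 0) msg <- c(msg, "channelSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PlasticityKinetics-class
#' @param plateau asymptotic multiplier (1 = no change).
#' @param tauPlasticityMin approach time constant (min).
#' @param channelSd between-channel plateau SD.
#' @return A [PlasticityKinetics-class].
#' @export
plasticityKinetics <- function(plateau = 1, tauPlasticityMin = 5,
                               channelSd = 0.05) {
  new("PlasticityKinetics", plateau = plateau,
      tauPlasticityMin = tauPlasticityMin, channelSd = channelSd)
}

#' Generative parameters for one experimental condition
#'
#' A `ConditionPreset` fixes the generative truth of the synthetic cohort
#' for one condition (`naive`, `observer`, `demonstrator`): per-layer LTP
#' and LTD plateaus (% of baseline), the paired-pulse facilitation curve,
#' expected numbers of recruited and silenced channels per slice and layer,
#' recruited-channel asymptotic amplitudes, and the baseline amplitude
#' field (peak amplitude at the stimulation site, minimum amplitude of an
#' activated channel).
#'
#' @slot condition condition label.
#' @slot ltpPlateauPct,ltdPlateauPct named numeric `c(superficial=, deep=)`
#'   plateaus in % of baseline.
#' @slot pprCurve named numeric, facilitation ratio per interval (ms).
#' @slot nRecruited,nSilenced expected per-slice counts per layer.
#' @slot recruitedAmpUv asymptotic post-induction amplitude of recruited
#'   channels per layer (uV).
#' @slot peakAmpUv baseline fEPSP amplitude at the stimulation site (uV).
#' @slot activeMinUv minimum baseline amplitude of an activated channel
#'   (uV); cells whose distance-decayed amplitude falls below this respond
#'   at 0 uV.
#' @slot tauPlasticityMin,channelSd kinetics shared by all channels.
#' @export
setClass("ConditionPreset",
  representation(
    condition = "character",
    ltpPlateauPct = "numeric", ltdPlateauPct = "numeric",
    pprCurve = "numeric",
    nRecruited = "numeric", nSilenced = "numeric",
    recruitedAmpUv = "numeric",
    peakAmpUv = "numeric", activeMinUv = "numeric",
    tauPlasticityMin = "numeric", channelSd = "numeric"
  )
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  need <- c("superficial", "deep")
  for (sl in c("ltpPlateauPct", "ltdPlateauPct", "nRecruited",
               "nSilenced", "recruitedAmpUv")) {
    v <- slot(object, sl)
    if (!all(need %in% names(v)))
      msg <- c(msg, sprintf("%s must be named for superficial and deep", sl))
  }
  if (any(object@ltpPlateauPct <= 0) || any(object@ltdPlateauPct <= 0))
    msg <- c(msg, "plateaus must be positive")
  if (any(object@nRecruited < 0) || any(object@nSilenced < 0))
    msg <- c(msg, "expected channel counts must be >= 0")
  if (object@peakAmpUv <= 0 || object@activeMinUv <= 0)
    msg <- c(msg, "amplitude field parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' One slice's raw recording bundle
#'
#' Container for a single slice: grid layout, protocol, the per-sweep
#' 64-channel voltage traces (stored as a `channels x samples x sweeps`
#' array, uV), sweep metadata, and - for synthetic bundles only - the
#' generative ground truth (per-channel baseline amplitude, plateau,
#' recruited/silenced flags) used by test harnesses. Blinded reads drop
#' the truth.
#'
#' @slot sliceId,mouseId,condition identifiers.
#' @slot layout a [GridLayout-class].
#' @slot protocol a [ProtocolSpec-class].
#' @slot waveform the [WaveformParams-class] used to generate the data
#'   (synthetic bundles) or describing the acquisition window.
#' @slot traces numeric array `[nChannels, nSamples, nSweeps]`, uV.
#' @slot sweepInfo data.frame with one row per sweep: `sweep_index`
#'   (0-based), `time_min`, and for PPF sweeps `interval_ms`, for IO sweeps
#'   `intensity_ma`.
#' @slot stimOnsetSample 0-based sample index of the (first) stimulus.
#' @slot truth `NULL`, or the generative ground-truth data.frame.
#' @export
setClass("SliceBundle",
  representation(
    sliceId = "character", mouseId = "character", condition = "character",
    layout = "GridLayout", protocol = "ProtocolSpec",
    waveform = "WaveformParams",
    traces = "array", sweepInfo = "data.frame",
    stimOnsetSample = "integer",
    truth = "ANY"
  )
)

setValidity("SliceBundle", function(object) {
  msg <- character()
  d <- dim(object@traces)
  nCh <- object@layout@nRows * object@layout@nCols
  if (length(d) != 3L)
    msg <- c(msg, "traces must be a 3-d array [channels, samples, sweeps]")
  else {
    if (d[1L] != nCh)
      msg <- c(msg, sprintf("expected %d channels, found %d", nCh, d[1L]))
    if (d[3L] != nrow(object@sweepInfo))
      msg <- c(msg, "sweepInfo rows must match the number of sweeps")
    if (object@stimOnsetSample < 0L || object@stimOnsetSample >= d[2L])
      msg <- c(msg, "stimOnsetSample outside the trace")
  }
  tm <- object@sweepInfo$time_min
  if (!is.null(tm) && length(tm) > 1L && any(diff(tm) <= 0))
    msg <- c(msg, "sweep times must be strictly increasing")
  if (!is.null(object@truth) && !is.data.frame(object@truth))
    msg <- c(msg, "truth must be NULL or a data.frame")
  if (length(msg)) msg else TRUE
})

#' A single evoked field-potential trace
#'
#' One channel's recorded voltage around one stimulus (or stimulus pair):
#' the sample vector (uV), the sampling rate, and the 0-based sample
#' index/indices of the stimulus onset(s). Negative-going fEPSPs are the
#' measurement convention; magnitudes are reported as positive numbers.
#'
#' @slot samples numeric voltage series (uV).
#' @slot samplingKhz sampling rate (kHz).
#' @slot stimOnsetSample integer, 0-based stimulus onset sample(s).
#' @export
setClass("FEPSPTrace",
  representation(samples = "numeric", samplingKhz = "numeric",
                 stimOnsetSample = "integer"))

setValidity("FEPSPTrace", function(object) {
  msg <- character()
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (object@samplingKhz <= 0)
    msg <- c(msg, "samplingKhz must be positive")
  if (any(object@stimOnsetSample < 0L) ||
      any(object@stimOnsetSample >= length(object@samples)))
    msg <- c(msg, "stimOnsetSample outside the trace")
  if (length(msg)) msg else TRUE
})

#' @rdname FEPSPTrace-class
#' @param samples voltage samples (uV).
#' @param samplingKhz sampling rate (kHz).
#' @param stimOnsetSample 0-based stimulus onset sample index (vector for
#'   paired pulses).
#' @return A [FEPSPTrace-class].
#' @export
fepspTrace <- function(samples, samplingKhz, stimOnsetSample) {
  new("FEPSPTrace", samples = as.numeric(samples),
      samplingKhz = samplingKhz,
      stimOnsetSample = as.integer(stimOnsetSample))
}

setMethod("show", "FEPSPTrace", function(object) {
  cat(sprintf("FEPSPTrace: %d samples at %g kHz, stimulus at %s\n",
              length(object@samples), object@samplingKhz,
              paste(object@stimOnsetSample, collapse = ", ")))
})

#' Per-slice quality-control report
#'
#' Records, per channel, the activation and baseline-stability decision,
#' and at slice level the number of activated channels, the unstable
#' fraction, and whether the slice is excluded. A slice is excluded when
#' more than `maxUnstableFrac` (default 10%) of its activated channels are
#' unstable, or when it has no activated channel at all.
#'
#' @slot sliceId slice identifier.
#' @slot channelStatus data.frame: `channel_id`, `status` (`inactive`,
#'   `active_stable`, `active_unstable`), `baseline_median_amp_uV`,
#'   `baseline_mean_slope`, `baseline_cv`, `reason`.
#' @slot nActive,nUnstable counts over activated channels.
#' @slot unstableFraction `nUnstable / nActive` (0 when `nActive` is 0).
#' @slot sliceExcluded logical.
#' @slot exclusionReason character ("" when retained).
#' @export
setClass("QCReport",
  representation(
    sliceId = "character",
    channelStatus = "data.frame",
    nActive = "integer", nUnstable = "integer",
    unstableFraction = "numeric",
    sliceExcluded = "logical", exclusionReason = "character"
  )
)

setValidity("QCReport", function(object) {
  msg <- character()
  st <- object@channelStatus$status
  if (!all(st %in% c("inactive", "active_stable", "active_unstable")))
    msg <- c(msg, "invalid channel status")
  nA <- sum(st != "inactive"); nU <- sum(st == "active_unstable")
  if (object@nActive != nA || object@nUnstable != nU)
    msg <- c(msg, "nActive/nUnstable inconsistent with channelStatus")
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "GridLayout", function(object) {
  cat(sprintf("GridLayout: %d x %d electrodes (%g um, pitch %g um)\n",
              object@nRows, object@nCols, object@electrodeSizeUm,
              object@pitchUm))
  cat(sprintf("  stimulation at (row %d, col %d), layer map: %s\n",
              object@stimChannel[1L], object@stimChannel[2L],
              paste(substr(object@layerOfColumn, 1L, 1L), collapse = "")))
})

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf("ProtocolSpec <%s>: baseline %g min, post %g min, sweep every %g min\n",
              object@kind, object@baselineMin, object@postMin,
              object@samplePeriodMin))
  if (object@kind == "PPF")
    cat(sprintf("  paired-pulse intervals: %s ms x %d repeats\n",
                paste(object@ppfIntervalsMs, collapse = ", "),
                object@ppfRepeats))
})

setMethod("show", "ConditionPreset", function(object) {
  cat(sprintf("ConditionPreset <%s>\n", object@condition))
  cat(sprintf("  LTP plateau %%: superficial %.3f, deep %.3f\n",
              object@ltpPlateauPct["superficial"], object@ltpPlateauPct["deep"]))
  cat(sprintf("  LTD plateau %%: superficial %.3f, deep %.3f\n",
              object@ltdPlateauPct["superficial"], object@ltdPlateauPct["deep"]))
  cat(sprintf("  recruited/slice: %.2f sup, %.2f deep (amp %.1f / %.1f uV)\n",
              object@nRecruited["superficial"], object@nRecruited["deep"],
              object@recruitedAmpUv["superficial"],
              object@recruitedAmpUv["deep"]))
  cat(sprintf("  silenced/slice: %.2f sup, %.2f deep\n",
              object@nSilenced["superficial"], object@nSilenced["deep"]))
})

setMethod("show", "SliceBundle", function(object) {
  d <- dim(object@traces)
  cat(sprintf("SliceBundle %s (%s, %s): %d channels x %d samples x %d sweeps\n",
              object@sliceId, object@condition, object@protocol@kind,
              d[1L], d[2L], d[3L]))
  cat(sprintf("  sampling %g kHz, stimulus at sample %d%s\n",
              object@waveform@samplingKhz, object@stimOnsetSample,
              if (is.null(object@truth)) ", blinded (no truth)" else
                ", with generative truth"))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport %s: %d active (%d unstable, %.1f%%) -> %s\n",
              object@sliceId, object@nActive, object@nUnstable,
              100 * object@unstableFraction,
              if (object@sliceExcluded)
                paste0("EXCLUDED (", object@exclusionReason, ")")
              else "retained"))
})

## ---- accessors ------------------------------------------------------------

#' @rdname SliceBundle-class
#' @param object,x a `SliceBundle`.
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))
#' @rdname SliceBundle-class
#' @export
setMethod("sliceId", "SliceBundle", function(x) x@sliceId)

#' @rdname SliceBundle-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname SliceBundle-class
#' @export
setMethod("condition", "SliceBundle", function(x) x@condition)

#' @rdname SliceBundle-class
#' @export
setGeneric("layout2d", function(x) standardGeneric("layout2d"))
#' @rdname SliceBundle-class
#' @export
setMethod("layout2d", "SliceBundle", function(x) x@layout)

#' @rdname SliceBundle-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname SliceBundle-class
#' @export
setMethod("protocol", "SliceBundle", function(x) x@protocol)

#' @rdname SliceBundle-class
#' @export
setGeneric("sweepTimes", function(x) standardGeneric("sweepTimes"))
#' @rdname SliceBundle-class
#' @export
setMethod("sweepTimes", "SliceBundle", function(x) x@sweepInfo$time_min)

#' @rdname SliceBundle-class
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))
#' @rdname SliceBundle-class
#' @export
setMethod("nSweeps", "SliceBundle", function(x) dim(x@traces)[3L])

#' @rdname SliceBundle-class
#' @export
setGeneric("bundleTruth", function(x) standardGeneric("bundleTruth"))
#' @rdname SliceBundle-class
#' @export
setMethod("bundleTruth", "SliceBundle", function(x) x@truth)

#' Extract one sweep's channel x sample matrix
#'
#' @param x a [SliceBundle-class].
#' @param i 1-based sweep number.
#' @return numeric matrix `[nChannels, nSamples]` (uV).
#' @export
setGeneric("sweepTrace", function(x, i) standardGeneric("sweepTrace"))
#' @rdname sweepTrace
#' @export
setMethod("sweepTrace", "SliceBundle", function(x, i) x@traces[, , i])

#' @rdname QCReport-class
#' @param x a `QCReport`.
#' @export
setGeneric("sliceExcluded", function(x) standardGeneric("sliceExcluded"))
#' @rdname QCReport-class
#' @export
setMethod("sliceExcluded", "QCReport", function(x) x@sliceExcluded)

#' @rdname QCReport-class
#' @export
setGeneric("channelStatus", function(x) standardGeneric("channelStatus"))
#' @rdname QCReport-class
#' @export
setMethod("channelStatus", "QCReport", function(x) x@channelStatus)
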