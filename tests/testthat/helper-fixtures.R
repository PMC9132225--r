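# Shared fixtures: scaled-down protocols/waveforms so unit tests stay fast,
# and constructors for hand-built feature tables.

smallParams <- function(noiseSdUv = 2, ...) {
  waveformParams(noiseSdUv = noiseSdUv, ...)
}

# short plasticity protocol: 3-min baseline, 12-min post (covers the
# default 10-min last window), sweeps every 0.5 min -> 30 sweeps
smallProtocol <- function(kind = "TBS_LTP", baselineMin = 3, postMin = 12,
                          ...) {
  protocolSpec(kind, baselineMin = baselineMin, postMin = postMin, ...)
}

# low-rate waveform for tests where per-sample resolution is irrelevant
coarseParams <- function(noiseSdUv = 0, ...) {
  waveformParams(noiseSdUv = noiseSdUv, samplingKhz = 10, postMs = 52, ...)
}

# hand-built single-slice feature table (one row per channel x sweep),
# with the attributes extractFeatures() would attach
makeFeatures <- function(channel_id, time_min, amplitude_uV,
                         slope_uV_per_ms = amplitude_uV / 2,
                         baseline_min = 15, layer = "deep",
                         protocol_kind = "TBS_LTP",
                         slice_id = "sliceA") {
  d <- expand.grid(channel_id = channel_id, time_min = time_min)
  n <- nrow(d)
  rep_ch <- function(v) if (length(v) == length(channel_id))
    v[match(d$channel_id, channel_id)] else rep_len(v, n)
  out <- data.frame(
    slice_id = slice_id, mouse_id = "mouseA", condition = "naive",
    channel_id = d$channel_id, row = 0L,
    col = rep_ch(if (length(layer) == length(channel_id)) seq_along(channel_id) else 1L),
    layer = rep_ch(layer),
    sweep_index = match(d$time_min, sort(unique(d$time_min))) - 1L,
    time_min = d$time_min,
    phase = ifelse(d$time_min <= baseline_min, "baseline", "post"),
    pulse = 1L, interval_ms = NA_real_, intensity_ma = NA_real_,
    amplitude_uV = rep_ch(amplitude_uV),
    slope_uV_per_ms = rep_ch(slope_uV_per_ms),
    fit_r2 = 1, flag = "")
  attr(out, "protocol_kind") <- protocol_kind
  attr(out, "baseline_min") <- baseline_min
  attr(out, "sample_period_min") <- 0.5
  out
}

# dense-grid brute-force oracle for the fEPSP slope: the same stated
# definition (least-squares line over the fracLo-fracHi amplitude window
# on the initial downstroke) evaluated on the analytic waveform at 1 MHz,
# independent of the package's measurement path
denseSlopeOracle <- function(peakAmp, tauRise = 1, tauDecay = 8,
                             latency = 2, fracLo = 0.2, fracHi = 0.8,
                             khz = 1000) {
  t <- seq(0, 50, by = 1 / khz)
  tt <- pmax(t - latency, 0)
  g <- exp(-tt / tauDecay) - exp(-tt / tauRise)
  tPk <- tauRise * tauDecay / (tauDecay - tauRise) * log(tauDecay / tauRise)
  gMax <- exp(-tPk / tauDecay) - exp(-tPk / tauRise)
  d <- peakAmp * g / gMax                 # depth (positive)
  ipk <- which.max(d); A <- d[ipk]
  iLo <- max(which(d[1:ipk] <= fracLo * A))
  iHi <- max(which(d[1:ipk] <= fracHi * A))
  idx <- iLo:iHi
  unname(abs(stats::coef(stats::lm(d[idx] ~ t[idx]))[2]))
}

# discrete closed-form mean of the plasticity multiplier over the sweeps
# in the final `windowMin` minutes (independent evaluation of m(t))
lastWindowMultiplierOracle <- function(plateau, tau, baselineMin, postMin,
                                       period = 0.5, windowMin = 10) {
  times <- seq(period, baselineMin + postMin, by = period)
  w <- times[times > baselineMin + postMin - windowMin]
  mean(1 + (plateau - 1) * (1 - exp(-(w - baselineMin) / tau)))
}

# 8-connected neighbourhood, re-derived independently of the package
gridNeighborsForTest <- function(row, col, nR, nC) {
  out <- integer()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- row + dr; cc <- col + dc
    if (r >= 0 && r < nR && cc >= 0 && cc < nC)
      out <- c(out, r * nC + cc + 1L)
  }
  out
}
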