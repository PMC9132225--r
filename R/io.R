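## On-disk bundle container: a directory with
##   metadata.json   slice/layout/protocol/waveform metadata + sweep info
##   sweep_0001.csv  one CSV per sweep, one column per channel (ch01..),
##                   one row per sample, values in uV
##   truth.csv       generative ground truth (synthetic bundles only),
##                   kept in a separate file so analyses can be run blinded
## Plain text throughout: UTF-8, '.' decimal, header rows.

.protocolToList <- function(p) {
  list(kind = p@kind, pulse_width_ms = p@pulseWidthMs,
       baseline_min = p@baselineMin, post_min = p@postMin,
       sample_period_min = p@samplePeriodMin,
       tbs_pulses_per_burst = p@tbsPulsesPerBurst,
       tbs_n_bursts = p@tbsNBursts, tbs_burst_hz = p@tbsBurstHz,
       tbs_inter_burst_hz = p@tbsInterBurstHz,
       lfs_freq_hz = p@lfsFreqHz, lfs_n_pulses = p@lfsNPulses,
       ppf_intervals_ms = p@ppfIntervalsMs, ppf_repeats = p@ppfRepeats,
       io_intensities_ma = p@ioIntensitiesMa)
}

.protocolFromList <- function(l) {
  protocolSpec(kind = l$kind, pulseWidthMs = l$pulse_width_ms,
               baselineMin = l$baseline_min, postMin = l$post_min,
               samplePeriodMin = l$sample_period_min,
               tbsPulsesPerBurst = l$tbs_pulses_per_burst,
               tbsNBursts = l$tbs_n_bursts, tbsBurstHz = l$tbs_burst_hz,
               tbsInterBurstHz = l$tbs_inter_burst_hz,
               lfsFreqHz = l$lfs_freq_hz, lfsNPulses = l$lfs_n_pulses,
               ppfIntervalsMs = unlist(l$ppf_intervals_ms),
               ppfRepeats = l$ppf_repeats,
               ioIntensitiesMa = unlist(l$io_intensities_ma))
}

.waveformToList <- function(w) {
  list(tau_rise_ms = w@tauRiseMs, tau_decay_ms = w@tauDecayMs,
       latency_ms = w@latencyMs, artifact_amp_uv = w@artifactAmpUv,
       artifact_width_ms = w@artifactWidthMs, noise_sd_uv = w@noiseSdUv,
       sampling_khz = w@samplingKhz, pre_ms = w@preMs, post_ms = w@postMs,
       decay_length_um = w@decayLengthUm)
}

.waveformFromList <- function(l) {
  waveformParams(tauRiseMs = l$tau_rise_ms, tauDecayMs = l$tau_decay_ms,
                 latencyMs = l$latency_ms,
                 artifactAmpUv = l$artifact_amp_uv,
                 artifactWidthMs = l$artifact_width_ms,
                 noiseSdUv = l$noise_sd_uv, samplingKhz = l$sampling_khz,
                 preMs = l$pre_ms, postMs = l$post_ms,
                 decayLengthUm = l$decay_length_um)
}

#' Write a slice bundle to a CSV-directory container
#'
#' Creates (or overwrites files in) `path` with `metadata.json`, one
#' `sweep_%04d.csv` per sweep (channels in columns `ch01..`, samples in
#' rows, uV) and, for synthetic bundles, the generative ground truth in a
#' separate `truth.csv` so that analysis code can be run blinded.
#'
#' @param bundle a [SliceBundle-class].
#' @param path target directory.
#' @return `path`, invisibly.
#' @export
writeBundle <- function(bundle, path) {
  stopifnot(is(bundle, "SliceBundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  d <- dim(bundle@traces)
  lay <- bundle@layout
  meta <- list(
    format = "medplast-bundle", version = 1L,
    slice_id = bundle@sliceId, mouse_id = bundle@mouseId,
    condition = bundle@condition,
    n_channels = d[1L], n_samples = d[2L], n_sweeps = d[3L],
    stim_onset_sample = bundle@stimOnsetSample,
    has_truth = !is.null(bundle@truth),
    layout = list(n_rows = lay@nRows, n_cols = lay@nCols,
                  electrode_size_um = lay@electrodeSizeUm,
                  pitch_um = lay@pitchUm,
                  stim_channel = lay@stimChannel,
                  layer_of_column = lay@layerOfColumn),
    protocol = .protocolToList(bundle@protocol),
    waveform = .waveformToList(bundle@waveform),
    sweep_info = bundle@sweepInfo)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  chNames <- sprintf("ch%02d", seq_len(d[1L]))
  for (s in seq_len(d[3L])) {
    m <- t(bundle@traces[, , s])
    colnames(m) <- chNames
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(path, sprintf("sweep_%04d.csv", s)))
  }
  if (!is.null(bundle@truth))
    data.table::fwrite(bundle@truth, file.path(path, "truth.csv"))
  invisible(path)
}

#' Read a slice bundle from a CSV-directory container
#'
#' Validates the container layout while reading; schema violations raise
#' a format error naming the first offending element. With
#' `blinded = TRUE` the generative ground truth is not loaded.
#'
#' @param path bundle directory.
#' @param blinded drop the truth record (default `FALSE`).
#' @return A [SliceBundle-class].
#' @export
readBundle <- function(path, blinded = FALSE) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) stop("format error: missing metadata.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "medplast-bundle")
    stop("format error: not a medplast bundle (metadata.json: format)")
  lay <- meta$layout
  layout <- gridLayout(nRows = lay$n_rows, nCols = lay$n_cols,
                       electrodeSizeUm = lay$electrode_size_um,
                       pitchUm = lay$pitch_um,
                       stimChannel = lay$stim_channel,
                       layerOfColumn = lay$layer_of_column)
  protocol <- .protocolFromList(meta$protocol)
  wave <- .waveformFromList(meta$waveform)
  nCh <- meta$n_channels; nSa <- meta$n_samples; nSw <- meta$n_sweeps
  info <- as.data.frame(meta$sweep_info)
  if (nrow(info) != nSw)
    stop("format error: sweep_info rows disagree with n_sweeps")
  traces <- array(NA_real_, dim = c(nCh, nSa, nSw))
  for (s in seq_len(nSw)) {
    f <- file.path(path, sprintf("sweep_%04d.csv", s))
    if (!file.exists(f))
      stop(sprintf("format error: missing %s", basename(f)))
    m <- as.matrix(data.table::fread(f))
    if (ncol(m) != nCh)
      stop(sprintf("format error in %s: expected %d channels, found %d",
                   basename(f), nCh, ncol(m)))
    if (nrow(m) != nSa)
      stop(sprintf("format error in %s: expected %d samples, found %d",
                   basename(f), nSa, nrow(m)))
    traces[, , s] <- t(m)
  }
  truth <- NULL
  tf <- file.path(path, "truth.csv")
  if (!blinded && file.exists(tf))
    truth <- as.data.frame(data.table::fread(tf))
  new("SliceBundle", sliceId = meta$slice_id, mouseId = meta$mouse_id,
      condition = meta$condition, layout = layout, protocol = protocol,
      waveform = wave, traces = traces, sweepInfo = info,
      stimOnsetSample = as.integer(meta$stim_onset_sample), truth = truth)
}

#' Validate a bundle container without raising on content problems
#'
#' Runs the structural checks (metadata present and well formed, sweep
#' files complete with the declared shapes, monotone sweep times,
#' positive declared sampling rate, complete layer assignment) and
#' reports each as passed/failed. Only an unreadable path raises.
#'
#' @param path bundle directory.
#' @return data.frame `check`, `passed`, `detail`.
#' @export
validateBundle <- function(path) {
  if (!dir.exists(path)) stop("cannot read bundle directory: ", path)
  checks <- list()
  add <- function(check, passed, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check,
                                                 passed = passed,
                                                 detail = detail)
  mf <- file.path(path, "metadata.json")
  meta <- NULL
  if (!file.exists(mf)) {
    add("metadata present", FALSE, "missing metadata.json")
  } else {
    meta <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                     error = function(e) NULL)
    add("metadata present", !is.null(meta),
        if (is.null(meta)) "metadata.json unparseable" else "")
  }
  if (!is.null(meta)) {
    tm <- meta$sweep_info$time_min
    mono <- !is.null(tm) && (length(tm) < 2L || all(diff(tm) > 0))
    add("monotone sweep times", mono,
        if (!mono) "non-monotone time stamps" else "")
    khz <- meta$waveform$sampling_khz
    add("declared sampling rate", !is.null(khz) && khz > 0,
        if (is.null(khz) || khz <= 0) "non-positive sampling rate" else "")
    loc <- meta$layout$layer_of_column
    complete <- !is.null(loc) && length(loc) == meta$layout$n_cols &&
      all(loc %in% LAYER_LEVELS)
    add("complete layer assignment", complete,
        if (!complete) "incomplete layer assignment" else "")
    nSw <- meta$n_sweeps %||% 0L
    files <- sprintf("sweep_%04d.csv", seq_len(nSw))
    missing <- files[!file.exists(file.path(path, files))]
    add("sweep files complete", length(missing) == 0L,
        if (length(missing)) paste("missing", missing[1L]) else "")
    if (length(missing) == 0L && nSw > 0L) {
      shapeOk <- TRUE; detail <- ""
      for (s in seq_len(nSw)) {
        m <- tryCatch(data.table::fread(file.path(path, files[s])),
                      error = function(e) NULL)
        if (is.null(m) || ncol(m) != meta$n_channels ||
            nrow(m) != meta$n_samples) {
          shapeOk <- FALSE
          detail <- sprintf("%s: expected %d channels x %d samples",
                            files[s], meta$n_channels, meta$n_samples)
          break
        }
      }
      add("sweep shapes", shapeOk, detail)
    }
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
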