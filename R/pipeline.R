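## One-command orchestration: simulate (or ingest) -> features -> QC ->
## plasticity / recruitment -> spatial maps -> group summaries, streaming
## slice by slice so raw traces never accumulate in memory.

#' Analyze a single slice bundle
#'
#' Runs feature extraction, QC, baseline normalization, last-window
#' plasticity calls, recruitment or silencing detection (by protocol
#' kind), and the spatial map for one bundle. An excluded slice returns
#' its QC report and exclusion reason with `NULL` analysis results.
#'
#' @param bundle a [SliceBundle-class].
#' @param thresholdUv activation threshold (uV).
#' @param cvLimit baseline-stability CV limit.
#' @param maxUnstableFrac slice-exclusion threshold.
#' @param stabilityWindowMin stability window (min).
#' @param lastWindowMin last-window duration (min).
#' @param potThresholdPct,depThresholdPct plasticity label thresholds.
#' @return list: `slice_id`, `qc`, `excluded`, `reason`, and for retained
#'   plasticity slices `calls`, `recruitment`, `map`, `counts`.
#' @export
analyzeSlice <- function(bundle, thresholdUv = 10, cvLimit = 0.05,
                         maxUnstableFrac = 0.10, stabilityWindowMin = 15,
                         lastWindowMin = 10, potThresholdPct = 115,
                         depThresholdPct = 85) {
  feats <- extractFeatures(bundle)
  qc <- sliceQC(feats, thresholdUv = thresholdUv,
                windowMin = stabilityWindowMin, cvLimit = cvLimit,
                maxUnstableFrac = maxUnstableFrac)
  base <- list(slice_id = sliceId(bundle), condition = condition(bundle),
               qc = qc, excluded = sliceExcluded(qc),
               reason = qc@exclusionReason,
               calls = NULL, recruitment = NULL, map = NULL, counts = NULL)
  if (sliceExcluded(qc)) return(base)
  kind <- bundle@protocol@kind
  if (!kind %in% c("TBS_LTP", "LFS_LTD")) {
    base$features <- feats
    return(base)
  }
  series <- normalizeToBaseline(feats, qc)
  calls <- summarizeLastWindow(series, windowMin = lastWindowMin,
                               potThresholdPct = potThresholdPct,
                               depThresholdPct = depThresholdPct)
  recruitment <- if (kind == "TBS_LTP")
    detectRecruited(feats, qc, thresholdUv, lastWindowMin)
  else
    detectSilenced(feats, qc, thresholdUv, lastWindowMin)
  map <- buildSpatialMap(qc, calls, recruitment, bundle@layout)
  map <- flagEdgeChannels(map)
  base$calls <- calls
  base$recruitment <- recruitment
  base$map <- map
  base$counts <- cbind(slice_id = sliceId(bundle), countByLayer(map))
  base
}

.protocolKind <- function(protocol) {
  k <- toupper(protocol)
  switch(k,
         TBS = , TBS_LTP = "TBS_LTP",
         LFS = , LFS_LTD = "LFS_LTD",
         PPF = "PPF", IO = "IO",
         stop("unknown protocol: ", protocol))
}

#' Simulate and analyze one condition's cohort
#'
#' Streams `nSlices` synthetic slices (one sub-seed each, derived from
#' `seed`) through [analyzeSlice()] and pools the results. The layer
#' group summary averages the per-channel last-window means over all
#' analyzed channels of the layer, excluding channels called silenced
#' (reported separately).
#'
#' @param condition condition name or a [ConditionPreset-class].
#' @param protocol protocol kind (`"tbs"`, `"lfs"`) or a
#'   [ProtocolSpec-class].
#' @param nSlices cohort size.
#' @param seed cohort seed.
#' @param layout a [GridLayout-class].
#' @param params a [WaveformParams-class].
#' @param ... thresholds passed to [analyzeSlice()].
#' @return list: `condition`, `calls`, `recruitment`, `counts`,
#'   `layer_summary`, `qc` (per-slice summaries), `excluded`.
#' @export
analyzeCohort <- function(condition, protocol = "tbs", nSlices = 1L,
                          seed = 1L, layout = gridLayout(),
                          params = waveformParams(), ...) {
  preset <- if (is(condition, "ConditionPreset")) condition
            else conditionPreset(condition)
  proto <- if (is(protocol, "ProtocolSpec")) protocol
           else protocolSpec(.protocolKind(protocol))
  subSeeds <- deriveSubSeeds(seed, nSlices)
  res <- vector("list", nSlices)
  for (i in seq_len(nSlices)) {
    b <- simulateSlice(preset, proto, layout, seed = subSeeds[i],
                       params = params,
                       sliceId = sprintf("%s_%s_%02d", preset@condition,
                                         tolower(proto@kind), i),
                       mouseId = sprintf("%s_mouse_%02d",
                                         preset@condition, i))
    res[[i]] <- analyzeSlice(b, ...)
    rm(b)
  }
  .poolCohort(res, preset@condition)
}

#' Analyze already-recorded bundles as one cohort
#'
#' @param paths bundle directories (read blinded).
#' @param ... thresholds passed to [analyzeSlice()].
#' @return as [analyzeCohort()].
#' @export
analyzeBundles <- function(paths, ...) {
  res <- lapply(paths, function(p) analyzeSlice(readBundle(p, blinded = TRUE),
                                                ...))
  cond <- unique(vapply(res, `[[`, "", "condition"))
  .poolCohort(res, paste(cond, collapse = "+"))
}

.poolCohort <- function(res, condition) {
  bindPart <- function(name) {
    parts <- Filter(Negate(is.null), lapply(res, `[[`, name))
    if (length(parts)) do.call(rbind, parts) else NULL
  }
  calls <- bindPart("calls")
  recruitment <- bindPart("recruitment")
  counts <- bindPart("counts")
  silencedKeys <- if (!is.null(recruitment))
    recruitment[recruitment$silenced, c("slice_id", "channel_id")]
  else NULL
  summary <- if (!is.null(calls))
    cbind(condition = condition, layerSummary(calls, exclude = silencedKeys))
  else NULL
  qcRows <- do.call(rbind, lapply(res, function(r)
    data.frame(slice_id = r$slice_id, n_active = r$qc@nActive,
               n_unstable = r$qc@nUnstable,
               unstable_fraction = r$qc@unstableFraction,
               excluded = r$excluded, reason = r$reason)))
  list(condition = condition, calls = calls, recruitment = recruitment,
       counts = counts, layer_summary = summary, qc = qcRows,
       excluded = qcRows[qcRows$excluded, , drop = FALSE],
       maps = Filter(Negate(is.null), lapply(res, `[[`, "map")))
}

#' Build a pipeline configuration
#'
#' @param conditions condition names to simulate.
#' @param protocol protocol kind (`"tbs"` or `"lfs"`).
#' @param nSlices cohort sizes, recycled across conditions.
#' @param inputs optional bundle directories to analyze instead of
#'   simulating (grouped by their stored condition).
#' @param seed root seed; all randomness derives from it.
#' @param outDir output directory.
#' @param params a [WaveformParams-class] for simulated cohorts.
#' @param thresholdUv,cvLimit,maxUnstableFrac,stabilityWindowMin,lastWindowMin,potThresholdPct,depThresholdPct
#'   analysis thresholds (see [analyzeSlice()]).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(conditions = c("naive", "observer", "demonstrator"),
                           protocol = "tbs", nSlices = 6L, inputs = NULL,
                           seed = 1L, outDir = tempfile("medplast_run_"),
                           params = waveformParams(),
                           thresholdUv = 10, cvLimit = 0.05,
                           maxUnstableFrac = 0.10, stabilityWindowMin = 15,
                           lastWindowMin = 10, potThresholdPct = 115,
                           depThresholdPct = 85) {
  stopifnot(thresholdUv > 0, cvLimit >= 0, maxUnstableFrac >= 0,
            lastWindowMin > 0)
  structure(list(conditions = conditions, protocol = protocol,
                 params = params,
                 nSlices = rep(as.integer(nSlices),
                               length.out = length(conditions)),
                 inputs = inputs, seed = as.integer(seed), outDir = outDir,
                 thresholdUv = thresholdUv, cvLimit = cvLimit,
                 maxUnstableFrac = maxUnstableFrac,
                 stabilityWindowMin = stabilityWindowMin,
                 lastWindowMin = lastWindowMin,
                 potThresholdPct = potThresholdPct,
                 depThresholdPct = depThresholdPct),
            class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Simulates (or ingests) every cohort, analyzes each slice, pools the
#' condition-level summaries, runs pairwise Welch comparisons of the
#' per-channel last-window means between conditions within each layer,
#' and writes tidy CSV results plus a JSON run manifest to the output
#' directory. Deterministic for a fixed configuration and seed.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list with per-condition results, `comparisons`,
#'   and the `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  thr <- config[c("thresholdUv", "cvLimit", "maxUnstableFrac",
                  "stabilityWindowMin", "lastWindowMin",
                  "potThresholdPct", "depThresholdPct")]
  cohorts <- list()
  if (is.null(config$inputs)) {
    condSeeds <- deriveSubSeeds(config$seed, length(config$conditions))
    for (i in seq_along(config$conditions)) {
      cohorts[[config$conditions[i]]] <-
        do.call(analyzeCohort,
                c(list(condition = config$conditions[i],
                       protocol = config$protocol,
                       nSlices = config$nSlices[i], seed = condSeeds[i],
                       params = config$params),
                  thr))
    }
  } else {
    cohorts[["input"]] <- do.call(analyzeBundles,
                                  c(list(paths = config$inputs), thr))
  }

  nRetained <- sum(vapply(cohorts, function(co)
    sum(!co$qc$excluded), 0L))
  if (nRetained == 0L)
    stop("pipeline error: all slices excluded by QC")

  calls <- do.call(rbind, Filter(Negate(is.null), lapply(names(cohorts),
    function(nm) {
      co <- cohorts[[nm]]
      if (is.null(co$calls)) return(NULL)
      cbind(condition = nm, co$calls)
    })))
  recruitment <- do.call(rbind, Filter(Negate(is.null),
    lapply(names(cohorts), function(nm) {
      co <- cohorts[[nm]]
      if (is.null(co$recruitment)) return(NULL)
      cbind(condition = nm, co$recruitment)
    })))
  counts <- do.call(rbind, Filter(Negate(is.null),
    lapply(cohorts, `[[`, "counts")))
  summaries <- do.call(rbind, Filter(Negate(is.null),
    lapply(cohorts, `[[`, "layer_summary")))

  comparisons <- .pairwiseWelch(calls, recruitment)

  wr <- function(d, f) if (!is.null(d))
    data.table::fwrite(d, file.path(config$outDir, f))
  wr(calls, "plasticity_calls.csv")
  wr(recruitment, "recruitment.csv")
  wr(counts, "layer_counts.csv")
  wr(summaries, "group_summary.csv")
  wr(comparisons, "comparisons.csv")

  manifest <- list(
    package = "medplast",
    version = as.character(utils::packageVersion("medplast")),
    seed = config$seed,
    protocol = if (is(config$protocol, "ProtocolSpec"))
      config$protocol@kind else config$protocol,
    conditions = lapply(names(cohorts), function(nm) {
      co <- cohorts[[nm]]
      list(condition = nm,
           n_slices = nrow(co$qc),
           n_excluded = sum(co$qc$excluded),
           excluded = if (nrow(co$excluded))
             co$excluded[, c("slice_id", "reason")] else NULL)
    }),
    thresholds = thr,
    outputs = list.files(config$outDir, pattern = "[.]csv$"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(list(cohorts = cohorts, calls = calls,
                 recruitment = recruitment, counts = counts,
                 summaries = summaries, comparisons = comparisons,
                 manifest = manifest))
}

## Welch comparisons of channel-level last-window means between every
## condition pair, within layer; silenced channels excluded as in the
## group summary
.pairwiseWelch <- function(calls, recruitment) {
  if (is.null(calls)) return(NULL)
  x <- calls[calls$layer %in% c("superficial", "deep"), ]
  if (!is.null(recruitment)) {
    sil <- recruitment[recruitment$silenced, ]
    x <- x[!paste(x$slice_id, x$channel_id) %in%
             paste(sil$slice_id, sil$channel_id), ]
  }
  conds <- unique(x$condition)
  if (length(conds) < 2L) return(NULL)
  out <- list()
  for (lay in unique(x$layer)) {
    for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds)) {
      a <- x$last_window_mean_pct[x$condition == conds[i] & x$layer == lay]
      b <- x$last_window_mean_pct[x$condition == conds[j] & x$layer == lay]
      if (length(a) >= 2L && length(b) >= 2L) {
        w <- welchT(a, b, conds[i], conds[j])
        out[[length(out) + 1L]] <- cbind(layer = lay, w)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
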