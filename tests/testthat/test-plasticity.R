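qcAllStable <- function(ids, slice_id = "sliceA") {
  cs <- data.frame(channel_id = ids, status = "active_stable",
                   baseline_median_amp_uV = 50, baseline_mean_slope = 25,
                   baseline_cv = 0.01, reason = "")
  new("QCReport", sliceId = slice_id, channelStatus = cs,
      nActive = length(ids), nUnstable = 0L, unstableFraction = 0,
      sliceExcluded = FALSE, exclusionReason = "")
}

test_that("baseline normalization averages to exactly 100%", {
  f <- makeFeatures(1:3, seq(0.5, 25, by = 0.5), amplitude_uV = 50,
                    slope_uV_per_ms = 25)
  s <- normalizeToBaseline(f, qcAllStable(1:3))
  base <- s[s$phase == "baseline", ]
  for (ch in 1:3)
    expect_equal(mean(base$normalized_slope_pct[base$channel_id == ch]),
                 100, tolerance = 1e-9)
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(5)
  sl <- 25 * exp(stats::rnorm(50, 0, 0.02))
  f <- makeFeatures(1L, seq(0.5, 25, by = 0.5), amplitude_uV = 50)
  f$slope_uV_per_ms <- sl
  s1 <- normalizeToBaseline(f, qcAllStable(1L))
  # doubling every raw slope changes nothing after normalization
  f2 <- f; f2$slope_uV_per_ms <- 2 * sl
  s2 <- normalizeToBaseline(f2, qcAllStable(1L))
  expect_equal(s1$normalized_slope_pct, s2$normalized_slope_pct,
               tolerance = 1e-12)
  # feeding the normalized series back in returns it unchanged
  f3 <- f; f3$slope_uV_per_ms <- s1$normalized_slope_pct
  s3 <- normalizeToBaseline(f3, qcAllStable(1L))
  expect_equal(s3$normalized_slope_pct, s1$normalized_slope_pct,
               tolerance = 1e-12)
})

test_that("excluded slices and non-positive baselines are refused/dropped", {
  f <- makeFeatures(1:2, seq(0.5, 25, by = 0.5), amplitude_uV = 50,
                    slope_uV_per_ms = 25)
  qc <- qcAllStable(1:2)
  qc@sliceExcluded <- TRUE; qc@exclusionReason <- "unstable"
  expect_error(normalizeToBaseline(f, qc), "excluded")
  f$slope_uV_per_ms[f$channel_id == 2] <- 0
  s <- normalizeToBaseline(f, qcAllStable(1:2))
  expect_false(2L %in% s$channel_id)
  expect_identical(attr(s, "dropped")$channel_id, 2L)
})

test_that("identity kinetics give 100% and label 'unchanged'", {
  b <- simulateSlice(conditionPreset("naive"), smallProtocol(),
                     seed = 31, params = smallParams(noiseSdUv = 0))
  tr <- bundleTruth(b)
  # force all plateaus to 1 by rebuilding with channelSd 0 and plateau 1
  p <- conditionPreset("naive", channelSd = 0)
  p@ltpPlateauPct <- c(superficial = 100, deep = 100)
  p@nRecruited <- c(superficial = 0, deep = 0)
  b <- simulateSlice(p, smallProtocol(), seed = 31,
                     params = smallParams(noiseSdUv = 0))
  f <- extractFeatures(b)
  qc <- sliceQC(f)
  calls <- summarizeLastWindow(normalizeToBaseline(f, qc))
  expect_equal(max(abs(calls$last_window_mean_pct - 100)), 0,
               tolerance = 1e-6)
  expect_true(all(calls$label == "unchanged"))
})

test_that("noise-free last-window means equal the closed-form kinetics", {
  # full-length protocol, plateau 1.5, no noise, no channel spread:
  # measured normalized slope must reproduce the sampled mean of m(t)
  p <- conditionPreset("naive", channelSd = 0)
  p@ltpPlateauPct <- c(superficial = 150, deep = 150)
  p@nRecruited <- c(superficial = 0, deep = 0)
  b <- simulateSlice(p, protocolSpec("TBS_LTP"), seed = 32,
                     params = coarseParams(noiseSdUv = 0))
  f <- extractFeatures(b)
  qc <- sliceQC(f)
  calls <- summarizeLastWindow(normalizeToBaseline(f, qc))
  oracle <- 100 * lastWindowMultiplierOracle(1.5, tau = 5,
                                             baselineMin = 15, postMin = 60)
  expect_lt(max(abs(calls$last_window_mean_pct - oracle)) / oracle, 1e-6)
})

test_that("group means recover plateaus across the LTP/LTD range", {
  # plateaus spanning the reported group outcomes; ~34 channels per run,
  # 2 uV noise; recovered group mean within 2 percentage points
  for (P in c(0.67, 0.85, 1.08, 1.29, 1.54)) {
    p <- conditionPreset("naive")
    kind <- if (P < 1) "LFS_LTD" else "TBS_LTP"
    if (P < 1) p@ltdPlateauPct <- c(superficial = P * 100, deep = P * 100)
    else       p@ltpPlateauPct <- c(superficial = P * 100, deep = P * 100)
    p@nRecruited <- c(superficial = 0, deep = 0)
    p@nSilenced <- c(superficial = 0, deep = 0)
    b <- simulateSlice(p, smallProtocol(kind, baselineMin = 3, postMin = 40),
                       seed = round(1000 * P),
                       params = smallParams(noiseSdUv = 2))
    f <- extractFeatures(b)
    qc <- sliceQC(f, windowMin = 3)
    calls <- summarizeLastWindow(normalizeToBaseline(f, qc))
    ls <- layerSummary(calls)
    pooled <- sum(ls$mean_pct * ls$n_channels) / sum(ls$n_channels)
    expect_lt(abs(pooled - P * 100), 2)
  }
})

test_that("paired-pulse ratios are exact without noise", {
  p <- conditionPreset("naive")
  proto <- protocolSpec("PPF", ppfIntervalsMs = c(25, 50), ppfRepeats = 2L)
  # identical pulses: ratio 1 everywhere
  p1 <- p; p1@pprCurve <- c("25" = 1, "50" = 1)
  b <- simulateSlice(p1, proto, seed = 41, params = smallParams(noiseSdUv = 0))
  ppr <- computePPR(extractFeatures(b))
  expect_lt(max(abs(ppr$ppr - 1)), 0.02)
  # facilitation 1.4 at 50 ms within 1%; overlapping tail at 25 ms within 2%
  p2 <- p; p2@pprCurve <- c("25" = 1.4, "50" = 1.4)
  b2 <- simulateSlice(p2, proto, seed = 42, params = smallParams(noiseSdUv = 0))
  ppr2 <- computePPR(extractFeatures(b2))
  m50 <- mean(ppr2$ppr[ppr2$interval_ms == 50])
  m25 <- mean(ppr2$ppr[ppr2$interval_ms == 25])
  expect_lt(abs(m50 - 1.4) / 1.4, 0.01)
  expect_lt(abs(m25 - 1.4) / 1.4, 0.02)
})

test_that("recruitment and silencing follow the threshold rules", {
  tm <- seq(0.5, 25, by = 0.5)
  f <- makeFeatures(1:3, tm, amplitude_uV = 1)
  # ch1: silent -> 18 uV (recruited); ch2: baseline 15 uV (ineligible);
  # ch3: stays silent
  post <- f$phase == "post"
  f$amplitude_uV[f$channel_id == 1 & post] <- 18
  f$amplitude_uV[f$channel_id == 2] <- 15
  f$amplitude_uV[f$channel_id == 3] <- 1
  qc <- qcAllStable(2L)
  rec <- detectRecruited(f, qc)
  expect_true(rec$recruited[rec$channel_id == 1])
  expect_false(rec$recruited[rec$channel_id == 2])
  expect_false(rec$recruited[rec$channel_id == 3])

  fL <- makeFeatures(1:3, tm, amplitude_uV = 20,
                     protocol_kind = "LFS_LTD")
  postL <- fL$phase == "post"
  fL$amplitude_uV[fL$channel_id == 1 & postL] <- 1    # silenced
  fL$amplitude_uV[fL$channel_id == 2 & postL] <- 15   # still active
  sil <- detectSilenced(fL, qcAllStable(1:3))
  expect_true(sil$silenced[sil$channel_id == 1])
  expect_false(sil$silenced[sil$channel_id == 2])
  expect_false(any(sil$recruited))
  # protocol-kind guard
  expect_error(detectRecruited(fL, qcAllStable(1:3)), "TBS")
  expect_error(detectSilenced(f, qcAllStable(1:3)), "LFS")
})

test_that("noise-free recruitment calls equal the generator truth", {
  b <- simulateSlice(conditionPreset("observer"), smallProtocol(),
                     seed = 51, params = smallParams(noiseSdUv = 0))
  f <- extractFeatures(b)
  qc <- sliceQC(f)
  rec <- detectRecruited(f, qc)
  tr <- bundleTruth(b)
  expect_identical(sort(rec$channel_id[rec$recruited]),
                   sort(tr$channel_id[tr$recruited]))

  # silencing needs the decayed response to dominate the final window, so
  # give the LFS slice a longer post period than the other small fixtures
  bL <- simulateSlice(conditionPreset("observer"),
                      smallProtocol("LFS_LTD", postMin = 30),
                      seed = 52, params = smallParams(noiseSdUv = 0))
  fL <- extractFeatures(bL)
  sil <- detectSilenced(fL, sliceQC(fL))
  trL <- bundleTruth(bL)
  expect_identical(sort(sil$channel_id[sil$silenced]),
                   sort(trL$channel_id[trL$silenced]))
  # disjointness: recruited, silenced and analysed sets are consistent
  expect_false(any(sil$recruited & sil$silenced))
  expect_true(all(sil$baseline_amp_uV[sil$silenced] > 10))
  expect_true(all(rec$baseline_amp_uV[rec$recruited] <= 10))
})
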