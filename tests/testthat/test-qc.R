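baseTimes <- seq(0.5, 15, by = 0.5)

test_that("activation uses a strict 10-uV threshold on the baseline median", {
  f <- makeFeatures(channel_id = 1:3, time_min = baseTimes,
                    amplitude_uV = c(9.9, 10.0, 10.1))
  act <- classifyActivated(f)
  expect_identical(act$activated, c(FALSE, FALSE, TRUE))
  expect_error(classifyActivated(f[0, ]), "empty")
})

test_that("noise-free activation flags equal the generator truth", {
  b <- simulateSlice(conditionPreset("naive"), smallProtocol(),
                     seed = 21, params = smallParams(noiseSdUv = 0))
  f <- extractFeatures(b)
  act <- classifyActivated(f)
  tr <- bundleTruth(b)
  expect_identical(act$activated[order(act$channel_id)],
                   tr$active[order(tr$channel_id)])
})

test_that("stability is the population CV of baseline slopes, strictly below 5%", {
  sl <- rep(c(95, 105), length.out = length(baseTimes))   # mean 100, sd 5
  f <- makeFeatures(1:2, baseTimes, amplitude_uV = 50,
                    slope_uV_per_ms = 25)
  f$slope_uV_per_ms[f$channel_id == 2] <- sl[f$sweep_index[f$channel_id == 2] + 1]
  st <- assessBaselineStability(f)
  expect_true(st$stable[st$channel_id == 1])               # CV = 0
  expect_equal(st$baseline_cv[st$channel_id == 2], 0.05, tolerance = 1e-12)
  expect_false(st$stable[st$channel_id == 2])              # strict <

  fz <- makeFeatures(1L, baseTimes, amplitude_uV = 50, slope_uV_per_ms = 0)
  stz <- assessBaselineStability(fz)
  expect_false(stz$stable)
  expect_identical(stz$reason, "degenerate baseline")
})

test_that("slice exclusion follows the strict >10% unstable rule", {
  mk <- function(nActive, nUnstable) {
    amp <- rep(50, nActive)
    f <- makeFeatures(seq_len(nActive), baseTimes, amplitude_uV = amp,
                      slope_uV_per_ms = 25)
    for (ch in seq_len(nUnstable)) {
      idx <- f$channel_id == ch
      f$slope_uV_per_ms[idx] <- 25 * rep(c(0.8, 1.2),
                                         length.out = sum(idx))
    }
    sliceQC(f)
  }
  qcBad <- mk(20, 3)                              # 15% -> excluded
  expect_true(sliceExcluded(qcBad))
  qcOk <- mk(20, 2)                               # exactly 10% -> retained
  expect_false(sliceExcluded(qcOk))
  # conservation: n_active = active_stable + active_unstable
  st <- channelStatus(qcBad)$status
  expect_identical(qcBad@nActive,
                   sum(st == "active_stable") + sum(st == "active_unstable"))
  expect_identical(qcBad@nUnstable, 3L)
})

test_that("a slice with no active channels is excluded with a reason", {
  f <- makeFeatures(1:4, baseTimes, amplitude_uV = 3)
  qc <- sliceQC(f)
  expect_true(sliceExcluded(qc))
  expect_match(qc@exclusionReason, "no active channels")
})

test_that("exclusion is monotone in the number of unstable channels", {
  mkReport <- function(nStable, nUnstable) {
    status <- c(rep("active_stable", nStable),
                rep("active_unstable", nUnstable))
    cs <- data.frame(channel_id = seq_along(status), status = status,
                     baseline_median_amp_uV = 50, baseline_mean_slope = 25,
                     baseline_cv = 0.01, reason = "")
    applySliceExclusion(new("QCReport", sliceId = "s", channelStatus = cs,
                            nActive = length(status),
                            nUnstable = as.integer(nUnstable),
                            unstableFraction = nUnstable / length(status),
                            sliceExcluded = FALSE, exclusionReason = ""))
  }
  for (nS in c(5L, 10L, 20L)) {
    excludedBefore <- FALSE
    for (nU in 0:6) {
      ex <- sliceExcluded(mkReport(nS, nU))
      expect_false(excludedBefore && !ex)   # never un-excludes
      excludedBefore <- ex
    }
  }
})

test_that("activation sensitivity and specificity beat 0.95 at 2 uV noise", {
  tp <- fp <- tn <- fn <- 0
  for (s in 1:4) {                       # 4 slices x 64 channels = 256
    b <- simulateSlice(conditionPreset("observer"), smallProtocol(),
                       seed = 100 + s, params = smallParams(noiseSdUv = 2))
    f <- extractFeatures(b)
    act <- classifyActivated(f)
    tr <- bundleTruth(b)
    truthAct <- tr$active[match(act$channel_id, tr$channel_id)]
    tp <- tp + sum(act$activated & truthAct)
    fn <- fn + sum(!act$activated & truthAct)
    fp <- fp + sum(act$activated & !truthAct)
    tn <- tn + sum(!act$activated & !truthAct)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tn / (tn + fp), 0.95)
})

test_that("layer assignment follows the layout and is measurement-neutral", {
  lay <- gridLayout()
  f <- makeFeatures(1:64, c(0.5, 1), amplitude_uV = 50)
  f2 <- assignLayers(lay, f)
  grid <- channelGrid(lay)
  stimId <- grid$channel_id[grid$is_stim]
  expect_identical(unique(f2$layer[f2$channel_id == stimId]), "deep")
  expect_identical(unique(f2$layer[f2$col == 0]), "outside")
  # relabelling columns permutes only the layer column
  lay2 <- gridLayout(layerOfColumn = c("superficial", "superficial",
                                       "superficial", "superficial",
                                       "deep", "deep", "deep", "deep"))
  f3 <- assignLayers(lay2, f2)
  expect_identical(f3$amplitude_uV, f2$amplitude_uV)
  expect_identical(f3$slope_uV_per_ms, f2$slope_uV_per_ms)
  expect_false(identical(f3$layer, f2$layer))
})

test_that("stimulus calibration picks the 40-60% band or falls back", {
  io <- data.frame(intensity = c(0.1, 0.2, 0.3, 0.4),
                   slope = c(10, 30, 55, 100))
  expect_equal(as.numeric(calibrateStimIntensity(io)), 0.3)
  # monotone curve skipping the band: fallback with warning
  io2 <- data.frame(intensity = c(0.1, 0.2, 0.3),
                    slope = c(10, 30, 100))
  expect_warning(pick <- calibrateStimIntensity(io2), "band")
  expect_equal(as.numeric(pick), 0.2)    # 30% of max, closest to 50%
  # all responses equal: every point is the max; fallback to the first
  io3 <- data.frame(intensity = c(0.1, 0.2, 0.3), slope = c(50, 50, 50))
  expect_warning(pick3 <- calibrateStimIntensity(io3))
  expect_equal(as.numeric(pick3), 0.1)
  expect_error(calibrateStimIntensity(
    data.frame(intensity = c(0.1, 0.2, 0.3), slope = c(0, 0, 0))), "zero")
  expect_error(calibrateStimIntensity(io[1:2, ]), "3")
})
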